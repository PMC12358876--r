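# Tomographic vesicle quantification: attachment fractions by rod end,
# internalized-membrane location fractions, and per-rod tube/disc content
# histograms.

#' Vesicle attachment and internal-location statistics
#'
#' Computes (i) the fraction of end-attached vesicles found at the thin vs
#' thick rod end and (ii) among rods containing internalized membrane, the
#' fraction located at the thick end vs centrally. Both raw fractions and
#' integer percentages are reported, under both floor and half-up rounding
#' side by side: published percentage pairs that sum to 99 indicate that at
#' least one printed value was truncated, so neither mode alone can
#' reproduce every printed figure.
#'
#' @param table A `vesicle_table` (see [gen_vesicle_table()]) or data.frame
#'   with columns attachment, internal_location.
#' @return A `vesicle_stats` list with elements `attachment` and
#'   `internal`, each holding `counts`, `n` (denominator), `fraction`,
#'   `pct_floor`, `pct_half_up`. A zero denominator yields the marker
#'   string "undefined" in place of the percentage lists.
#' @export
#' @examples
#' tab <- gen_vesicle_table(249, seed = 1)
#' vesicle_stats(tab)
vesicle_stats <- function(table) {
  tab <- as.data.frame(table)
  if (nrow(tab) == 0L) stop("empty vesicle table", call. = FALSE)

  summarize <- function(x, levels) {
    x <- x[x %in% levels]
    n <- length(x)
    if (n == 0L) return("undefined")
    counts <- vapply(levels, function(l) sum(x == l), integer(1))
    frac <- counts / n
    list(counts = counts, n = n, fraction = frac,
         pct_floor = floor(100 * frac),
         pct_half_up = floor(100 * frac + 0.5))
  }
  structure(
    list(attachment = summarize(tab$attachment,
                                c("thin_end", "thick_end")),
         internal = summarize(tab$internal_location,
                              c("thick_end", "central"))),
    class = "vesicle_stats")
}

#' @export
print.vesicle_stats <- function(x, ...) {
  show <- function(s, what) {
    if (identical(s, "undefined")) {
      cat(sprintf("  %s: undefined (zero denominator)\n", what))
      return(invisible())
    }
    cat(sprintf("  %s (n = %d): %s\n", what, s$n,
                paste(sprintf("%s %d (%d%%)", names(s$counts), s$counts,
                              s$pct_half_up), collapse = ", ")))
  }
  cat("Tomographic vesicle statistics (half-up percentages):\n")
  show(x$attachment, "end attachments")
  show(x$internal, "internal locations")
  invisible(x)
}

#' Per-rod tube and disc content histograms
#'
#' Integer-binned histograms of the number of tubular vesicles and
#' membrane discs per rod, with the modal range (the contiguous run of
#' counts, containing the mode, whose frequency is at least half the modal
#' frequency) summarizing what an average rod contains.
#'
#' @param table A `vesicle_table` or data.frame with columns n_tubes,
#'   n_discs.
#' @return List with `tubes` and `discs` (data.frames count, n), `modal`
#'   (list of integer ranges), and `n_rods`. An empty table gives empty
#'   histograms.
#' @export
rod_content_hist <- function(table) {
  tab <- as.data.frame(table)
  hist_of <- function(x) {
    if (length(x) == 0L) {
      return(data.frame(count = integer(0), n = integer(0)))
    }
    vals <- 0:max(x)
    data.frame(count = vals,
               n = vapply(vals, function(v) sum(x == v), integer(1)))
  }
  modal_range <- function(h) {
    if (nrow(h) == 0L || all(h$n == 0)) return(c(NA_integer_, NA_integer_))
    peak <- which.max(h$n)
    ok <- h$n >= h$n[peak] / 2
    lo <- peak
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- peak
    while (hi < nrow(h) && ok[hi + 1L]) hi <- hi + 1L
    c(h$count[lo], h$count[hi])
  }
  tubes <- hist_of(tab$n_tubes)
  discs <- hist_of(tab$n_discs)
  list(tubes = tubes, discs = discs,
       modal = list(tubes = modal_range(tubes), discs = modal_range(discs)),
       n_rods = nrow(tab))
}
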