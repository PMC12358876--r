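# Flat-file interchange: point clouds as CSV, umbrella windows and tables
# as TSV. All coordinates are Angstrom, energies kcal mol^-1.

#' Read and write leaflet point clouds as CSV
#'
#' Columns: x, y, z, leaflet.
#'
#' @param cloud A `leaflet_cloud` or a data.frame with those columns.
#' @param path File path.
#' @return `read_leaflet_cloud` returns a data.frame usable by
#'   [split_leaflets()] and [fit_gaussian_surface()].
#' @export
write_leaflet_cloud <- function(cloud, path) {
  pts <- if (inherits(cloud, "leaflet_cloud")) cloud$points else cloud
  write.csv(pts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_leaflet_cloud
#' @export
read_leaflet_cloud <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write umbrella windows as long-format TSV
#'
#' Columns: window_id, center, k, sample (one row per retained sample).
#'
#' @param dataset An `umbrella_dataset`.
#' @param path File path.
#' @param temperature Temperature in K attached on read.
#' @return `read_umbrella_windows` returns an `umbrella_dataset` (without
#'   a truth function).
#' @export
write_umbrella_windows <- function(dataset, path) {
  rows <- do.call(rbind, lapply(seq_along(dataset$windows), function(i) {
    w <- dataset$windows[[i]]
    data.frame(window_id = i, center = w$center, k = w$k,
               sample = w$samples)
  }))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_umbrella_windows
#' @export
read_umbrella_windows <- function(path, temperature = 300) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  windows <- lapply(split(tab, tab$window_id), function(d) {
    list(center = d$center[1], k = d$k[1], samples = d$sample)
  })
  cen <- vapply(windows, `[[`, numeric(1), "center")
  structure(list(windows = unname(windows[order(cen)]),
                 temperature = temperature, truth = NULL),
            class = "umbrella_dataset")
}

#' Read and write PMF profiles as TSV
#'
#' Columns: z, W, sd.
#'
#' @param profile A `pmf_profile`.
#' @param path File path.
#' @param temperature Temperature in K attached on read.
#' @return `read_pmf` returns a `pmf_profile`.
#' @export
write_pmf <- function(profile, path) {
  write.table(data.frame(z = profile$z, W = profile$W, sd = profile$sd),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path, temperature = 300) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(z = tab$z, W = tab$W, sd = tab$sd,
                 temperature = temperature,
                 reference = list(type = "as-read"),
                 convergence = NULL),
            class = "pmf_profile")
}

#' Read and write vesicle annotation tables as TSV
#'
#' Columns: rod, attachment, internal_location, n_tubes, n_discs.
#'
#' @param table A `vesicle_table`.
#' @param path File path.
#' @return `read_vesicle_table` returns a `vesicle_table`.
#' @export
write_vesicle_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_vesicle_table
#' @export
read_vesicle_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  structure(tab, class = c("vesicle_table", "data.frame"))
}
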