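# Constant-arc helical lattice model for protein rod assemblies: the
# Bessel order n of the ~110 A layer line equals the number of subunits in
# one circumferential rung, so at fixed per-subunit arc length s the rod
# diameter is D = n s / pi and inserting one subunit widens the rod by
# D / n (about 20 A for the narrowest 200 A, n = 10 class).

#' Helical lattice geometry from one rung
#'
#' Given a rod diameter and the Bessel order (subunits per rung), computes
#' the per-subunit arc length s = pi D / n and the diameter increment
#' produced by inserting one subunit at constant arc, Delta D = s / pi =
#' D / n.
#'
#' @param diameter Rod diameter in Angstrom (> 0).
#' @param n Subunits per rung (Bessel order), integer >= 1.
#' @param rung_spacing Axial rung repeat in Angstrom (default 110); layer-
#'   line metadata only, it does not enter the diameter arithmetic.
#' @return A `helical_lattice`: list with `n`, `diameter`, `rung_spacing`,
#'   `arc` (s, Angstrom) and `diameter_step` (Delta D, Angstrom).
#' @export
#' @examples
#' lattice_from_rung(200, 10)  # arc 62.83 A, step 20 A
lattice_from_rung <- function(diameter, n, rung_spacing = 110) {
  check_positive(diameter, "diameter")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  check_positive(rung_spacing, "rung_spacing")
  structure(list(n = as.integer(n), diameter = diameter,
                 rung_spacing = rung_spacing,
                 arc = pi * diameter / n,
                 diameter_step = diameter / n),
            class = "helical_lattice")
}

#' @export
print.helical_lattice <- function(x, ...) {
  cat(sprintf("Helical lattice: n = %d subunits/rung, D = %.4g A, rung spacing %.4g A\n",
              x$n, x$diameter, x$rung_spacing))
  cat(sprintf("  subunit arc s = %.4g A, diameter step D/n = %.4g A\n",
              x$arc, x$diameter_step))
  invisible(x)
}

#' Predict rod diameter from Bessel order at constant subunit arc
#'
#' Inverse of [lattice_from_rung()]: D = n s / pi. The constant-arc model
#' predicts the observed diameter series only approximately (the measured
#' arc shrinks from about 62.8 to 60.2 A between the n = 10 and n = 18
#' classes), so deviations from measured diameters are expected at the
#' 5-15 A level and should be reported, not assumed away.
#'
#' @param n Subunits per rung (vectorized), >= 1.
#' @param subunit_arc Per-subunit arc length s in Angstrom (> 0).
#' @return Predicted diameter(s) in Angstrom.
#' @export
#' @examples
#' predict_diameter(10:18, pi * 200 / 10)
predict_diameter <- function(n, subunit_arc) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  check_positive(subunit_arc, "subunit_arc")
  n * subunit_arc / pi
}

#' Classify measured rod diameters into diameter classes
#'
#' Assigns each measured segment diameter to the nearest class centre
#' (exact midpoints go to the lower class, for determinism) and tabulates
#' counts and relative occurrence, the per-class histogram underlying rod
#' diameter distributions.
#'
#' @param measurements Numeric vector of measured diameters, Angstrom.
#' @param class_centers Strictly increasing class centres, Angstrom.
#' @return A `diameter_histogram`: data.frame (center, count, fraction);
#'   fractions sum to 1 for nonempty input.
#' @export
#' @examples
#' classify_rod_diameters(c(201, 214, 299, 341),
#'                        c(200, 215, 235, 250, 270, 280, 290, 305, 320, 345))
classify_rod_diameters <- function(measurements, class_centers) {
  if (length(class_centers) == 0L) {
    stop("`class_centers` must be nonempty", call. = FALSE)
  }
  if (is.unsorted(class_centers, strictly = TRUE)) {
    stop("`class_centers` must be strictly increasing", call. = FALSE)
  }
  n_cl <- length(class_centers)
  if (n_cl == 1L) {
    idx <- rep(1L, length(measurements))
  } else {
    midpoints <- (head(class_centers, -1) + tail(class_centers, -1)) / 2
    # left-open intervals: a value exactly at a midpoint stays in the
    # lower class
    idx <- findInterval(measurements, midpoints, left.open = TRUE) + 1L
  }
  counts <- tabulate(idx, nbins = n_cl)
  total <- sum(counts)
  structure(data.frame(center = class_centers, count = counts,
                       fraction = if (total > 0) counts / total
                                  else rep(NA_real_, n_cl)),
            class = c("diameter_histogram", "data.frame"))
}
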