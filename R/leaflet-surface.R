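# Leaflet assignment, 2D Gaussian ("bell curve") surface fitting, and
# component density profiles along the membrane normal.

new_gaussian_surface_fit <- function(amplitude, sigma_x, sigma_y, x0, y0,
                                     z0, leaflet = NA_character_, rms, n,
                                     flat = FALSE, converged = TRUE,
                                     iterations = NA_integer_) {
  structure(list(amplitude = amplitude, sigma_x = sigma_x,
                 sigma_y = sigma_y, x0 = x0, y0 = y0, z0 = z0,
                 leaflet = leaflet, rms = rms, n = n, flat = flat,
                 converged = converged, iterations = iterations),
            class = "gaussian_surface_fit")
}

#' @export
print.gaussian_surface_fit <- function(x, ...) {
  cat("2D Gaussian surface fit",
      if (!is.na(x$leaflet)) sprintf("(%s leaflet)", x$leaflet), "\n")
  cat(sprintf("  amplitude %.4g A, sigma (%.4g, %.4g) A, centre (%.4g, %.4g), baseline %.4g A\n",
              x$amplitude, x$sigma_x, x$sigma_y, x$x0, x$y0, x$z0))
  cat(sprintf("  rms residual %.4g A over %d points%s\n", x$rms, x$n,
              if (isTRUE(x$flat)) " [flat]" else ""))
  invisible(x)
}

# height of the fitted surface at (x, y)
surface_height <- function(fit, x, y) {
  fit$z0 + fit$amplitude *
    exp(-((x - fit$x0)^2 / (2 * fit$sigma_x^2) +
            (y - fit$y0)^2 / (2 * fit$sigma_y^2)))
}

#' @export
predict.gaussian_surface_fit <- function(object, x, y, ...) {
  surface_height(object, x, y)
}

#' Split a point cloud into upper and lower leaflets
#'
#' Generator labels, when present, are honoured. Unlabelled points are
#' split at the median z, then reassigned once to whichever fitted leaflet
#' surface is vertically nearer; points equidistant from both surfaces (or
#' exactly at the midplane) go to the lower leaflet for determinism.
#'
#' @param cloud A [gen_leaflet_cloud()] result, or a data.frame with
#'   columns x, y, z and optionally leaflet.
#' @return List with data.frames `upper` and `lower`.
#' @export
split_leaflets <- function(cloud) {
  pts <- if (inherits(cloud, "leaflet_cloud")) cloud$points else cloud
  if (nrow(pts) == 0L) stop("empty point cloud", call. = FALSE)
  if (!is.null(pts$leaflet) && !anyNA(pts$leaflet)) {
    return(list(upper = pts[pts$leaflet == "upper", , drop = FALSE],
                lower = pts[pts$leaflet == "lower", , drop = FALSE]))
  }
  if (diff(range(pts$z)) < .Machine$double.eps^0.5) {
    stop("cannot separate leaflets: all points coplanar", call. = FALSE)
  }
  # initial split at the local midplane: a global median fails when the
  # bump height exceeds the bilayer thickness, so the median is taken per
  # xy cell
  nx <- max(1L, min(8L, floor(sqrt(nrow(pts) / 40))))
  ix <- cut(pts$x, nx, labels = FALSE)
  iy <- cut(pts$y, nx, labels = FALSE)
  cell <- (ix - 1L) * nx + iy
  up <- logical(nrow(pts))
  for (cl in unique(cell)) {
    sel <- cell == cl
    up[sel] <- pts$z[sel] > median(pts$z[sel])
  }
  if (!any(up) || all(up)) {
    stop("cannot separate leaflets: degenerate z distribution",
         call. = FALSE)
  }
  # one refinement round against fitted surfaces
  fit_up <- try(fit_gaussian_surface(pts[up, ], leaflet = "upper"),
                silent = TRUE)
  fit_lo <- try(fit_gaussian_surface(pts[!up, ], leaflet = "lower"),
                silent = TRUE)
  if (!inherits(fit_up, "try-error") && !inherits(fit_lo, "try-error")) {
    d_up <- abs(pts$z - surface_height(fit_up, pts$x, pts$y))
    d_lo <- abs(pts$z - surface_height(fit_lo, pts$x, pts$y))
    up <- d_up < d_lo  # ties go to the lower leaflet
  }
  list(upper = pts[up, , drop = FALSE], lower = pts[!up, , drop = FALSE])
}

#' Fit a 2D Gaussian surface to leaflet marker points
#'
#' Nonlinear least squares of z over (A, sigma, x0, y0, z0) for the model
#' z = z0 + A exp(-((x - x0)^2 / (2 sigma_x^2) + (y - y0)^2 / (2 sigma_y^2))),
#' the smooth bell-curve representation of a leaflet deformed by a protein
#' adhesion (local fluctuation curvature is deliberately averaged away).
#' By default one isotropic width is fitted, matching the downstream
#' height-by-width energy maps; set `isotropic = FALSE` for independent
#' sigma_x, sigma_y.
#'
#' @param points Data.frame or matrix with columns/names x, y, z; at least
#'   6 points (the parameter count).
#' @param isotropic Fit a single width for both axes (default TRUE).
#' @param start Optional named list of starting values (A, sigma, x0, y0,
#'   z0); otherwise a robust guess is built from the data (baseline at the
#'   median z, centre at the extreme point, width from the half-height
#'   extent).
#' @param lower,upper Optional named parameter bounds (names among A,
#'   sigma, sx, sy, x0, y0, z0) passed to the optimizer; useful when the
#'   data only weakly constrain the amplitude-width ridge (e.g. nearly
#'   paraboloidal caps).
#' @param leaflet Optional leaflet tag stored in the result.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A `gaussian_surface_fit`. Degenerate flat input returns
#'   amplitude 0 with the `flat` flag set; a fit whose amplitude is below
#'   the noise floor (3 residual SD / sqrt(n)) is also flagged flat.
#'   Non-convergence is an error carrying the last iterate.
#' @export
#' @examples
#' cl <- gen_leaflet_cloud(150, 50, n_points = 2000, noise_sd = 0, seed = 1)
#' fit_gaussian_surface(split_leaflets(cl)$upper)
fit_gaussian_surface <- function(points, isotropic = TRUE, start = NULL,
                                 lower = NULL, upper = NULL,
                                 leaflet = NA_character_, max_iter = 200) {
  pts <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z") %in% names(pts)))
  n <- nrow(pts)
  if (n < 6L) stop("need at least 6 points to fit 6 parameters",
                   call. = FALSE)
  x <- pts$x; y <- pts$y; z <- pts$z

  z0_init <- median(z)
  dev_hi <- max(z) - z0_init
  dev_lo <- min(z) - z0_init
  a_init <- if (abs(dev_hi) >= abs(dev_lo)) dev_hi else dev_lo
  i_pk <- if (a_init >= 0) which.max(z) else which.min(z)
  # width guess: rms xy-distance of points beyond half height from the peak
  half <- abs(z - z0_init) > abs(a_init) / 2
  s_init <- if (sum(half) > 3) {
    sqrt(mean((x[half] - x[i_pk])^2 + (y[half] - y[i_pk])^2)) / 1.18
  } else {
    (diff(range(x)) + diff(range(y))) / 8
  }
  s_init <- max(s_init, .Machine$double.eps^0.25)

  flat_fit <- function(rms) {
    new_gaussian_surface_fit(amplitude = 0, sigma_x = s_init,
                             sigma_y = s_init, x0 = mean(x), y0 = mean(y),
                             z0 = mean(z), leaflet = leaflet, rms = rms,
                             n = n, flat = TRUE, converged = TRUE)
  }
  if (diff(range(z)) < .Machine$double.eps^0.5) {
    return(flat_fit(rms = sd(z)))
  }

  if (is.null(start)) {
    start <- list(A = a_init, sigma = s_init, x0 = x[i_pk], y0 = y[i_pk],
                  z0 = z0_init)
  }
  dat <- data.frame(x = x, y = y, z = z)
  start_list <- if (isotropic) {
    list(A = start$A, sigma = start$sigma, x0 = start$x0, y0 = start$y0,
         z0 = start$z0)
  } else {
    list(A = start$A, sx = start$sigma, sy = start$sigma, x0 = start$x0,
         y0 = start$y0, z0 = start$z0)
  }
  par_names <- names(start_list)
  bound_vec <- function(b, default) {
    out <- rep(default, length(par_names))
    names(out) <- par_names
    if (!is.null(b)) out[names(b)] <- b
    # clamp starting values into the bounds
    out
  }
  lo <- bound_vec(lower, -Inf)
  hi <- bound_vec(upper, Inf)
  start_list <- as.list(pmin(pmax(unlist(start_list), lo), hi))
  form <- if (isotropic) {
    z ~ z0 + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))
  } else {
    z ~ z0 + A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2)))
  }
  fit <- try(minpack.lm::nlsLM(
    form, data = dat, start = start_list, lower = lo, upper = hi,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         maxfev = 100 * max_iter)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    # near-flat noisy data commonly defeats the optimizer; report it as flat
    resid_sd <- sd(z - median(z))
    if (abs(a_init) < 3 * resid_sd) return(flat_fit(rms = resid_sd))
    stop("surface fit failed: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo
  if (!isTRUE(conv$isConv)) {
    stop(sprintf(paste0("surface fit did not converge after %d iterations; ",
                        "last iterate: %s"),
                 conv$finIter,
                 paste(sprintf("%s=%.6g", names(cf), cf), collapse = ", ")),
         call. = FALSE)
  }
  rms <- sqrt(mean(stats::residuals(fit)^2))
  # degenerate near-flat data can converge to a huge-amplitude, huge-width
  # surface indistinguishable from a baseline shift; no explained variance
  # means there is no bump to report
  if (1 - rms^2 / stats::var(z) < 0.01) return(flat_fit(rms = sd(z)))
  sx <- abs(if (isotropic) cf[["sigma"]] else cf[["sx"]])
  sy <- abs(if (isotropic) cf[["sigma"]] else cf[["sy"]])
  out <- new_gaussian_surface_fit(
    amplitude = cf[["A"]], sigma_x = sx, sigma_y = sy,
    x0 = cf[["x0"]], y0 = cf[["y0"]], z0 = cf[["z0"]], leaflet = leaflet,
    rms = rms, n = n, flat = FALSE, converged = TRUE,
    iterations = conv$finIter)
  if (abs(out$amplitude) < 3 * rms / sqrt(n)) out$flat <- TRUE
  out
}

#' Component density profile along the membrane normal
#'
#' Histograms labelled coordinates along z and divides by the bin volume
#' (box area x bin width) to give number densities per component, the
#' standard electron-density-style profile showing the water, headgroup and
#' acyl-chain regions of a bilayer. A summed "LIP" component over all lipid
#' labels is appended.
#'
#' @param coords Data.frame with columns `z` and `component`.
#' @param bin_width Bin width in Angstrom (> 0).
#' @param box_area Box cross-section area in Angstrom^2 used for the bin
#'   volume.
#' @param weights Optional named per-component weights (e.g. electrons per
#'   bead); unweighted counts otherwise.
#' @param water_label Label excluded from the lipid sum (default "WAT").
#' @param lipid_components Labels summed into "LIP"; default every
#'   component except `water_label`.
#' @return A `density_profile`: list with `z` (bin centres), `density`
#'   (matrix bins x components, including LIP), `bin_width`, `box_area`.
#' @export
density_profile <- function(coords, bin_width = 1, box_area = 1,
                            weights = NULL, water_label = "WAT",
                            lipid_components = NULL) {
  check_positive(bin_width, "bin_width")
  check_positive(box_area, "box_area")
  coords <- as.data.frame(coords)
  if (nrow(coords) == 0L) stop("empty input", call. = FALSE)
  stopifnot(all(c("z", "component") %in% names(coords)))
  comps <- unique(as.character(coords$component))
  if (is.null(lipid_components)) {
    lipid_components <- setdiff(comps, water_label)
  }
  lo <- floor(min(coords$z) / bin_width) * bin_width
  hi <- ceiling(max(coords$z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  centers <- head(breaks, -1) + bin_width / 2
  vol <- box_area * bin_width
  dens <- sapply(comps, function(cmp) {
    zc <- coords$z[coords$component == cmp]
    h <- hist(zc, breaks = breaks, plot = FALSE, right = FALSE)$counts
    w <- if (!is.null(weights) && cmp %in% names(weights)) weights[[cmp]] else 1
    h * w / vol
  })
  dens <- matrix(dens, nrow = length(centers),
                 dimnames = list(NULL, comps))
  lip <- rowSums(dens[, lipid_components, drop = FALSE])
  dens <- cbind(dens, LIP = lip)
  structure(list(z = centers, density = dens, bin_width = bin_width,
                 box_area = box_area, lipid_components = lipid_components),
            class = "density_profile")
}
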