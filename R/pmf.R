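# Potential of mean force from umbrella-sampling windows (WHAM), its
# integration to a standard binding free energy, and Jarzynski work-average
# replica selection for adaptive steered-MD protocols.

#' Estimate a PMF from umbrella windows by WHAM
#'
#' Binned, self-consistent weighted-histogram analysis: window free-energy
#' shifts f_i are iterated until the maximum change falls below
#' `tolerance`, and the unbiased probability is converted to
#' W(z) = -k_B T ln p(z). The profile is re-referenced so that the mean
#' over the unbound plateau (the high-z tail of the sampled range) is zero,
#' matching the convention of quoting binding profiles relative to the
#' unbound state.
#'
#' @param dataset An `umbrella_dataset` (see [gen_umbrella_dataset()]) or a
#'   list with `windows` (each with `center`, `k`, `samples`) and
#'   `temperature`.
#' @param n_bins Number of histogram bins spanning all samples.
#' @param tolerance Convergence tolerance on the window free energies,
#'   kcal mol^-1.
#' @param max_iterations Iteration cap; exceeding it is an error carrying
#'   the convergence trace.
#' @param reference "plateau" (default) zeroes the mean over the top
#'   `plateau_fraction` of the z range; "min" zeroes the minimum; "none"
#'   leaves the raw -k_B T ln p.
#' @param plateau_fraction Fraction of the sampled z range treated as the
#'   unbound plateau.
#' @param trim Report only bins between the outermost window centres
#'   (default TRUE); beyond them the coordinate is unrestrained and the
#'   profile is tail extrapolation.
#' @param min_count Minimum total histogram count for a bin to be reported;
#'   bins sampled only by the far tails of the outermost windows carry
#'   essentially unbounded noise in -k_B T ln p and are dropped (default
#'   10).
#' @param n_boot Bootstrap replicates (resampling within windows) for the
#'   per-bin SD; 0 (default) skips the bootstrap and reports NA.
#' @return A `pmf_profile`: list with `z` (bin centres with data), `W`,
#'   `sd`, `reference` info, `window_f` (converged shifts), and
#'   `convergence` (iterations, final max change).
#' @export
wham_pmf <- function(dataset, n_bins = 200, tolerance = 1e-7,
                     max_iterations = 50000,
                     reference = c("plateau", "min", "none"),
                     plateau_fraction = 0.2, trim = TRUE, min_count = 10,
                     n_boot = 0) {
  reference <- match.arg(reference)
  windows <- dataset$windows
  if (length(windows) < 2L) {
    stop("need at least 2 umbrella windows", call. = FALSE)
  }
  temperature <- if (!is.null(dataset$temperature)) dataset$temperature else 300
  kT <- kBT(temperature)

  cen <- vapply(windows, `[[`, numeric(1), "center")
  windows <- windows[order(cen)]
  cen <- sort(cen)
  # adjacent windows must share reaction-coordinate support
  for (i in seq_len(length(windows) - 1L)) {
    if (max(windows[[i]]$samples) < min(windows[[i + 1L]]$samples)) {
      stop(sprintf(paste0("no histogram overlap between windows centred at ",
                          "%.3g and %.3g Angstrom"),
                   cen[i], cen[i + 1L]), call. = FALSE)
    }
  }

  all_z <- unlist(lapply(windows, `[[`, "samples"))
  breaks <- seq(min(all_z), max(all_z), length.out = n_bins + 1L)
  mids <- head(breaks, -1) + diff(breaks) / 2

  run_wham <- function(wins) {
    H <- vapply(wins, function(w) {
      hist(w$samples, breaks = breaks, plot = FALSE,
           include.lowest = TRUE)$counts
    }, numeric(n_bins))                         # bins x windows
    N <- colSums(H)
    n_tot <- rowSums(H)
    bias <- vapply(wins, function(w) w$k / 2 * (mids - w$center)^2,
                   numeric(n_bins))             # bins x windows
    expb <- exp(-bias / kT)
    f <- numeric(length(wins))
    trace <- numeric(0)
    for (it in seq_len(max_iterations)) {
      denom <- as.vector(expb %*% (N * exp(f / kT)))
      p <- ifelse(denom > 0, n_tot / denom, 0)
      f_new <- -kT * log(as.vector(t(expb) %*% p))
      f_new <- f_new - f_new[1]
      delta <- max(abs(f_new - f))
      f <- f_new
      if (it <= 50 || it %% 100 == 0) trace <- c(trace, delta)
      if (delta < tolerance) {
        return(list(p = p, f = f, n_tot = n_tot, iterations = it,
                    delta = delta))
      }
    }
    stop(sprintf(paste0("WHAM did not converge in %d iterations ",
                        "(last max change %.3g, trace tail: %s)"),
                 max_iterations, delta,
                 paste(signif(tail(trace, 5), 3), collapse = ", ")),
         call. = FALSE)
  }

  sol <- run_wham(windows)
  keep <- sol$p > 0 & sol$n_tot >= min_count
  if (trim) keep <- keep & mids >= min(cen) & mids <= max(cen)
  z <- mids[keep]
  W <- -kT * log(sol$p[keep])

  ref_value <- 0
  plateau_lo <- NA_real_
  if (reference == "plateau") {
    plateau_lo <- max(z) - plateau_fraction * diff(range(z))
    ref_value <- mean(W[z >= plateau_lo])
  } else if (reference == "min") {
    ref_value <- min(W)
  }
  W <- W - ref_value

  sd_W <- rep(NA_real_, length(W))
  if (n_boot > 0) {
    boots <- replicate(n_boot, {
      wins_b <- lapply(windows, function(w) {
        w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
        w
      })
      sol_b <- run_wham(wins_b)
      Wb <- rep(NA_real_, n_bins)
      kb <- sol_b$p > 0
      Wb[kb] <- -kT * log(sol_b$p[kb])
      if (reference == "plateau") {
        Wb <- Wb - mean(Wb[mids >= plateau_lo], na.rm = TRUE)
      } else if (reference == "min") {
        Wb <- Wb - min(Wb, na.rm = TRUE)
      }
      Wb
    })
    sd_W <- apply(boots[keep, , drop = FALSE], 1, sd, na.rm = TRUE)
  }

  structure(list(z = z, W = W, sd = sd_W, temperature = temperature,
                 reference = list(type = reference,
                                  plateau_z_min = plateau_lo,
                                  offset = ref_value),
                 window_f = sol$f,
                 convergence = list(iterations = sol$iterations,
                                    max_delta = sol$delta)),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF: %d bins, z in [%.3g, %.3g] A, min W = %.3g kcal/mol (reference: %s)\n",
              length(x$z), min(x$z), max(x$z), min(x$W), x$reference$type))
  cat(sprintf("  WHAM converged in %d iterations (max change %.2g)\n",
              x$convergence$iterations, x$convergence$max_delta))
  invisible(x)
}

#' Cumulative integral of a PMF along the reaction coordinate
#'
#' Trapezoidal cumulative integral of W(z), used to localize where along
#' the membrane normal the energetic contribution to (un)binding accrues
#' (for the alpha0 peptide, mostly below 30 Angstrom from the membrane
#' centre).
#'
#' @param profile A `pmf_profile` (or list with `z`, `W`).
#' @param from_unbound Integrate from the high-z (unbound) end downwards
#'   instead of from low z upwards.
#' @return Data.frame (z, cumulative) in kcal mol^-1 Angstrom.
#' @export
cumulative_pmf <- function(profile, from_unbound = FALSE) {
  z <- profile$z
  W <- profile$W
  ok <- is.finite(W)
  z <- z[ok]; W <- W[ok]
  if (from_unbound) {
    cum <- rev(-pracma::cumtrapz(rev(z), rev(W))[, 1])
  } else {
    cum <- pracma::cumtrapz(z, W)[, 1]
  }
  data.frame(z = z, cumulative = cum)
}

#' Standard binding free energy from a PMF
#'
#' Integrates the Boltzmann factor of the PMF over the bound region and
#' converts to the 1 M standard state:
#' dG0 = -k_B T ln\[(A / V0) * integral over bound z of exp(-W(z)/k_B T) dz\]
#' + entropy correction, where A is the sampled cross-sectional area and
#' V0 the standard-state volume (1661 A^3). The bound region is the set of
#' z with W(z) below `bound_threshold` (default 0 relative to the unbound
#' plateau); configurational/conformational entropy loss on binding enters
#' as an explicit additive term so any chosen correction stays auditable in
#' the component breakdown.
#'
#' @param profile A `pmf_profile` referenced to the unbound plateau.
#' @param sampled_area Cross-sectional area A in Angstrom^2 sampled by the
#'   unbound peptide (e.g. the simulation box area).
#' @param standard_volume Standard-state volume in Angstrom^3, default 1661.
#' @param entropy_correction Additive correction in kcal mol^-1 (default 0).
#' @param temperature Temperature in K.
#' @param bound_threshold Bound-region cutoff on W in kcal mol^-1; use
#'   `Inf` to integrate the whole profile.
#' @return A `binding_free_energy`: `dG_standard` plus its components
#'   (`pmf_integral`, `volume_term`, `entropy_correction`), which sum to
#'   the total.
#' @export
standard_binding_dg <- function(profile, sampled_area,
                                standard_volume = 1661,
                                entropy_correction = 0, temperature = 300,
                                bound_threshold = 0) {
  check_positive(sampled_area, "sampled_area")
  check_positive(standard_volume, "standard_volume")
  kT <- kBT(temperature)
  z <- profile$z
  W <- profile$W
  ok <- is.finite(W)
  z <- z[ok]; W <- W[ok]
  bound <- W < bound_threshold
  if (!any(bound)) stop("no bound state: W never falls below threshold",
                        call. = FALSE)
  # integrate each contiguous bound stretch separately (no bridging gaps)
  runs <- rle(bound)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  I <- 0
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    if (length(idx) >= 2L) {
      I <- I + pracma::trapz(z[idx], exp(-W[idx] / kT))
    }
  }
  if (I <= 0) stop("bound region too narrow to integrate", call. = FALSE)
  pmf_integral <- -kT * log(I)
  volume_term <- -kT * log(sampled_area / standard_volume)
  dG <- pmf_integral + volume_term + entropy_correction
  structure(list(dG_standard = dG,
                 components = c(pmf_integral = pmf_integral,
                                volume_term = volume_term,
                                entropy_correction = entropy_correction),
                 temperature = temperature,
                 standard_volume = standard_volume,
                 sampled_area = sampled_area,
                 bound_threshold = bound_threshold,
                 bound_width = sum(bound) * mean(diff(z))),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("Standard binding free energy: dG0 = %.3f kcal/mol\n",
              x$dG_standard))
  cat(sprintf("  PMF integral %.3f + volume term %.3f + entropy correction %.3f\n",
              x$components[["pmf_integral"]], x$components[["volume_term"]],
              x$components[["entropy_correction"]]))
  invisible(x)
}

#' Jarzynski work average and replica selection
#'
#' Computes the Jarzynski free-energy estimate
#' F = -k_B T ln mean(exp(-W_i / k_B T)) over replica work values and
#' selects the replica whose work is closest to F, the restart-structure
#' rule used in adaptive steered-MD iterations. Ties go to the lowest
#' replica index. By Jensen's inequality F never exceeds the arithmetic
#' mean of the works.
#'
#' @param works Numeric vector of per-replica work values, kcal mol^-1
#'   (nonempty).
#' @param temperature Temperature in K.
#' @return List with `free_energy` (kcal mol^-1) and `index` (selected
#'   replica).
#' @export
#' @examples
#' jarzynski_select(c(0, 1))  # F = -0.596 * log((1 + exp(-1/0.596)) / 2)
jarzynski_select <- function(works, temperature = 300) {
  if (length(works) == 0L || any(!is.finite(works))) {
    stop("`works` must be a nonempty vector of finite work values",
         call. = FALSE)
  }
  kT <- kBT(temperature)
  F <- -kT * (logsumexp(-works / kT) - log(length(works)))
  list(free_energy = F, index = which.min(abs(works - F)))
}
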