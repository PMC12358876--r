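# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised against these, with the generating parameters kept as ground
# truth, so no molecular dynamics or cryo-EM raw data is needed for testing.

#' Generate a two-leaflet membrane marker point cloud
#'
#' Emulates leaflet marker points (phosphate-plane positions) read from
#' simulation frames of a bilayer deformed by a protein adhesion: a flat
#' bilayer of constant thickness whose two leaflets are both displaced by a
#' radially symmetric Gaussian bump, plus independent Gaussian positional
#' noise along the membrane normal. The membrane midplane is at z = 0 and
#' the bump is centred in the box.
#'
#' @param amplitude Bump height A in Angstrom (>= 0). `amplitude = 0`
#'   produces two flat planes separated by `thickness`.
#' @param sigma Bump width (standard deviation of the Gaussian, per axis) in
#'   Angstrom. Must be positive.
#' @param thickness Bilayer thickness in Angstrom; default 34, the constant
#'   thickness measured for membrane tubules inside PspA rods.
#' @param box Numeric length-2: box extents (Lx, Ly) in Angstrom. Default
#'   426.6 x 426.6, the lateral box of the coarse-grained rod system.
#' @param n_points Number of marker points per leaflet (>= 1).
#' @param noise_sd Standard deviation in Angstrom of Gaussian noise added to
#'   z only; xy positions are uniform in the box.
#' @param seed Optional integer seed; for a fixed seed the cloud is
#'   bit-reproducible and the caller's RNG state is left untouched.
#' @return A `leaflet_cloud`: list with `points` (data.frame x, y, z,
#'   leaflet), `box`, and `truth` (the generating surfaces as
#'   [gaussian_surface_fit] objects plus `noise_sd`).
#' @export
#' @examples
#' cl <- gen_leaflet_cloud(150, 50, n_points = 1000, noise_sd = 2, seed = 1)
#' range(cl$points$z)
gen_leaflet_cloud <- function(amplitude, sigma, thickness = 34,
                              box = c(426.6, 426.6), n_points,
                              noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  check_positive(sigma, "sigma")
  check_positive(thickness, "thickness")
  stopifnot(length(box) == 2L)
  check_positive(box, "box")
  stopifnot(is.numeric(n_points), length(n_points) == 1L, n_points >= 1)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)

  x0 <- box[1] / 2
  y0 <- box[2] / 2
  bump <- function(x, y) {
    amplitude * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2))
  }

  pts <- with_local_seed(seed, {
    one_leaflet <- function(z_base, label) {
      x <- runif(n_points, 0, box[1])
      y <- runif(n_points, 0, box[2])
      z <- z_base + bump(x, y)
      if (noise_sd > 0) z <- z + rnorm(n_points, 0, noise_sd)
      data.frame(x = x, y = y, z = z, leaflet = label,
                 stringsAsFactors = FALSE)
    }
    rbind(one_leaflet(thickness / 2, "upper"),
          one_leaflet(-thickness / 2, "lower"))
  })

  truth_fit <- function(z0, label) {
    new_gaussian_surface_fit(amplitude = amplitude, sigma_x = sigma,
                             sigma_y = sigma, x0 = x0, y0 = y0, z0 = z0,
                             leaflet = label, rms = 0, n = n_points,
                             flat = amplitude == 0, converged = TRUE)
  }
  structure(
    list(points = pts, box = box,
         truth = list(upper = truth_fit(thickness / 2, "upper"),
                      lower = truth_fit(-thickness / 2, "lower"),
                      noise_sd = noise_sd)),
    class = "leaflet_cloud")
}

#' @export
print.leaflet_cloud <- function(x, ...) {
  cat(sprintf("Leaflet point cloud: %d points (%d per leaflet), box %.1f x %.1f A\n",
              nrow(x$points), nrow(x$points) / 2L, x$box[1], x$box[2]))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: A = %.3g A, sigma = %.3g A, noise sd = %.3g A\n",
                x$truth$upper$amplitude, x$truth$upper$sigma_x,
                x$truth$noise_sd))
  }
  invisible(x)
}

#' Generate harmonically biased umbrella-sampling windows from a known PMF
#'
#' Draws reaction-coordinate samples for each umbrella window from the
#' biased density proportional to exp(-(W(z) + k/2 (z - z_i)^2) / k_B T)
#' by Metropolis sampling with burn-in and chain thinning. The true PMF is
#' retained as ground truth so WHAM recovery can be tested.
#'
#' @param true_pmf Function of z (Angstrom) returning the unbiased free
#'   energy W(z) in kcal mol^-1. Must be finite wherever the biased density
#'   has appreciable mass.
#' @param centers Umbrella window centres z_i in Angstrom (nonempty; stored
#'   sorted ascending).
#' @param spring_k Harmonic spring constant(s) in kcal mol^-1 A^-2; scalar
#'   or one per window. Must be positive.
#' @param n_samples Retained samples per window (>= 1).
#' @param temperature Temperature in K (default 300).
#' @param seed Optional integer seed for reproducibility.
#' @param burn_in Discarded initial Metropolis steps per window.
#' @param thin Keep every `thin`-th step after burn-in; thinning reduces the
#'   autocorrelation that would otherwise bias WHAM error estimates.
#' @param proposal_sd Random-walk proposal width; default
#'   `sqrt(kBT(temperature) / spring_k)`, the width of the bias alone.
#' @return An `umbrella_dataset`: list with `windows` (each a list with
#'   `center`, `k`, `samples`), `temperature`, and `truth` (the PMF
#'   function).
#' @export
gen_umbrella_dataset <- function(true_pmf, centers, spring_k, n_samples,
                                 temperature = 300, seed = NULL,
                                 burn_in = 1000, thin = 10,
                                 proposal_sd = NULL) {
  stopifnot(is.function(true_pmf))
  if (length(centers) < 1L) stop("`centers` must be nonempty", call. = FALSE)
  check_positive(spring_k, "spring_k")
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("`n_samples` must be >= 1", call. = FALSE)
  }
  kT <- kBT(temperature)
  ord <- order(centers)
  spring_k <- rep_len(spring_k, length(centers))[ord]
  centers <- centers[ord]

  windows <- with_local_seed(seed, {
    lapply(seq_along(centers), function(i) {
      z_i <- centers[i]
      k_i <- spring_k[i]
      psd <- if (is.null(proposal_sd)) sqrt(kT / k_i) else proposal_sd
      # reject PMFs that make the biased density unnormalizable
      probe <- true_pmf(seq(z_i - 8 * psd, z_i + 8 * psd, length.out = 33))
      if (any(!is.finite(probe))) {
        stop("`true_pmf` is not finite near window centre ", z_i,
             "; biased density is unnormalizable", call. = FALSE)
      }
      log_dens <- function(z) -(true_pmf(z) + k_i / 2 * (z - z_i)^2) / kT
      n_steps <- burn_in + n_samples * thin
      prop <- rnorm(n_steps, 0, psd)
      logu <- log(runif(n_steps))
      z <- z_i
      ld <- log_dens(z)
      keep <- numeric(n_samples)
      kept <- 0L
      for (s in seq_len(n_steps)) {
        z_new <- z + prop[s]
        ld_new <- log_dens(z_new)
        if (is.finite(ld_new) && logu[s] < ld_new - ld) {
          z <- z_new
          ld <- ld_new
        }
        if (s > burn_in && (s - burn_in) %% thin == 0L) {
          kept <- kept + 1L
          keep[kept] <- z
        }
      }
      list(center = z_i, k = k_i, samples = keep)
    })
  })
  structure(list(windows = windows, temperature = temperature,
                 truth = true_pmf),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  cen <- vapply(x$windows, `[[`, numeric(1), "center")
  n <- vapply(x$windows, function(w) length(w$samples), integer(1))
  cat(sprintf("Umbrella dataset: %d windows, centres %.1f..%.1f A, %d samples/window, T = %g K\n",
              length(cen), min(cen), max(cen), n[1], x$temperature))
  invisible(x)
}

#' Generate an ideal helical rod assembly
#'
#' Places subunits on a cylinder: each circumferential rung carries
#' `n_per_rung` equally spaced subunits (the Bessel order of the ~110 A
#' layer line equals the number of subunits per rung), and rungs repeat
#' along the axis at `rung_spacing`.
#'
#' @param n_per_rung Subunits per rung (Bessel order), integer >= 1.
#' @param diameter Rod diameter in Angstrom.
#' @param rung_spacing Axial repeat between rungs in Angstrom (default 110).
#' @param n_rungs Number of rungs.
#' @param rung_twist Angular offset in radians added per rung (0 for an
#'   untwisted stack; negative for a left-handed lattice).
#' @return A `rod_assembly`: list with `positions` (data.frame x, y, z,
#'   rung, subunit), `n_per_rung`, `diameter`, `rung_spacing`.
#' @export
#' @examples
#' rod <- gen_rod_assembly(10, 200, n_rungs = 3)
#' pi * 200 / 10  # nearest-neighbour arc length
gen_rod_assembly <- function(n_per_rung, diameter, rung_spacing = 110,
                             n_rungs = 1, rung_twist = 0) {
  if (!is.numeric(n_per_rung) || n_per_rung < 1) {
    stop("`n_per_rung` must be an integer >= 1", call. = FALSE)
  }
  n_per_rung <- as.integer(n_per_rung)
  check_positive(diameter, "diameter")
  check_positive(rung_spacing, "rung_spacing")
  stopifnot(n_rungs >= 1)
  r <- diameter / 2
  pos <- do.call(rbind, lapply(seq_len(n_rungs), function(j) {
    theta <- 2 * pi * (seq_len(n_per_rung) - 1L) / n_per_rung +
      (j - 1L) * rung_twist
    data.frame(x = r * cos(theta), y = r * sin(theta),
               z = (j - 1L) * rung_spacing,
               rung = j, subunit = seq_len(n_per_rung))
  }))
  structure(list(positions = pos, n_per_rung = n_per_rung,
                 diameter = diameter, rung_spacing = rung_spacing),
            class = "rod_assembly")
}

#' Generate peptide/headgroup coordinate frames with known contact propensities
#'
#' Builds frames in which residue i of an interfacial peptide sits within
#' the contact cutoff of a lipid headgroup bead with probability
#' `contact_propensity[i]` per frame; headgroup bead types follow the lipid
#' composition. Non-contacting residues have no bead within the cutoff, and
#' a layer of background headgroup beads lies far below the peptide, so the
#' realized contact frequency converges to the propensity.
#'
#' @param n_frames Number of frames (>= 1).
#' @param n_residues Number of peptide residues (ids contiguous from 1).
#' @param composition Named numeric of lipid-type fractions (e.g.
#'   `c(PG = 0.25, PE = 0.75)`); must sum to 1 within 1e-9.
#' @param contact_propensity Per-residue contact probability in \[0, 1\];
#'   scalar or length `n_residues`.
#' @param cutoff Contact cutoff in Angstrom used when placing contact beads
#'   (default 6).
#' @param seed Optional integer seed.
#' @return A `contact_frames` object: list with `frames` (each a list with
#'   data.frames `peptide` (residue, x, y, z) and `headgroups` (type, x, y,
#'   z)), `composition`, `cutoff`, and `truth` (the propensities).
#' @export
gen_contact_frames <- function(n_frames, n_residues, composition,
                               contact_propensity, cutoff = 6, seed = NULL) {
  stopifnot(n_frames >= 1, n_residues >= 1)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  if (any(contact_propensity < 0 | contact_propensity > 1)) {
    stop("contact propensities must lie in [0, 1]", call. = FALSE)
  }
  check_positive(cutoff, "cutoff")
  prop <- rep_len(contact_propensity, n_residues)
  types <- names(composition)
  # residues on a line, spaced far apart relative to the cutoff so a bead
  # placed at a residue can never touch its neighbours
  res_x <- (seq_len(n_residues) - 1) * 4 * cutoff
  z_pep <- 40

  frames <- with_local_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      pep <- data.frame(residue = seq_len(n_residues), x = res_x, y = 0,
                        z = z_pep)
      touch <- runif(n_residues) < prop
      hg <- list()
      if (any(touch)) {
        idx <- which(touch)
        d <- runif(length(idx), 0.1, 0.9) * cutoff
        ang <- runif(length(idx), 0, 2 * pi)
        hg[[1]] <- data.frame(
          type = sample(types, length(idx), replace = TRUE,
                        prob = composition),
          x = res_x[idx] + d * cos(ang), y = d * sin(ang), z = z_pep,
          stringsAsFactors = FALSE)
      }
      # background headgroup layer well outside the cutoff
      n_bg <- n_residues
      hg[[2]] <- data.frame(
        type = sample(types, n_bg, replace = TRUE, prob = composition),
        x = runif(n_bg, min(res_x), max(res_x) + 1), y = 0, z = 0,
        stringsAsFactors = FALSE)
      list(peptide = pep, headgroups = do.call(rbind, hg))
    })
  })
  structure(list(frames = frames, composition = composition,
                 cutoff = cutoff, truth = prop),
            class = "contact_frames")
}

#' Generate a synthetic tomographic vesicle annotation table
#'
#' Draws, for each rod, the end at which a vesicle is attached, the location
#' of internalized membrane, and counts of tubular vesicles and membrane
#' discs inside the rod lumen. Defaults reproduce the observed frequencies:
#' 106/165 thin-end vs 59/165 thick-end attachments, 84/249 thick-end vs
#' 165/249 central internal locations, one-or-two tubes and two-to-five
#' discs per rod.
#'
#' @param n_rods Number of rods; 0 yields an empty table.
#' @param attachment_probs Named probabilities over `c("thin_end",
#'   "thick_end")`, summing to 1.
#' @param internal_probs Named probabilities over `c("thick_end", "central",
#'   "none")`, summing to 1.
#' @param tube_counts,disc_counts Integer support of the per-rod tube and
#'   disc count distributions.
#' @param tube_probs,disc_probs Probabilities over those supports (default
#'   uniform).
#' @param seed Optional integer seed.
#' @return A `vesicle_table`: data.frame with columns rod, attachment,
#'   internal_location, n_tubes, n_discs.
#' @export
gen_vesicle_table <- function(n_rods,
                              attachment_probs = c(thin_end = 106 / 165,
                                                   thick_end = 59 / 165),
                              internal_probs = c(thick_end = 84 / 249,
                                                 central = 165 / 249,
                                                 none = 0),
                              tube_counts = 1:2, disc_counts = 2:5,
                              tube_probs = NULL, disc_probs = NULL,
                              seed = NULL) {
  stopifnot(n_rods >= 0)
  for (p in list(attachment_probs, internal_probs)) {
    if (abs(sum(p) - 1) > 1e-9) {
      stop("category probabilities must sum to 1", call. = FALSE)
    }
  }
  if (is.null(tube_probs)) tube_probs <- rep(1 / length(tube_counts),
                                             length(tube_counts))
  if (is.null(disc_probs)) disc_probs <- rep(1 / length(disc_counts),
                                             length(disc_counts))
  if (n_rods == 0L) {
    tab <- data.frame(rod = integer(0), attachment = character(0),
                      internal_location = character(0),
                      n_tubes = integer(0), n_discs = integer(0),
                      stringsAsFactors = FALSE)
    return(structure(tab, class = c("vesicle_table", "data.frame")))
  }
  tab <- with_local_seed(seed, {
    data.frame(
      rod = seq_len(n_rods),
      attachment = sample(names(attachment_probs), n_rods, replace = TRUE,
                          prob = attachment_probs),
      internal_location = sample(names(internal_probs), n_rods,
                                 replace = TRUE, prob = internal_probs),
      n_tubes = sample(tube_counts, n_rods, replace = TRUE,
                       prob = tube_probs),
      n_discs = sample(disc_counts, n_rods, replace = TRUE,
                       prob = disc_probs),
      stringsAsFactors = FALSE)
  })
  structure(tab, class = c("vesicle_table", "data.frame"))
}
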