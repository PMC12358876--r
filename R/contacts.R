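# Peptide-residue / lipid-headgroup contact statistics, availability
# scaling by composition and area per lipid, membrane-bound helix counting,
# and the binding-versus-bending energy balance.

#' Per-residue contact counts with lipid headgroups
#'
#' A contact is a (residue bead, headgroup bead) pair within the cutoff;
#' counts are averaged over frames and split by lipid type. This is the raw
#' per-residue contact profile that identifies the membrane-interacting
#' residues of an amphipathic helix (M1, R6, R9, K12 for the alpha0
#' peptide).
#'
#' @param frames A `contact_frames` object (see [gen_contact_frames()]) or
#'   a list of frames, each a list with data.frames `peptide` (residue, x,
#'   y, z) and `headgroups` (type, x, y, z).
#' @param cutoff Contact cutoff in Angstrom between representative beads
#'   (default 6).
#' @return A `contact_profile`: list with `raw` (named per-residue mean
#'   contacts), `by_type` (residues x lipid types matrix), `scaled` (NULL
#'   until [scale_contacts()] is applied), `cutoff`, `n_frames`,
#'   `frequency` (fraction of frames with >= 1 contact per residue).
#' @export
residue_contacts <- function(frames, cutoff = 6) {
  check_positive(cutoff, "cutoff")
  fr <- if (inherits(frames, "contact_frames")) frames$frames else frames
  if (length(fr) == 0L) stop("empty frames", call. = FALSE)
  residues <- sort(unique(unlist(lapply(fr, function(f) f$peptide$residue))))
  types <- sort(unique(unlist(lapply(fr, function(f) f$headgroups$type))))
  acc <- matrix(0, length(residues), length(types),
                dimnames = list(residue = residues, type = types))
  freq <- setNames(numeric(length(residues)), residues)
  cut2 <- cutoff^2
  for (f in fr) {
    pep <- f$peptide
    hg <- f$headgroups
    if (nrow(hg) == 0L) next
    d2 <- outer(pep$x, hg$x, "-")^2 + outer(pep$y, hg$y, "-")^2 +
      outer(pep$z, hg$z, "-")^2
    within <- d2 <= cut2
    for (t in types) {
      cols <- hg$type == t
      if (any(cols)) {
        cnt <- rowSums(within[, cols, drop = FALSE])
        acc[as.character(pep$residue), t] <-
          acc[as.character(pep$residue), t] + cnt
      }
    }
    any_contact <- rowSums(within) > 0
    freq[as.character(pep$residue)] <- freq[as.character(pep$residue)] +
      any_contact
  }
  by_type <- acc / length(fr)
  structure(list(residues = residues, raw = rowSums(by_type),
                 by_type = by_type, scaled = NULL, cutoff = cutoff,
                 n_frames = length(fr), frequency = freq / length(fr)),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("Contact profile: %d residues, %d frames, cutoff %.3g A\n",
              length(x$residues), x$n_frames, x$cutoff))
  top <- order(x$raw, decreasing = TRUE)[seq_len(min(4, length(x$raw)))]
  cat("  most contacted residues:",
      paste(sprintf("%s (%.2f)", names(x$raw)[top], x$raw[top]),
            collapse = ", "), "\n")
  if (!is.null(x$scaled)) cat("  composition-scaled counts available\n")
  invisible(x)
}

#' Scale contact counts by lipid availability
#'
#' Divides per-type contact counts by (composition fraction x area per
#' lipid), converting raw counts into a per-available-surface propensity so
#' lipid types present at different abundance become comparable. For the
#' alpha0 peptide this scaling reveals the preference for the negatively
#' charged PG headgroups over the majority PE.
#'
#' @param profile A [residue_contacts()] result.
#' @param composition Named fractions per lipid type, summing to 1.
#' @param area_per_lipid Named areas per lipid in Angstrom^2 (defaults
#'   PG = 70, PE = 65).
#' @return The profile with its `scaled` matrix filled (residues x types).
#' @export
scale_contacts <- function(profile, composition,
                           area_per_lipid = c(PG = 70, PE = 65)) {
  stopifnot(inherits(profile, "contact_profile"))
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  check_positive(area_per_lipid, "area_per_lipid")
  types <- colnames(profile$by_type)
  if (!all(types %in% names(composition)) ||
      !all(types %in% names(area_per_lipid))) {
    stop("composition and area_per_lipid must cover every lipid type",
         call. = FALSE)
  }
  scaled <- profile$by_type
  for (t in types) {
    if (composition[[t]] == 0) {
      if (any(profile$by_type[, t] > 0)) {
        stop(sprintf("lipid type %s has zero composition but nonzero contacts",
                     t), call. = FALSE)
      }
      scaled[, t] <- 0
    } else {
      scaled[, t] <- profile$by_type[, t] /
        (composition[[t]] * area_per_lipid[[t]])
    }
  }
  profile$scaled <- scaled
  profile$composition <- composition
  profile$area_per_lipid <- area_per_lipid[types]
  profile
}

#' Count membrane-bound helices in an assembly
#'
#' A helix counts as membrane-bound in a frame when at least `min_residues`
#' of its terminal-segment residues lie within `cutoff` of the fitted
#' membrane surface (vertical distance to the surface height function).
#' Applied per frame to the terminal helices of a rod assembly, this gives
#' the bound-helix count whose binding free energy is weighed against the
#' membrane bending cost.
#'
#' @param assembly_frames List of frames; each frame is a list of helices,
#'   each helix a data.frame/matrix with columns x, y, z (one row per
#'   residue reference bead).
#' @param fit A `gaussian_surface_fit` of the membrane surface.
#' @param cutoff Vertical distance cutoff in Angstrom (default 8).
#' @param min_residues Minimum residues within the cutoff (default 3).
#' @return Integer vector of bound-helix counts, one per frame, each in
#'   \[0, number of helices\].
#' @export
bound_helix_count <- function(assembly_frames, fit, cutoff = 8,
                              min_residues = 3) {
  if (missing(fit) || !inherits(fit, "gaussian_surface_fit")) {
    stop("a fitted membrane surface is required", call. = FALSE)
  }
  check_positive(cutoff, "cutoff")
  stopifnot(min_residues >= 1)
  vapply(assembly_frames, function(frame) {
    bound <- vapply(frame, function(hel) {
      hel <- as.data.frame(hel)
      dz <- abs(hel$z - surface_height(fit, hel$x, hel$y))
      sum(dz <= cutoff) >= min_residues
    }, logical(1))
    sum(bound)
  }, integer(1))
}

#' Binding-versus-bending energy balance
#'
#' Weighs the total binding free energy of the bound helices
#' (n x |dG per helix|) against the Helfrich bending cost of the curved
#' membrane. The verdict is "favorable" when binding exceeds bending by
#' more than the tolerance, "unfavorable" when it falls short by more, and
#' "balanced" otherwise — the regime in which an internalized membrane
#' tubule is at equilibrium.
#'
#' @param n_bound Number of membrane-bound helices (>= 0).
#' @param dG_per_helix Per-helix standard binding free energy,
#'   kcal mol^-1; expected negative (a warning is raised otherwise).
#' @param bending_energy Helfrich bending cost, kcal mol^-1.
#' @param tolerance Dead-band half-width for the verdict, kcal mol^-1.
#' @return A `balance_result`: list with `n_bound_helices`,
#'   `dG_per_helix`, `total_binding`, `bending_energy`, `verdict`.
#' @export
#' @examples
#' energy_balance(30, -6.32, 160, tolerance = 25)
energy_balance <- function(n_bound, dG_per_helix, bending_energy,
                           tolerance = 0) {
  stopifnot(n_bound >= 0, tolerance >= 0)
  if (dG_per_helix > 0) {
    warning("dG_per_helix is positive; expected a (negative) binding free energy")
  }
  total <- n_bound * abs(dG_per_helix)
  verdict <- if (total > bending_energy + tolerance) {
    "favorable"
  } else if (total < bending_energy - tolerance) {
    "unfavorable"
  } else {
    "balanced"
  }
  structure(list(n_bound_helices = as.integer(n_bound),
                 dG_per_helix = dG_per_helix, total_binding = total,
                 bending_energy = bending_energy, tolerance = tolerance,
                 verdict = verdict),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("Energy balance: %d helices x %.3g kcal/mol = %.4g kcal/mol binding\n",
              x$n_bound_helices, abs(x$dG_per_helix), x$total_binding))
  cat(sprintf("  vs bending cost %.4g kcal/mol (tolerance %.3g): %s\n",
              x$bending_energy, x$tolerance, x$verdict))
  invisible(x)
}
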