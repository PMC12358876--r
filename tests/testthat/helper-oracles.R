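# Shared fixtures and independent oracles used across test files.

# A truth surface fit without generating a cloud
truth_fit <- function(amplitude, sigma, thickness = 34) {
  gen_leaflet_cloud(amplitude, sigma, thickness = thickness,
                    n_points = 1, seed = 1)$truth$upper
}

# Central finite-difference curvatures from the height function alone;
# independent of the analytic-derivative path in surface_curvatures().
fd_curvature <- function(fit, x, y, h = 1e-4) {
  f <- function(xx, yy) predict(fit, xx, yy)
  hx <- (f(x + h, y) - f(x - h, y)) / (2 * h)
  hy <- (f(x, y + h) - f(x, y - h)) / (2 * h)
  hxx <- (f(x + h, y) - 2 * f(x, y) + f(x - h, y)) / h^2
  hyy <- (f(x, y + h) - 2 * f(x, y) + f(x, y - h)) / h^2
  hxy <- (f(x + h, y + h) - f(x + h, y - h) -
            f(x - h, y + h) + f(x - h, y - h)) / (4 * h^2)
  g <- 1 + hx^2 + hy^2
  list(H = ((1 + hy^2) * hxx - 2 * hx * hy * hxy + (1 + hx^2) * hyy) /
         (2 * g^1.5),
       K = (hxx * hyy - hxy^2) / g^2)
}

# Brute-force Cartesian-mesh Helfrich sum with finite-difference
# curvatures: an independent quadrature route for E_total.
mesh_helfrich_energy <- function(fit, moduli, radius, dx = 1) {
  xs <- seq(fit$x0 - radius, fit$x0 + radius, by = dx)
  ys <- seq(fit$y0 - radius, fit$y0 + radius, by = dx)
  grid <- expand.grid(x = xs, y = ys)
  inside <- (grid$x - fit$x0)^2 + (grid$y - fit$y0)^2 <= radius^2
  g <- grid[inside, ]
  cv <- fd_curvature(fit, g$x, g$y, h = dx / 4)
  f <- function(xx, yy) predict(fit, xx, yy)
  hx <- (f(g$x + dx / 4, g$y) - f(g$x - dx / 4, g$y)) / (dx / 2)
  hy <- (f(g$x, g$y + dx / 4) - f(g$x, g$y - dx / 4)) / (dx / 2)
  dA <- sqrt(1 + hx^2 + hy^2)
  sum((2 * moduli$kappa * (cv$H - moduli$c0)^2 + moduli$kappa_bar * cv$K) *
        dA) * dx^2
}

# All-pairs contact counting by explicit loops; the oracle for
# residue_contacts().
brute_force_contacts <- function(frames, cutoff) {
  fr <- if (inherits(frames, "contact_frames")) frames$frames else frames
  residues <- sort(unique(unlist(lapply(fr, function(f) f$peptide$residue))))
  total <- setNames(numeric(length(residues)), residues)
  for (f in fr) {
    for (i in seq_len(nrow(f$peptide))) {
      ri <- as.character(f$peptide$residue[i])
      for (j in seq_len(nrow(f$headgroups))) {
        d <- sqrt((f$peptide$x[i] - f$headgroups$x[j])^2 +
                    (f$peptide$y[i] - f$headgroups$y[j])^2 +
                    (f$peptide$z[i] - f$headgroups$z[j])^2)
        if (d <= cutoff) total[ri] <- total[ri] + 1
      }
    }
  }
  total / length(fr)
}
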