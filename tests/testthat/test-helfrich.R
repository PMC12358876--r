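moduli <- bending_moduli()

test_that("curvatures match closed forms at the apex and vanish when flat", {
  f <- truth_fit(150, 50)
  cv <- surface_curvatures(f, f$x0, f$y0)
  expect_equal(cv$H, -150 / 50^2, tolerance = 1e-12)   # -0.06 1/A
  expect_equal(cv$K, 150^2 / 50^4, tolerance = 1e-12)  # 3.6e-3 1/A^2

  flat <- truth_fit(0, 50)
  cv0 <- surface_curvatures(flat, c(0, 10, 50), c(0, -3, 8))
  expect_true(all(cv0$H == 0))
  expect_true(all(cv0$K == 0))
})

test_that("analytic curvatures agree with a finite-difference oracle", {
  f <- truth_fit(150, 50)
  xs <- f$x0 + seq(-120, 120, by = 15)
  ys <- f$y0 + seq(-120, 120, by = 15)
  grid <- expand.grid(x = xs, y = ys)
  ana <- surface_curvatures(f, grid$x, grid$y)
  # Richardson-extrapolated central differences: O(h^4) accurate
  fd_h <- fd_curvature(f, grid$x, grid$y, h = 1)
  fd_h2 <- fd_curvature(f, grid$x, grid$y, h = 0.5)
  fd_H <- (4 * fd_h2$H - fd_h$H) / 3
  fd_K <- (4 * fd_h2$K - fd_h$K) / 3
  expect_lt(max(abs(ana$H - fd_H)) / max(abs(ana$H)), 1e-6)
  expect_lt(max(abs(ana$K - fd_K)) / max(abs(ana$K)), 1e-6)
})

test_that("a locally fitted sphere cap recovers -1/R and 1/R^2", {
  R <- 200
  set.seed(5)
  r <- sqrt(runif(4000)) * 0.08 * R  # local cap around the pole
  th <- runif(4000, 0, 2 * pi)
  cap <- data.frame(x = r * cos(th), y = r * sin(th),
                    z = sqrt(R^2 - r^2) - R)
  # pin the width well beyond the cap so only the apex curvature A/sigma^2
  # is identified (a tight cap carries no independent width information)
  fit <- fit_gaussian_surface(cap, lower = c(sigma = 160),
                              upper = c(sigma = 160))
  cv <- surface_curvatures(fit, fit$x0, fit$y0)
  expect_lt(abs(cv$H - (-1 / R)) / (1 / R), 0.01)
  expect_lt(abs(cv$K - 1 / R^2) / (1 / R^2), 0.01)
})

test_that("flat surfaces cost no bending energy", {
  res <- helfrich_energy(truth_fit(0, 50), moduli)
  expect_equal(res$E_total, 0)
  expect_true(all(res$profile$E_total == 0))
})

test_that("bending energy is invariant under uniform scaling at c0 = 0", {
  e1 <- helfrich_energy(truth_fit(150, 50), moduli)$E_total
  e2 <- helfrich_energy(truth_fit(300, 100), moduli)$E_total
  e3 <- helfrich_energy(truth_fit(75, 25), moduli)$E_total
  expect_lt(abs(e2 - e1) / e1, 0.005)
  expect_lt(abs(e3 - e1) / e1, 0.005)
})

test_that("small-slope limit reproduces kappa pi (A/sigma)^2", {
  f <- truth_fit(1, 50)
  res <- helfrich_energy(f, moduli, truncation_radius = 400)
  expect_lt(abs(res$E_mean - moduli$kappa * pi * (1 / 50)^2) /
              (moduli$kappa * pi * (1 / 50)^2), 0.01)
})

test_that("Gauss term vanishes over the full plane (Gauss-Bonnet)", {
  res <- helfrich_energy(truth_fit(150, 50), moduli,
                         truncation_radius = 350)
  expect_lt(abs(res$E_gauss), 1e-3 * res$E_mean)
  # and the decomposition closes
  expect_lt(abs(res$E_total - (res$E_mean + res$E_gauss)),
            1e-8 * max(1, abs(res$E_total)))
})

test_that("polar quadrature agrees with a brute-force mesh sum", {
  f <- truth_fit(150, 50)  # A/sigma = 3
  res <- helfrich_energy(f, moduli, truncation_radius = 200)
  oracle <- mesh_helfrich_energy(f, moduli, radius = 200, dx = 1)
  expect_lt(abs(res$E_total - oracle) / abs(oracle), 0.02)
})

test_that("energy is invariant under in-plane translation", {
  f0 <- truth_fit(150, 50)
  f1 <- f0
  f1$x0 <- f0$x0 + 123.4
  f1$y0 <- f0$y0 - 77.7
  e0 <- helfrich_energy(f0, moduli)
  e1 <- helfrich_energy(f1, moduli)
  expect_equal(e1$E_total, e0$E_total, tolerance = 1e-12)
})

test_that("radial profile starts at zero, is monotone, and localizes the cost", {
  res <- helfrich_energy(truth_fit(150, 50), moduli,
                         truncation_radius = 300)
  prof <- radial_energy_profile(res, cavity_radius = 100)
  expect_equal(unlist(prof[1, c("E_total", "E_mean", "E_gauss")]),
               c(E_total = 0, E_mean = 0, E_gauss = 0))
  expect_true(all(diff(prof$E_mean) >= -1e-12))
  expect_equal(attr(prof, "cavity_radius"), 100)
  # at least half of the asymptotic mean-curvature energy inside 2 sigma
  at_2sigma <- max(prof$E_mean[prof$rho <= 100])
  expect_gte(at_2sigma, 0.5 * res$E_mean)
  # Gauss contribution decays back to ~0 at the truncation radius
  expect_lt(abs(prof$E_gauss[nrow(prof)]), 1e-3 * res$E_mean)
})

test_that("truncation below 3 sigma is recorded as a warning", {
  res <- helfrich_energy(truth_fit(150, 50), moduli,
                         truncation_radius = 120)
  expect_match(res$quadrature$warnings, "truncation")
})

test_that("isoenergy map is zero at zero height and monotone in both axes", {
  m <- energy_map(heights = seq(0, 150, by = 30),
                  widths = seq(30, 90, by = 15), moduli)
  expect_true(all(m$energy[1, ] == 0))
  # energy strictly increases with height at every width
  expect_true(all(apply(m$energy[-1, ], 2, diff) > 0))
  expect_true(all(m$energy[-1, ] > 0))
  # and strictly decreases with width at every nonzero height
  expect_true(all(apply(m$energy[-1, ], 1, diff) < 0))
  expect_error(energy_map(10, widths = c(-5, 10)), "positive")
})

test_that("equal height-to-width ratios give equal map energies", {
  m <- energy_map(heights = c(50, 100), widths = c(25, 50), moduli)
  expect_equal(m$energy["50", "25"], m$energy["100", "50"],
               tolerance = 0.005)
})

test_that("projected snapshot energies match direct evaluation", {
  expect_equal(nrow(project_fits(list())), 0L)

  fits <- list(truth_fit(150, 50), truth_fit(100, 50), truth_fit(50, 50),
               truth_fit(0, 50))
  tab <- project_fits(fits, moduli)
  direct <- vapply(fits, function(f) helfrich_energy(f, moduli)$E_total,
                   numeric(1))
  expect_equal(tab$energy, direct, tolerance = 1e-12)
  # decreasing amplitude at fixed width -> decreasing energy
  expect_true(all(diff(tab$energy) < 1e-12))

  lower <- truth_fit(100, 50)
  lower$leaflet <- "lower"
  both <- project_fits(list(list(fits[[2]], lower)), moduli)
  tot <- attr(both, "totals")
  expect_equal(nrow(tot), 1L)
  expect_equal(tot$total, both$energy[1] + both$energy[2])
})
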