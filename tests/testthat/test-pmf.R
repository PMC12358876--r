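flat_pmf <- function(z) 0 * z
harmonic_truth <- function(z) 0.05 * (z - 30)^2 - 5

test_that("WHAM recovers a flat PMF from unbiased-truth windows", {
  ds <- gen_umbrella_dataset(flat_pmf, centers = seq(10, 50, length.out = 10),
                             spring_k = 0.2, n_samples = 20000, seed = 3)
  p <- wham_pmf(ds, n_bins = 60)
  expect_lt(max(abs(p$W)), 0.1)
})

test_that("WHAM recovers a harmonic well against the generator truth", {
  ds <- gen_umbrella_dataset(harmonic_truth,
                             centers = seq(12, 48, length.out = 20),
                             spring_k = 1, n_samples = 5000, seed = 4)
  p <- wham_pmf(ds, n_bins = 150)
  truth <- harmonic_truth(p$z)
  offset <- mean(truth - p$W)  # common gauge: profiles are defined up to a shift
  expect_lt(sqrt(mean((p$W - (truth - offset))^2)), 0.2)
  expect_lt(p$convergence$max_delta, 1e-7)
})

test_that("disjoint window supports raise an overlap error naming the gap", {
  ds <- list(windows = list(list(center = 10, k = 50,
                                 samples = rnorm(100, 10, 0.05)),
                            list(center = 30, k = 50,
                                 samples = rnorm(100, 30, 0.05))),
             temperature = 300)
  expect_error(wham_pmf(ds), "no histogram overlap.*10.*30")
})

test_that("WHAM output is invariant to window order and coordinate shifts", {
  ds <- gen_umbrella_dataset(flat_pmf, centers = seq(15, 35, length.out = 6),
                             spring_k = 0.3, n_samples = 3000, seed = 8)
  p1 <- wham_pmf(ds, n_bins = 50)
  ds_rev <- ds
  ds_rev$windows <- rev(ds$windows)
  p2 <- wham_pmf(ds_rev, n_bins = 50)
  expect_equal(p1$W, p2$W, tolerance = 1e-9)
  # shifting centers and samples by a constant shifts the grid only
  ds_sh <- ds
  ds_sh$windows <- lapply(ds$windows, function(w) {
    w$center <- w$center + 100
    w$samples <- w$samples + 100
    w
  })
  p3 <- wham_pmf(ds_sh, n_bins = 50)
  expect_equal(p3$z - 100, p1$z, tolerance = 1e-9)
  expect_equal(p3$W, p1$W, tolerance = 1e-6)
})

test_that("cumulative PMF integrates to zero for a flat profile and is additive", {
  prof <- list(z = seq(0, 50, by = 0.5), W = rep(0, 101))
  expect_true(all(cumulative_pmf(prof)$cumulative == 0))

  z <- seq(0, 50, by = 0.1)
  W <- -6 * exp(-(z - 20)^2 / 8)
  cum <- cumulative_pmf(list(z = z, W = W))
  # additivity over concatenated segments
  i_mid <- which.min(abs(z - 25))
  seg1 <- cumulative_pmf(list(z = z[1:i_mid], W = W[1:i_mid]))
  seg2 <- cumulative_pmf(list(z = z[i_mid:length(z)],
                              W = W[i_mid:length(z)]))
  expect_equal(tail(seg1$cumulative, 1) + tail(seg2$cumulative, 1),
               tail(cum$cumulative, 1), tolerance = 1e-10)
})

test_that("a well below 30 A dominates the cumulative integral", {
  z <- seq(5, 50, by = 0.05)
  W <- -8 * exp(-(z - 20)^2 / 18)  # essentially zero above 30 A
  cum <- cumulative_pmf(list(z = z, W = W))
  total <- abs(tail(cum$cumulative, 1))
  below30 <- abs(cum$cumulative[which.min(abs(z - 30))])
  expect_gte(below30 / total, 0.95)
})

test_that("standard binding free energy matches the square-well closed form", {
  kT <- kBT(300)
  z <- seq(0, 40, by = 0.005)
  W <- ifelse(z > 15 & z < 25, -5, 0)
  prof <- list(z = z, W = W)
  dg <- standard_binding_dg(prof, sampled_area = 100)
  oracle <- -kT * log(100 * 10 * exp(5 / kT) / 1661)
  expect_lt(abs(dg$dG_standard - oracle), 0.1)
  # components sum to the total
  expect_equal(unname(sum(dg$components)), dg$dG_standard,
               tolerance = 1e-9)
})

test_that("with the threshold disabled a flat PMF gives the pure volume term", {
  kT <- kBT(300)
  L <- 30
  prof <- list(z = seq(0, L, by = 0.01), W = rep(0, 3001))
  dg <- standard_binding_dg(prof, sampled_area = 250,
                            bound_threshold = Inf)
  expect_equal(dg$dG_standard, -kT * log(250 * L / 1661),
               tolerance = 1e-3)
})

test_that("deepening the well monotonically strengthens binding", {
  z <- seq(0, 40, by = 0.01)
  dgs <- vapply(c(2, 4, 6, 8), function(depth) {
    W <- -depth * exp(-(z - 20)^2 / 8)
    standard_binding_dg(list(z = z, W = W), sampled_area = 100)$dG_standard
  }, numeric(1))
  expect_true(all(diff(dgs) < 0))
  expect_error(standard_binding_dg(list(z = z, W = rep(1, length(z))),
                                   sampled_area = 100),
               "no bound state")
})

test_that("re-referencing to the plateau leaves dG unchanged", {
  z <- seq(0, 40, by = 0.01)
  W <- -6 * exp(-(z - 20)^2 / 8)
  ref <- function(W) W - mean(W[z > 35])
  d1 <- standard_binding_dg(list(z = z, W = ref(W)), sampled_area = 100)
  d2 <- standard_binding_dg(list(z = z, W = ref(W + 3.7)),
                            sampled_area = 100)
  expect_equal(d1$dG_standard, d2$dG_standard, tolerance = 1e-9)
})

test_that("Jarzynski average selects the replica closest to the estimate", {
  kT <- kBT(300)
  same <- jarzynski_select(rep(2.5, 8))
  expect_equal(same$free_energy, 2.5)
  expect_equal(same$index, 1L)

  two <- jarzynski_select(c(0, 1))
  expect_equal(two$free_energy, -kT * log((1 + exp(-1 / kT)) / 2),
               tolerance = 1e-12)

  set.seed(10)
  for (i in 1:20) {
    w <- rnorm(8, mean = runif(1, -2, 5), sd = runif(1, 0.1, 3))
    est <- jarzynski_select(w)
    expect_lte(est$free_energy, mean(w))  # Jensen
    expect_equal(est$index, which.min(abs(w - est$free_energy)))
  }
  expect_error(jarzynski_select(numeric(0)), "nonempty")
})

test_that("umbrella and PMF round-trip through their TSV formats", {
  ds <- gen_umbrella_dataset(flat_pmf, centers = c(18, 20, 22),
                             spring_k = 0.5, n_samples = 200, seed = 9)
  tf <- tempfile(fileext = ".tsv")
  write_umbrella_windows(ds, tf)
  ds2 <- read_umbrella_windows(tf)
  expect_equal(length(ds2$windows), 3L)
  expect_equal(ds2$windows[[1]]$samples, ds$windows[[1]]$samples)

  prof <- structure(list(z = 1:10, W = rnorm(10), sd = rep(NA_real_, 10)),
                    class = "pmf_profile")
  tf2 <- tempfile(fileext = ".tsv")
  write_pmf(prof, tf2)
  expect_equal(read_pmf(tf2)$W, prof$W, tolerance = 1e-10)
  unlink(c(tf, tf2))
})
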