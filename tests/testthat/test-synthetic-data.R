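test_that("zero-amplitude cloud is two flat planes at the bilayer thickness", {
  cl <- gen_leaflet_cloud(0, 50, n_points = 500, noise_sd = 0, seed = 1)
  up <- cl$points[cl$points$leaflet == "upper", ]
  lo <- cl$points[cl$points$leaflet == "lower", ]
  expect_equal(unique(up$z), 17)
  expect_equal(unique(lo$z), -17)
  expect_equal(nrow(up), 500)
  expect_equal(nrow(lo), 500)
})

test_that("noiseless cloud satisfies the Gaussian bump identity exactly", {
  cl <- gen_leaflet_cloud(150, 50, n_points = 1000, noise_sd = 0, seed = 2)
  up <- cl$points[cl$points$leaflet == "upper", ]
  x0 <- cl$box[1] / 2
  y0 <- cl$box[2] / 2
  expect_equal(up$z - 17,
               150 * exp(-((up$x - x0)^2 + (up$y - y0)^2) / (2 * 50^2)),
               tolerance = 1e-12)
  # points stay inside the box
  expect_true(all(up$x >= 0 & up$x <= cl$box[1]))
  expect_true(all(up$y >= 0 & up$y <= cl$box[2]))
})

test_that("mean bump height matches the analytic box average", {
  cl <- gen_leaflet_cloud(150, 50, box = c(426.6, 426.6), n_points = 50000,
                          noise_sd = 2, seed = 3)
  up <- cl$points[cl$points$leaflet == "upper", ]
  dev <- up$z - 17
  expected <- 150 * 2 * pi * 50^2 / 426.6^2
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev) - expected), 3 * se)
})

test_that("leaflet generator is reproducible and validates parameters", {
  a <- gen_leaflet_cloud(150, 50, n_points = 100, noise_sd = 2, seed = 42)
  b <- gen_leaflet_cloud(150, 50, n_points = 100, noise_sd = 2, seed = 42)
  expect_identical(a$points, b$points)
  expect_error(gen_leaflet_cloud(150, -1, n_points = 10), "sigma")
  expect_error(gen_leaflet_cloud(150, 50, thickness = 0, n_points = 10),
               "thickness")
})

test_that("unbiased umbrella window samples the Gaussian bias distribution", {
  k <- 2
  ds <- gen_umbrella_dataset(function(z) 0 * z, centers = 20, spring_k = k,
                             n_samples = 4000, seed = 5)
  s <- ds$windows[[1]]$samples
  sd_expect <- sqrt(kBT(300) / k)
  expect_lt(abs(mean(s) - 20), 4 * sd_expect / sqrt(length(s)))
  expect_lt(abs(sd(s) - sd_expect), 0.05 * sd_expect)
  ks <- suppressWarnings(stats::ks.test(s, "pnorm", 20, sd_expect))
  expect_gt(ks$p.value, 0.01)
})

test_that("window far from a harmonic well samples the product-Gaussian mean", {
  # truth well at z = 30 with stiffness kw; bias at z = 40 with stiffness k.
  # The biased density is Gaussian with mean (k*40 + kw*30) / (k + kw).
  kw <- 0.5
  k <- 1
  ds <- gen_umbrella_dataset(function(z) kw / 2 * (z - 30)^2, centers = 40,
                             spring_k = k, n_samples = 4000, seed = 6)
  s <- ds$windows[[1]]$samples
  post_mean <- (k * 40 + kw * 30) / (k + kw)
  post_sd <- sqrt(kBT(300) / (k + kw))
  expect_lt(abs(mean(s) - post_mean), 5 * post_sd / sqrt(length(s)))
  expect_gt(mean(s), 30)
  expect_lt(mean(s), 40)
})

test_that("umbrella generator rejects bad inputs", {
  expect_error(gen_umbrella_dataset(function(z) 0 * z, centers = 20,
                                    spring_k = 1, n_samples = 0),
               "n_samples")
  expect_error(gen_umbrella_dataset(function(z) 0 * z, centers = numeric(0),
                                    spring_k = 1, n_samples = 10),
               "nonempty")
  expect_error(gen_umbrella_dataset(function(z) ifelse(z > 19, -Inf, 0),
                                    centers = 20, spring_k = 1,
                                    n_samples = 10, seed = 1),
               "unnormalizable")
})

test_that("rod assembly places subunits on the cylinder at equal arcs", {
  rod <- gen_rod_assembly(10, 200, n_rungs = 3)
  r <- sqrt(rod$positions$x^2 + rod$positions$y^2)
  expect_true(all(abs(r - 100) < 1e-9))
  expect_equal(unname(table(rod$positions$rung)), rep(10L, 3),
               ignore_attr = TRUE)
  # nearest-neighbour arc length pi * D / n
  first <- rod$positions[rod$positions$rung == 1, ]
  ang <- atan2(first$y, first$x)
  arc <- 100 * min(diff(sort(ang)))
  expect_equal(arc, pi * 200 / 10, tolerance = 1e-9)
  expect_equal(pi * 345 / 18, 60.21, tolerance = 1e-3)
  one <- gen_rod_assembly(1, 100)
  expect_equal(nrow(one$positions), 1L)
  expect_equal(one$positions$y, 0)
  expect_error(gen_rod_assembly(0, 200), "n_per_rung")
})

test_that("contact frame generator realizes the requested propensities", {
  comp <- c(PG = 0.25, PE = 0.75)
  zero <- gen_contact_frames(50, 5, comp, 0, seed = 1)
  expect_true(all(residue_contacts(zero)$raw == 0))

  ones <- gen_contact_frames(1000, 3, comp, c(1, 0, 0), seed = 2)
  prof <- residue_contacts(ones)
  expect_equal(unname(prof$frequency[1]), 1)
  expect_equal(unname(prof$frequency[2]), 0)

  half <- gen_contact_frames(2000, 2, comp, 0.5, seed = 3)
  freq <- residue_contacts(half)$frequency
  expect_lt(max(abs(freq - 0.5)), 3 * sqrt(0.25 / 2000))

  expect_error(gen_contact_frames(10, 2, comp, -0.1), "propensit")
  expect_error(gen_contact_frames(10, 2, c(PG = 0.5, PE = 0.4), 0.5),
               "sum to 1")
})

test_that("vesicle table generator reproduces stated category frequencies", {
  all_thin <- gen_vesicle_table(200, attachment_probs = c(thin_end = 1,
                                                          thick_end = 0),
                                seed = 1)
  expect_true(all(all_thin$attachment == "thin_end"))

  tab <- gen_vesicle_table(10000, attachment_probs = c(thin_end = 0.64,
                                                       thick_end = 0.36),
                           seed = 2)
  frac <- mean(tab$attachment == "thin_end")
  expect_lt(abs(frac - 0.64), 3 * sqrt(0.64 * 0.36 / 10000))

  empty <- gen_vesicle_table(0)
  expect_equal(nrow(empty), 0L)
  expect_error(gen_vesicle_table(10, attachment_probs = c(thin_end = 0.7,
                                                          thick_end = 0.2)),
               "sum to 1")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_leaflet_cloud(10, 20, n_points = 10, noise_sd = 1, seed = 1))
  invisible(gen_vesicle_table(10, seed = 2))
  expect_identical(.Random.seed, before)
})
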