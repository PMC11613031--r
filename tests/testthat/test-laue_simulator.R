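# Synthetic-data generator: structure factors, ground truth, spectrum,
# observation corruption model.

test_that("structure factors match closed forms and a brute-force sum", {
  cr <- crystal_form(c(10, 12, 14, 90, 90, 90), "P1", dmin = 3)
  hkl <- asu_indices(cr)
  m1 <- toy_model(data.frame(x = 0, y = 0, z = 0, weight = 5))
  expect_equal(structure_factors_from_model(m1, cr, hkl = hkl),
               rep(5 + 0i, nrow(hkl)))
  # two equal atoms at x and -x (mod 1): purely real 2 w cos(2 pi h x)
  xv <- c(0.1, 0.27, 0.33)
  m2 <- toy_model(data.frame(x = c(xv[1], 1 - xv[1]), y = c(xv[2], 1 - xv[2]),
                             z = c(xv[3], 1 - xv[3]), weight = 3))
  F2 <- structure_factors_from_model(m2, cr, hkl = hkl)
  H <- as.matrix(hkl[, c("h", "k", "l")])
  expect_equal(Im(F2), rep(0, nrow(hkl)), tolerance = 1e-10)
  expect_equal(Re(F2), 2 * 3 * cos(2 * pi * as.vector(H %*% xv)),
               tolerance = 1e-10)
  # ten random atoms with B-factors against an explicit double loop
  set.seed(5)
  at <- data.frame(x = runif(10), y = runif(10), z = runif(10),
                   weight = runif(10, 1, 5), b = runif(10, 0, 30))
  m3 <- toy_model(at)
  F3 <- structure_factors_from_model(m3, cr, hkl = hkl)
  oracle <- sapply(seq_len(nrow(hkl)), function(i) {
    h <- as.numeric(hkl[i, c("h", "k", "l")])
    d <- resolution(h, cr$cell)
    s <- 0 + 0i
    for (j in 1:10) {
      s <- s + at$weight[j] * exp(-at$b[j] / (4 * d^2)) *
        exp(2i * pi * sum(h * c(at$x[j], at$y[j], at$z[j])))
    }
    s
  })
  expect_equal(F3, oracle, tolerance = 1e-10)
  expect_error(structure_factors_from_model(toy_model(data.frame(
    x = numeric(0), y = numeric(0), z = numeric(0),
    weight = numeric(0))), cr), "no atoms")
})

test_that("ground-truth chain has the right limits and planted difference", {
  cr <- crystal_form(c(10, 12, 14, 90, 90, 90), "P1", dmin = 2.5)
  set.seed(8)
  model <- toy_model(data.frame(x = runif(6), y = runif(6), z = runif(6),
                                weight = 4))
  # r -> 1: children equal the parent
  t1 <- generate_ground_truth(cr, 3, 0.999999, model,
                              perturbation_fraction = 0, seed = 1)
  rel <- sqrt(mean((t1$true_F[, 2] - t1$true_F[, 1])^2)) /
    sqrt(mean(t1$true_F[, 1]^2))
  expect_lt(rel, 0.001)
  # r = 0: statistically independent child
  t0 <- generate_ground_truth(cr, 2, 0, model, 0, seed = 2)
  rho <- cor(t0$true_F[, 1], t0$true_F[, 2])
  expect_lt(abs(rho), 3 / sqrt(nrow(t0$hkl)))
  # planted perturbation: analytic closed-form delta, stored exactly
  tp <- generate_ground_truth(cr, 2, 0.99, model,
                              perturbation_fraction = 0.2, seed = 3,
                              perturb_atom = 4L)
  H <- as.matrix(tp$hkl[, c("h", "k", "l")])
  xs <- as.numeric(model$atoms[4, c("x", "y", "z")])
  dexp <- -0.2 * model$atoms$weight[4] *
    exp(2i * pi * as.vector(H %*% xs))
  expect_equal(tp$perturbation_delta, dexp, tolerance = 1e-12)
  expect_equal(tp$perturbation_site, xs)
})

test_that("spectrum sampling is right-skewed, peaked, and reproducible", {
  sp0 <- spectrum_model(bandwidth_frac = 0)
  s0 <- sample_spectrum(sp0, 50, seed = 1)
  expect_true(all(s0$wavelength == sp0$lambda_peak))
  expect_true(all(s0$flux_weight == 1))

  sp <- spectrum_model()
  s <- sample_spectrum(sp, 1e5, seed = 2)
  # histogram mode within 1% of lambda_peak
  hh <- hist(s$wavelength, breaks = 400, plot = FALSE)
  mode_est <- hh$mids[which.max(hh$counts)]
  expect_lt(abs(mode_est - sp$lambda_peak) / sp$lambda_peak, 0.01)
  sk <- mean((s$wavelength - mean(s$wavelength))^3) /
    sd(s$wavelength)^3
  expect_gt(sk, 0)
  # FWHM of the density matches the configured bandwidth
  lam <- seq(sp$lambda_min + 1e-9, sp$lambda_max, length.out = 20000)
  dens <- spectrum_density(sp, lam)
  half <- max(dens) / 2
  fw <- diff(range(lam[dens >= half]))
  expect_equal(fw, 0.05 * sp$lambda_peak, tolerance = 0.02)
  s2 <- sample_spectrum(sp, 1000, seed = 9)
  s3 <- sample_spectrum(sp, 1000, seed = 9)
  expect_identical(s2, s3)
})

test_that("the identity configuration reproduces |F|^2 exactly", {
  cr <- crystal_form(c(10, 12, 14, 90, 90, 90), "P1", dmin = 2.5)
  set.seed(4)
  model <- toy_model(data.frame(x = runif(5), y = runif(5), z = runif(5),
                                weight = 4))
  truth <- generate_ground_truth(cr, 1, 0, model, 0, seed = 4)
  sim <- simulate_observations(truth, spectrum_model(bandwidth_frac = 0),
                               n_images_per_dataset = 3, obs_per_image = 10,
                               scale_jitter_range = c(1, 1), noise_frac = 0,
                               noise_floor = 0, outlier_frac = 0,
                               harmonic_prob = 0, flip_prob = 0,
                               detector_modulation = 0, seed = 5)
  Ftrue <- truth$true_F[sim$truth$obs$asu_row, 1]
  expect_equal(sim$table$I, Ftrue^2, tolerance = 1e-12)
  # every observation multiplied by the outlier factor
  sim2 <- simulate_observations(truth, spectrum_model(bandwidth_frac = 0),
                                3, 10, c(1, 1), 0, 0, outlier_frac = 1,
                                outlier_factor = 10, harmonic_prob = 0,
                                flip_prob = 0, detector_modulation = 0,
                                seed = 5)
  expect_equal(sim2$table$I, 10 * Ftrue^2, tolerance = 1e-12)
})

test_that("corruption rates and reproducibility hold at defaults", {
  sc <- small_scene(1)
  n <- nrow(sc$table)
  harm <- sum(sc$truth$obs$harmonic)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.01)
  expect_gte(harm, ci[1]); expect_lte(harm, ci[2])
  out <- sum(sc$truth$obs$outlier)
  ci2 <- qbinom(c(0.0005, 0.9995), n, 0.02)
  expect_gte(out, ci2[1]); expect_lte(out, ci2[2])
  # reproducibility: identical seed, identical tables
  again <- build_scene("small", seed = 1)
  expect_identical(as.data.frame(sc$table), as.data.frame(again$table))
})

test_that("per-image clean intensities conserve scale times flux", {
  sc <- small_scene(1)
  tr <- sc$truth
  obs <- tr$obs
  Ftrue <- tr$true_F[cbind(obs$asu_row, obs$dataset + 1L)]
  df <- as.data.frame(sc$table)
  det <- 1 + 0.2 * sin(2 * pi * 3 * df$X / 100) * sin(2 * pi * 3 * df$Y / 100)
  clean <- !obs$outlier & !obs$harmonic
  ratio <- df$I[clean] / (Ftrue[clean]^2 * obs$flux[clean] * det[clean])
  key <- paste(obs$dataset, obs$image)[clean]
  est <- tapply(ratio, key, mean)
  se <- tapply(ratio, key, function(x) sd(x) / sqrt(length(x)))
  truth_scale <- tr$image_scales$scale[
    match(names(est), paste(tr$image_scales$dataset, tr$image_scales$image))]
  z <- (est - truth_scale) / pmax(se, 1e-9)
  expect_gt(mean(abs(z) <= 3), 0.97)
})

test_that("the planted site is the global extremum of the ideal difference map", {
  sc <- small_scene(1)
  tr <- sc$truth
  co <- data.frame(h = tr$hkl$h, k = tr$hkl$k, l = tr$hkl$l)
  co$coefficient <- (tr$true_F[, 2] - tr$true_F[, 1]) *
    complex(modulus = 1,
            argument = Arg(structure_factors_from_model(sc$model,
                                                        sc$crystal,
                                                        hkl = tr$hkl)))
  attr(co, "crystal") <- sc$crystal
  class(co) <- c("map_coefficients", "data.frame")
  map <- compute_map(co, sc$crystal)
  pk <- find_peaks(map, 3)
  top <- pk[1, ]
  expect_lte(site_orbit_dist(c(top$x, top$y, top$z), sc),
             2 * max(map$spacing))
})

test_that("ground truth writes a readable text sidecar", {
  sc <- tiny_scene()
  p <- tempfile()
  write_ground_truth(sc$truth, p)
  lines <- readLines(p)
  expect_true(any(grepl("true_r", lines)))
  body <- read.delim(p, comment.char = "#")
  expect_equal(nrow(body), nrow(sc$truth$hkl))
  expect_equal(body$F_0, sc$truth$true_F[, 1], tolerance = 1e-8)
})
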