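# Figures of merit: CC_half, CC_pred, bootstrap, difference maps, peaks,
# RSCC, scale-vs-wavelength.

make_pred_df <- function(n = 200, rho = 0.9, seed = 2) {
  set.seed(seed)
  x <- rlnorm(n, 3)
  y <- rho * x + sqrt(1 - rho^2) * rlnorm(n, 3)
  data.frame(I = x, SigI = runif(n, 0.5, 3), predicted_mean_I = y,
             predicted_std_I = 1,
             is_test = rep(c(FALSE, TRUE), length.out = n))
}

test_that("cc_half is 1 for duplicated noiseless data and 0 for pure noise", {
  cr <- crystal_form(c(20, 20, 20, 90, 90, 90), "P1", dmin = 2)
  hkl <- asu_indices(cr)
  set.seed(4)
  Iv <- rlnorm(nrow(hkl), 3)
  dup <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(dataset = 0L, image = i, h = hkl$h, k = hkl$k, l = hkl$l,
               I = Iv, SigI = 1)
  }))
  cc <- cc_half(refl_table(dup), cr, n_bins = 5, seed = 1)
  expect_true(all(abs(cc$cc_half - 1) < 1e-12))

  noise <- dup
  set.seed(5)
  noise$I <- rnorm(nrow(noise))
  ccn <- cc_half(refl_table(noise), cr, n_bins = 4, seed = 1)
  expect_true(all(abs(ccn$cc_half) < 3 / sqrt(ccn$n), na.rm = TRUE))
})

test_that("cc_half falls with resolution on scale-corrected simulator data", {
  sc <- fixture("scene_nooutlier",
                build_scene("small", seed = 9, outlier_frac = 0,
                            n_images_per_dataset = 50))
  tr <- sc$truth
  oracle <- tr$obs$clean_I /
    tr$true_F[cbind(tr$obs$asu_row, tr$obs$dataset + 1L)]^2
  cc <- cc_half(sc$table, sc$crystal, seed = 5, scales = pmax(oracle, 1e-9))
  expect_lt(cor(seq_len(nrow(cc)), cc$cc_half, method = "spearman"), 0)
  expect_gt(cc$cc_half[1], cc_half_highest(cc))
})

test_that("cc_pred matches trivial and independently coded formulas", {
  pr <- data.frame(I = c(1, 2, 3), SigI = 1, predicted_mean_I = c(1, 2, 3),
                   is_test = FALSE)
  expect_equal(unname(cc_pred(pr, "pearson_weighted")["train"]), 1)
  expect_equal(unname(cc_pred(pr, "spearman")["train"]), 1)
  pr$predicted_mean_I <- c(3, 2, 1)
  expect_equal(unname(cc_pred(pr, "pearson_weighted")["train"]), -1)
  expect_equal(unname(cc_pred(pr, "spearman")["train"]), -1)

  pred <- make_pred_df(200)
  got <- cc_pred(pred, "pearson_weighted")
  # direct covariance-ratio oracle
  oracle <- function(sel) {
    w <- 1 / pred$SigI[sel]^2
    x <- pred$I[sel]; y <- pred$predicted_mean_I[sel]
    mx <- weighted.mean(x, w); my <- weighted.mean(y, w)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  expect_equal(unname(got["train"]), oracle(!pred$is_test),
               tolerance = 1e-12)
  expect_equal(unname(got["test"]), oracle(pred$is_test), tolerance = 1e-12)
  sp <- cc_pred(pred, "spearman")
  expect_equal(unname(sp["train"]),
               cor(pred$I[!pred$is_test],
                   pred$predicted_mean_I[!pred$is_test],
                   method = "spearman"), tolerance = 1e-12)
})

test_that("bootstrap CC has the right count, limits, and sqrt(n) scaling", {
  pred <- make_pred_df(60)
  bs <- bootstrap_cc(pred, "spearman", n_resamples = 1000, seed = 3)
  expect_length(bs$train, 1000)
  expect_length(bs$test, 1000)
  # perfectly correlated data: every resample is exactly 1
  perf <- data.frame(I = 1:50, SigI = 1, predicted_mean_I = (1:50) * 2,
                     is_test = FALSE)
  bp <- bootstrap_cc(perf, "pearson_weighted", n_resamples = 50, seed = 1)
  expect_true(all(bp$train == 1))
  # degenerate rows flag as NA
  dg <- data.frame(I = rep(1, 10), SigI = 1, predicted_mean_I = 1,
                   is_test = FALSE)
  bd <- bootstrap_cc(dg, "pearson_weighted", n_resamples = 10, seed = 1)
  expect_true(all(is.na(bd$train)))
  # bootstrap spread shrinks like 1/sqrt(n)
  s1 <- sd(bootstrap_cc(make_pred_df(50, 0.8, seed = 11), "spearman",
                        400, seed = 2)$train)
  s2 <- sd(bootstrap_cc(make_pred_df(200, 0.8, seed = 11), "spearman",
                        400, seed = 2)$train)
  expect_gt(s1 / s2, 1.2)
  expect_lt(s1 / s2, 3.5)
})

test_that("difference coefficients vanish for equal merges and match the planted truth", {
  sc <- small_scene(1)
  m <- data.frame(dataset = 0L, h = sc$truth$hkl$h, k = sc$truth$hkl$k,
                  l = sc$truth$hkl$l, F = sc$truth$true_F[, 1],
                  SigF = 0.1)
  m0 <- merged_sf(m)
  co <- difference_coefficients(m0, m0, sc$model, sc$crystal)
  expect_true(all(Mod(co$coefficient) == 0))
  # symmetry expansion covers the full point-group orbit
  expect_gt(nrow(co), nrow(m0) * 3)

  # truth amplitudes for t vs 0: matches the closed-form planted difference
  mt <- merged_sf(transform(m, F = sc$truth$true_F[, 2]))
  expect_error(difference_coefficients(mt[0, ], m0, sc$model, sc$crystal),
               "common")
  # amplitude differences of the truth equal |F_t| - |F_0| (ASU synthesis)
  cot <- difference_coefficients(mt, m0, sc$model, sc$crystal,
                                 expand_symmetry = FALSE)
  key <- pinkmerge:::.miller_key(sc$truth$hkl$h, sc$truth$hkl$k,
                                 sc$truth$hkl$l)
  idx <- match(pinkmerge:::.miller_key(cot$h, cot$k, cot$l), key)
  expect_equal(Mod(cot$coefficient),
               abs(sc$truth$true_F[idx, 2] - sc$truth$true_F[idx, 1]),
               tolerance = 1e-10)
})

test_that("map synthesis obeys single-mode forms and Parseval", {
  cr <- crystal_form(c(10, 10, 10, 90, 90, 90), "P1", dmin = 2)
  co <- data.frame(h = 1L, k = 0L, l = 0L)
  co$coefficient <- 2 + 0i
  attr(co, "crystal") <- cr
  map <- compute_map(co, cr, grid_spacing = 1, sigma_scale = FALSE)
  # single real coefficient at (1,0,0): cosine along a, maximal at x = 0
  d <- dim(map$grid)
  xprof <- map$grid[, 1, 1]
  expect_equal(xprof, 2 * 2 * cos(2 * pi * (seq_len(d[1]) - 1) / d[1]),
               tolerance = 1e-10)
  expect_equal(which.max(xprof), 1L)

  # all-zero coefficients: flat map, flagged
  co0 <- co; co0$coefficient <- 0 + 0i
  map0 <- compute_map(co0, cr, grid_spacing = 1)
  expect_true(map0$flat)
  expect_equal(find_peaks(map0)$height, numeric(0))

  # Parseval over a random coefficient set
  set.seed(8)
  hs <- expand.grid(h = 0:2, k = -2:2, l = -2:2)
  hs <- hs[rowSums(abs(hs)) > 0, ][sample(40), ]
  asu <- map_to_asu(as.matrix(hs), "P1")
  hs <- unique(data.frame(h = asu$h, k = asu$k, l = asu$l))
  hs$coefficient <- complex(real = rnorm(nrow(hs)),
                            imaginary = rnorm(nrow(hs)))
  attr(hs, "crystal") <- cr
  mp <- compute_map(hs, cr, grid_spacing = 1, sigma_scale = FALSE)
  lhs <- 2 * sum(Mod(hs$coefficient)^2) # h and its Friedel mate
  rhs <- mean(mp$grid^2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  expect_error(compute_map(hs, cr, grid_spacing = 1.5), "aliases")
})

test_that("peak finding is localized, interpolated, and antisymmetric", {
  cr <- crystal_form(c(12, 12, 12, 90, 90, 90), "P1", dmin = 2)
  g <- array(0, dim = c(12, 12, 12))
  g[4, 7, 9] <- 5
  map <- structure(list(grid = g, spacing = rep(1, 3), crystal = cr,
                        flat = FALSE, sigma_scaled = TRUE),
                   class = "density_map")
  pk <- find_peaks(map, 3)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$height, 5)
  expect_equal(c(pk$x, pk$y, pk$z), c(3, 6, 8) / 12)
  neg <- map; neg$grid <- -neg$grid
  pkn <- find_peaks(neg, 3)
  expect_equal(pkn$height, -5)
  expect_equal(c(pkn$x, pkn$y, pkn$z), c(pk$x, pk$y, pk$z))
})

test_that("fitted difference maps peak at the planted site", {
  hits <- vapply(1:3, function(seed) {
    fit <- small_fit(seed)
    sc <- small_scene(seed)
    m <- coef(fit)
    m0 <- merged_subset(m, 0L)
    co <- difference_coefficients(merged_subset(m, 1L), m0, sc$model,
                                  sc$crystal)
    map <- compute_map(co, sc$crystal)
    pk <- find_peaks(map, 3)
    if (nrow(pk) == 0) return(FALSE)
    site_orbit_dist(c(pk$x[1], pk$y[1], pk$z[1]), sc) <= 2 * max(map$spacing)
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("rscc matches a direct covariance computation and handles masks", {
  cr <- crystal_form(c(10, 10, 10, 90, 90, 90), "P1", dmin = 2)
  set.seed(6)
  mk <- function() structure(list(grid = array(rnorm(1000), c(10, 10, 10)),
                                  spacing = rep(1, 3), crystal = cr,
                                  flat = FALSE, sigma_scaled = TRUE),
                             class = "density_map")
  a <- mk(); b <- mk()
  expect_equal(rscc(a, a), 1)
  neg <- a; neg$grid <- -neg$grid
  expect_equal(rscc(a, neg), -1)
  mask <- array(runif(1000) < 0.3, c(10, 10, 10))
  expect_equal(rscc(a, b, mask), cor(a$grid[mask], b$grid[mask]),
               tolerance = 1e-12)
  cst <- a; cst$grid[] <- 1
  expect_warning(v <- rscc(cst, b), "undefined")
  expect_true(is.na(v))
  sph <- mask_sphere(a, c(0.5, 0.5, 0.5), radius = 2)
  expect_true(any(sph) && !all(sph))
})

test_that("scale-vs-wavelength is deterministic and refuses mono fits", {
  fit <- small_fit(1)
  s1 <- scale_vs_wavelength(fit, 12)
  s2 <- scale_vs_wavelength(fit, 12)
  expect_identical(s1, s2)
  expect_equal(sum(s1$hist), nrow(small_scene(1)$table))
  sc <- tiny_scene()
  fmono <- vi_merge(sc$table, sc$crystal, prior = sc$prior,
                    scale_config = scale_model_config(
                      mlp_layers = 2, mlp_width = 4, image_layers = 0,
                      positional_encoding_frequencies = 0),
                    mode = "mono", steps = 30, learning_rate = 0.02,
                    seed = 1)
  expect_error(scale_vs_wavelength(fmono), "mono")
})

test_that("the CCP4 map writer produces a well-formed file", {
  cr <- crystal_form(c(10, 10, 10, 90, 90, 90), "P1", dmin = 2)
  g <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  map <- structure(list(grid = g, spacing = rep(1, 3), crystal = cr,
                        flat = FALSE, sigma_scaled = TRUE),
                   class = "density_map")
  p <- tempfile(fileext = ".ccp4")
  write_ccp4_map(map, p)
  expect_equal(file.size(p), 1024 + 4 * length(g))
  con <- file(p, "rb")
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  close(con)
  expect_equal(dims, dim(g))
})
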