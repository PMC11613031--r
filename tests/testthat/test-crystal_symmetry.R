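# Cell geometry, ASU mapping, harmonic enumeration, ambiguity resolution.

test_that("resolution matches axial spacings and a metric-tensor oracle", {
  cell <- c(10, 20, 30, 90, 90, 90)
  expect_equal(resolution(c(1, 0, 0), cell), 10)
  expect_equal(resolution(c(0, 0, 3), cell), 10)
  # independent oracle: explicit reciprocal basis via cross products
  tric <- c(10, 11, 12, 85, 95, 100)
  M <- pinkmerge:::.frac_to_cart(tric)
  a <- M[, 1]; b <- M[, 2]; cc <- M[, 3]
  V <- abs(det(M))
  cross <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3],
                            u[1]*v[2]-u[2]*v[1])
  astar <- cross(b, cc) / V; bstar <- cross(cc, a) / V
  cstar <- cross(a, b) / V
  h <- c(1, 2, 3)
  q <- h[1]*astar + h[2]*bstar + h[3]*cstar
  expect_equal(resolution(h, tric), 1 / sqrt(sum(q^2)), tolerance = 1e-10)
  expect_error(resolution(c(0, 0, 0), cell), "resolution")
})

test_that("P3121 ASU mapping agrees with an exhaustive orbit oracle", {
  # hand-written operation list for point group 321 (hexagonal axes)
  ops <- list(function(h) h,
              function(h) c(h[2], -h[1]-h[2], h[3]),
              function(h) c(-h[1]-h[2], h[1], h[3]),
              function(h) c(h[2], h[1], -h[3]),
              function(h) c(-h[1]-h[2], h[2], -h[3]),
              function(h) c(h[1], -h[1]-h[2], -h[3]))
  grid <- as.matrix(expand.grid(h = -4:4, k = -4:4, l = -4:4))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  res <- map_to_asu(grid, "P3121")
  for (i in sample(nrow(grid), 200)) {
    h <- as.integer(grid[i, ])
    images <- do.call(rbind, lapply(ops, function(f) f(h)))
    orbit <- unique(images)
    # same representative for every mate
    reps <- map_to_asu(orbit, "P3121")
    expect_true(all(reps$h == res$h[i] & reps$k == res$k[i] &
                      reps$l == res$l[i]))
    # centricity: -h in the proper-rotation orbit
    expect_equal(res$centric[i],
                 any(apply(orbit, 1, function(m) all(m == -h))))
    # epsilon: stabilizer size over the operation images (with repeats)
    expect_equal(res$epsilon[i],
                 sum(apply(images, 1, function(m) all(m == h))))
  }
})

test_that("ASU mapping is idempotent and P1 uses Friedel pairs", {
  set.seed(3)
  H <- matrix(sample(-8:8, 300, replace = TRUE), ncol = 3)
  H <- H[rowSums(abs(H)) > 0, ]
  for (sg in c("P1", "P21", "P3121")) {
    a1 <- map_to_asu(H, sg)
    a2 <- map_to_asu(as.matrix(a1[, 1:3]), sg)
    expect_equal(a1, a2)
  }
  p1 <- map_to_asu(rbind(c(1, -2, 3), c(-1, 2, -3)), "P1")
  expect_equal(p1$h[1], p1$h[2])
  expect_equal(p1$epsilon, c(1L, 1L))
})

test_that("harmonic candidates follow the gcd and lambda/n rules", {
  cell <- c(30, 30, 30, 90, 90, 90)
  hg <- harmonic_candidates(c(2, 4, 6), 1.0, cell, 0.5, 1.5, dmin = 1)
  expect_equal(hg$primitive_ray, c(1L, 2L, 3L))
  hg2 <- harmonic_candidates(c(1, 1, 1), 2.0, cell, 0.95, 2.1, dmin = 1)
  expect_equal(hg2$members$n, c(1L, 2L))
  expect_equal(hg2$members$wavelength, c(2.0, 1.0))
  expect_equal(as.matrix(hg2$members[2, c("h", "k", "l")]),
               matrix(c(2L, 2L, 2L), 1), ignore_attr = TRUE)
  # collinearity: reciprocal vectors of all members are parallel
  Gs <- solve(pinkmerge:::.cell_metric(c(10, 11, 12, 85, 95, 100)))
  hg3 <- harmonic_candidates(c(1, 2, 1), 2.4, c(10, 11, 12, 85, 95, 100),
                             0.4, 2.5, dmin = 1)
  vecs <- as.matrix(hg3$members[, c("h", "k", "l")]) %*% Gs
  un <- vecs / sqrt(rowSums(vecs^2))
  expect_true(all(abs(un %*% un[1, ] - 1) < 1e-12))
  expect_error(harmonic_candidates(c(1, 1, 1), 30.0, cell, 0.95, 2.1,
                                   dmin = 1), "no harmonic member")
})

test_that("enumerated harmonic fraction on simulated data is small and matches the injection rate", {
  sc <- small_scene(1)
  df <- as.data.frame(sc$table)
  sp <- sc$truth$spectrum
  multi <- vapply(seq_len(nrow(df)), function(i) {
    nrow(harmonic_candidates(c(df$h[i], df$k[i], df$l[i]), df$Wavelength[i],
                             sc$crystal$cell, sp$lambda_min, sp$lambda_max,
                             dmin = sc$crystal$dmin)$members) > 1
  }, logical(1))
  frac <- mean(multi)
  expect_lt(frac, 0.02)
  # consistency: enumerated overlaps are exactly the injected ones
  expect_identical(multi, sc$truth$obs$harmonic)
  ci <- qbinom(c(0.0005, 0.9995), nrow(df), 0.01) / nrow(df)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("indexing-ambiguity resolution recovers planted flips", {
  # already-consistent data stays untouched
  sc0 <- fixture("amb_scene",
                 build_scene("small", seed = 12, n_datasets = 2,
                             n_images_per_dataset = 15, obs_per_image = 50,
                             noise_frac = 0.02, outlier_frac = 0,
                             detector_modulation = 0, harmonic_prob = 0))
  res0 <- resolve_indexing_ambiguity(sc0$table, sc0$crystal)
  expect_true(all(res0$assignment$operator == "identity"))
  expect_equal(as.data.frame(res0$table), as.data.frame(sc0$table))

  # one dataset flipped wholesale comes back
  df <- as.data.frame(sc0$table)
  op <- pinkmerge:::.sg_get("P3121")$ambiguity_op
  sel <- df$dataset == 1
  Hf <- as.matrix(df[sel, c("h", "k", "l")]) %*% t(op)
  df[sel, c("h", "k", "l")] <- Hf
  res1 <- resolve_indexing_ambiguity(refl_table(df), sc0$crystal)
  a1 <- res1$assignment
  expect_true(all(a1$operator[a1$dataset == 1] == "alternative"))
  expect_true(all(a1$operator[a1$dataset == 0] == "identity"))

  # 50% random per-image flips, 5 seeds: >= 99% of images recovered
  acc <- vapply(1:5, function(seed) {
    sc <- fixture(paste0("flip_scene_", seed),
                  build_scene("small", seed = seed, flip_prob = 0.5))
    res <- resolve_indexing_ambiguity(sc$table, sc$crystal)
    tf <- merge(res$assignment, sc$truth$flip_ops,
                by = c("dataset", "image"))
    got <- tf$operator == ifelse(tf$flipped, "alternative", "identity")
    max(mean(got), mean(!got)) # global convention is arbitrary
  }, numeric(1))
  expect_gte(mean(acc), 0.99)
})

test_that("ambiguity resolution is invariant to a global flip of all inputs", {
  sc <- fixture("amb_scene",
                build_scene("small", seed = 12, n_datasets = 2,
                            n_images_per_dataset = 15, obs_per_image = 50,
                            noise_frac = 0.02, outlier_frac = 0,
                            detector_modulation = 0, harmonic_prob = 0))
  op <- pinkmerge:::.sg_get("P3121")$ambiguity_op
  df <- as.data.frame(sc$table)
  dfg <- df
  dfg[, c("h", "k", "l")] <- as.matrix(df[, c("h", "k", "l")]) %*% t(op)
  r1 <- resolve_indexing_ambiguity(sc$table, sc$crystal)
  r2 <- resolve_indexing_ambiguity(refl_table(dfg), sc$crystal)
  # the two runs agree up to the arbitrary reference convention
  same <- r1$assignment$operator == r2$assignment$operator
  expect_true(all(same) || all(!same))
})
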