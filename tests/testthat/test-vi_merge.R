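# Priors, error models, the harmonic forward model, the ELBO estimator, and
# the fitting engine.

test_that("Wilson log-density matches closed forms and integrates to one", {
  expect_equal(wilson_logpdf(1, FALSE, 1, 1), log(2) - 1)
  expect_equal(wilson_logpdf(1e-12, TRUE, 1, 1), 0.5 * log(2 / pi),
               tolerance = 1e-9)
  for (cen in c(FALSE, TRUE)) for (eps in 1:3) {
    z <- integrate(function(F) exp(wilson_logpdf(F, cen, eps, 1)), 0, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
  expect_error(wilson_logpdf(-0.1), "non-negative")
})

test_that("double-Wilson reduces to Wilson at r = 0 and integrates to one", {
  set.seed(1)
  Fv <- rexp(100)
  cen <- sample(c(TRUE, FALSE), 100, TRUE)
  ep <- sample(1:3, 100, TRUE)
  expect_equal(double_wilson_logpdf(Fv, 2, 0, cen, ep, 1),
               wilson_logpdf(Fv, cen, ep, 1), tolerance = 1e-12)
  for (r in c(0.5, 0.9, 0.99)) for (cen1 in c(FALSE, TRUE)) {
    z <- integrate(function(F) exp(double_wilson_logpdf(F, 1.3, r, cen1,
                                                        2, 1)),
                   0, Inf, rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
  # concentration: conditional mean approaches the parent amplitude
  m1 <- integrate(function(F) F * exp(double_wilson_logpdf(F, 2, 0.999,
                                                           FALSE, 1, 1)),
                  0, Inf)$value
  expect_lt(abs(m1 - 2) / 2, 0.01)
  expect_error(double_wilson_logpdf(1, 1, 1.0), "r must")
})

test_that("gradients of the priors match numerical differentiation", {
  h <- 1e-6
  for (cen in c(FALSE, TRUE)) {
    Fv <- c(0.3, 1.1, 2.7)
    ga <- pinkmerge:::.wilson_grad(Fv, cen, 2, 1.3)
    gn <- (wilson_logpdf(Fv + h, cen, 2, 1.3) -
             wilson_logpdf(Fv - h, cen, 2, 1.3)) / (2 * h)
    expect_equal(ga, gn, tolerance = 1e-6)
    gd <- pinkmerge:::.double_wilson_grad(Fv, 1.7, 0.9, cen, 2, 1.3)
    gnc <- (double_wilson_logpdf(Fv + h, 1.7, 0.9, cen, 2, 1.3) -
              double_wilson_logpdf(Fv - h, 1.7, 0.9, cen, 2, 1.3)) / (2 * h)
    gnp <- (double_wilson_logpdf(Fv, 1.7 + h, 0.9, cen, 2, 1.3) -
              double_wilson_logpdf(Fv, 1.7 - h, 0.9, cen, 2, 1.3)) / (2 * h)
    expect_equal(gd$child, gnc, tolerance = 1e-5)
    expect_equal(gd$parent, gnp, tolerance = 1e-5)
  }
})

test_that("error models match their special-function forms", {
  # standard Cauchy at its mode
  expect_equal(likelihood_logpdf(0, 1, 0, likelihood_spec("studentt", 1)),
               -log(pi))
  # nu -> infinity converges to the normal model
  x <- seq(-4, 4, length.out = 50)
  dt_big <- likelihood_logpdf(x, 1.3, 0, likelihood_spec("studentt", 1e6))
  dn <- likelihood_logpdf(x, 1.3, 0, likelihood_spec("normal"))
  expect_lt(max(abs(dt_big - dn)), 1e-3)
  # explicit lgamma form as an independent oracle at z = 3, nu = 32
  nu <- 32; sig <- 1.7; z <- 3
  oracle <- lgamma((nu + 1) / 2) - lgamma(nu / 2) -
    0.5 * log(nu * pi) - ((nu + 1) / 2) * log1p(z^2 / nu) - log(sig)
  expect_equal(likelihood_logpdf(z * sig, sig, 0,
                                 likelihood_spec("studentt", nu)),
               oracle, tolerance = 1e-12)
  expect_error(likelihood_spec("studentt", 0), "positive")
})

test_that("the harmonic forward model sums member contributions", {
  expect_equal(predicted_intensity(1, 2), 4)
  expect_equal(predicted_intensity(c(1, 0.5), c(2, 2)), 6)
  set.seed(3)
  s <- runif(9); Fv <- rexp(9); grp <- rep(1:3, each = 3)
  got <- predicted_intensity(s, Fv, grp)
  oracle <- vapply(1:3, function(g) {
    tot <- 0
    for (i in which(grp == g)) tot <- tot + s[i] * Fv[i]^2
    tot
  }, numeric(1))
  expect_equal(unname(got), oracle)
  expect_error(predicted_intensity(numeric(0), numeric(0)), "non-empty")
})

test_that("test splitting is seeded, sized, and frozen", {
  tb <- refl_table(random_refl_df(10000))
  t0 <- split_test(tb, 0, seed = 1)
  expect_equal(sum(t0$is_test), 0)
  t1 <- split_test(tb, 0.1, seed = 1)
  ci <- qbinom(c(0.0005, 0.9995), 10000, 0.1)
  expect_gte(sum(t1$is_test), ci[1])
  expect_lte(sum(t1$is_test), ci[2])
  t2 <- split_test(tb, 0.1, seed = 1)
  expect_identical(t1$is_test, t2$is_test)
  expect_error(split_test(tb, 0.6), "0.5")
})

test_that("ELBO estimator variance halves when samples double", {
  sc <- tiny_scene()
  fit <- vi_merge(sc$table, sc$crystal, prior = sc$prior,
                  scale_config = scale_model_config(
                    mlp_layers = 2, mlp_width = 4, image_layers = 0,
                    positional_encoding_frequencies = 2),
                  steps = 60, learning_rate = 0.02, seed = 3,
                  keep_data = TRUE)
  set.seed(10)
  e1 <- replicate(200, elbo(fit, 1))
  e2 <- replicate(200, elbo(fit, 2))
  ratio <- var(e1) / var(e2)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("with a flat likelihood the optimized ELBO attains the quadrature KL bound", {
  # one reflection, one nearly uninformative observation: the ELBO optimum
  # is the constant data term minus the minimal KL(q || Wilson prior) over
  # the log-normal family, computed here by an independent quadrature oracle
  df <- data.frame(dataset = 0L, image = 0L, h = 2L, k = 1L, l = 1L,
                   I = 1, SigI = 1e6)
  cr <- crystal_form(c(10, 10, 10, 90, 90, 90), "P1", dmin = 2)
  fit <- vi_merge(refl_table(df), cr, likelihood = likelihood_spec("normal"),
                  mode = "mono", scale = "fixed", steps = 3000,
                  learning_rate = 0.02, n_mc_samples = 8, seed = 2,
                  keep_data = TRUE)
  const <- dnorm(1, 0, 1e6, log = TRUE)
  kl_of <- function(par) {
    m <- par[1]; s <- exp(par[2])
    integrate(function(F) {
      q <- dlnorm(F, m, s)
      lq <- dlnorm(F, m, s, log = TRUE)
      q * (lq - wilson_logpdf(F, FALSE, 1, 1))
    }, 0, Inf, rel.tol = 1e-10)$value
  }
  opt <- optim(c(0, log(0.5)), kl_of)
  e <- mean(replicate(50, elbo(fit, 8)))
  expect_equal(e, const - opt$value, tolerance = 0.02)
  expect_lte(e, const + 0.01)
})

test_that("single-reflection fit recovers the conjugate Gaussian posterior", {
  mu0 <- 10; tau0 <- 2; sigma <- 1; n <- 4
  set.seed(42)
  y <- rnorm(n, 9, sigma)
  post_var <- 1 / (1 / tau0^2 + n / sigma^2)
  post_mean <- post_var * (mu0 / tau0^2 + sum(y) / sigma^2)
  df <- data.frame(dataset = 0L, image = seq_len(n) - 1L, h = 1L, k = 0L,
                   l = 0L, I = y, SigI = sigma)
  cr <- crystal_form(c(10, 10, 10, 90, 90, 90), "P1", dmin = 2)
  fit <- vi_merge(refl_table(df), cr,
                  prior = prior_spec(family = "gaussian", mean = mu0,
                                     sd = tau0),
                  likelihood = likelihood_spec("normal"), mode = "mono",
                  scale = "fixed", forward = "amplitude", steps = 2500,
                  learning_rate = 0.015, n_mc_samples = 16,
                  average_frac = 0.4, seed = 5)
  m <- coef(fit)
  expect_lt(abs(m$F - post_mean) / post_mean, 0.02)
  expect_lt(abs(m$SigF - sqrt(post_var)) / sqrt(post_var), 0.02)
  # ELBO climbs monotonically through the transient (smoothed over 50-step
  # windows), then plateaus near the optimum
  tr <- fit$elbo_trace
  blocks <- tapply(tr, (seq_along(tr) - 1) %/% 50, mean)
  expect_true(all(diff(blocks[1:5]) > 0))
  expect_gt(mean(tail(blocks, 5)), blocks[1] + 0.9 * (max(blocks) -
                                                        blocks[1]))
})

test_that("fits are bitwise reproducible given the seed", {
  sc <- tiny_scene()
  f1 <- vi_merge(sc$table, sc$crystal, prior = sc$prior,
                 scale_config = scale_model_config(
                   mlp_layers = 2, mlp_width = 4, image_layers = 1,
                   positional_encoding_frequencies = 2),
                 steps = 80, learning_rate = 0.02, seed = 31,
                 test_fraction = 0.1)
  f2 <- vi_merge(sc$table, sc$crystal, prior = sc$prior,
                 scale_config = scale_model_config(
                   mlp_layers = 2, mlp_width = 4, image_layers = 1,
                   positional_encoding_frequencies = 2),
                 steps = 80, learning_rate = 0.02, seed = 31,
                 test_fraction = 0.1)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$predictions, f2$predictions)
})

test_that("poly mode demands wavelengths and prior coverage is checked", {
  df <- random_refl_df(50)
  df$Wavelength <- NULL
  cr <- crystal_form(c(10, 10, 10, 90, 90, 90), "P1", dmin = 2)
  expect_error(vi_merge(refl_table(df), cr, mode = "poly"), "Wavelength")
  sc <- tiny_scene()
  expect_error(vi_merge(sc$table, sc$crystal, prior = prior_spec(NA, 0)),
               "datasets")
})

test_that("clean simulator data is recovered almost exactly", {
  sc <- fixture("scene_clean", {
    cr <- crystal_form(c(16, 16, 22, 90, 90, 120), "P3121", dmin = 2)
    set.seed(6)
    model <- toy_model(data.frame(x = runif(8), y = runif(8), z = runif(8),
                                  weight = 5))
    truth <- generate_ground_truth(cr, 2, 0.99, model, 0.2, seed = 6)
    sim <- simulate_observations(truth, spectrum_model(bandwidth_frac = 0),
                                 30, 40, c(0.5, 2), 0.01, 0.5, 0, 10, 0, 0,
                                 detector_modulation = 0, seed = 7)
    list(crystal = cr, truth = sim$truth, table = sim$table)
  })
  fit <- vi_merge(sc$table, sc$crystal,
                  prior = prior_spec_reference(2, 0.99),
                  scale_config = desk_scale_config(), mode = "mono",
                  steps = 500, learning_rate = 0.03, seed = 13)
  for (d in 0:1) expect_gt(truth_cor(fit, sc, d), 0.99)
})

test_that("methods on the fit object are coherent", {
  fit <- small_fit(1)
  expect_s3_class(coef(fit), "merged_sf")
  expect_output(print(fit), "Variational merge")
  expect_output(print(summary(fit)), "CC_pred")
  r <- residuals(fit)
  expect_equal(length(r), nrow(small_scene(1)$table))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(coef(fit)), 3))
  expect_true(all(sims > 0))
  expect_equal(fitted(fit), predict(fit)$predicted_mean_I)
})
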