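# Variational-inference merging engine. Jointly estimates merged structure
# factor amplitudes (one posterior per dataset and ASU Miller index) and the
# neural scale model by maximizing a reparameterized Monte-Carlo estimate of
# the evidence lower bound with Adam. The surrogate posterior over each
# amplitude is log-normal (strictly positive, trivially reparameterized as
# F = exp(m + s * eps)); the prior is Wilson for root datasets and the
# conditional double-Wilson density for children, with the parent amplitude
# sampled jointly from its own surrogate.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a frozen cross-validation split
#'
#' Flags a random per-observation test partition, reproducible by seed. Test
#' observations are excluded from the training gradient but still receive
#' prediction records.
#'
#' @param table A [refl_table()].
#' @param test_fraction Fraction in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return The table with an `is_test` column.
#' @export
split_test <- function(table, test_fraction, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction < 0.5)
  set.seed(seed)
  df <- as.data.frame(table)
  df$is_test <- stats::runif(nrow(df)) < test_fraction
  refl_table(df, metadata_keys = attr(table, "metadata_keys"))
}

# One reparameterized Monte-Carlo sample of the ELBO and its gradients in the
# surrogate parameters (m, t) and, when the scale model is learned, the
# network parameters. Noise is drawn from the current RNG stream, so fixing
# the seed gives common random numbers across calls (used by the
# finite-difference gradient checks). The objective contains exactly three
# terms: expected log-likelihood over training observations, expected
# log-prior over amplitudes, and the surrogate entropy; no penalty on
# network parameters or outputs exists anywhere.
.vi_grads <- function(ctx, qpar, p) {
  nq <- ctx$nq
  eps_q <- stats::rnorm(nq)
  sdl <- exp(qpar$t)
  F <- exp(qpar$m + sdl * eps_q)
  if (ctx$learned) {
    eta <- stats::rnorm(ctx$nrows)
    fw <- .scale_fwd(ctx$Z, ctx$img_idx, ctx$cfg_used, p, cache = TRUE)
    sigs <- exp(fw$log_sigma)
    s_row <- exp(fw$mu + sigs * eta)
  } else {
    s_row <- rep(1, ctx$nrows)
  }
  Fq_row <- F[ctx$qi]^ctx$pow
  I_pred <- rowsum(s_row * Fq_row, ctx$obs_id)[, 1L]
  ll <- likelihood_logpdf(ctx$I, ctx$SigI, I_pred, ctx$likelihood)
  gI <- .likelihood_grad(ctx$I, ctx$SigI, I_pred, ctx$likelihood)
  gI[!ctx$train_obs] <- 0
  data_term <- sum(ll[ctx$train_obs])
  lp <- numeric(nq)
  gF <- numeric(nq)
  if (ctx$prior$family == "gaussian") {
    lp <- stats::dnorm(F, ctx$prior$mean, ctx$prior$sd, log = TRUE)
    gF <- -(F - ctx$prior$mean) / ctx$prior$sd^2
  } else {
    Sgv <- rep_len(ctx$Sg, nq)
    root <- !ctx$is_child
    lp[root] <- wilson_logpdf(F[root], ctx$centric[root],
                              ctx$epsilonq[root] * Sgv[root], 1)
    gF[root] <- .wilson_grad(F[root], ctx$centric[root],
                             ctx$epsilonq[root] * Sgv[root], 1)
    if (any(ctx$is_child)) {
      for (rr in split(which(ctx$is_child), ctx$r_q[ctx$is_child])) {
        r_val <- ctx$r_q[rr[1L]]
        Fp <- F[ctx$parent_qi[rr]]
        lp[rr] <- double_wilson_logpdf(F[rr], Fp, r_val, ctx$centric[rr],
                                       ctx$epsilonq[rr] * Sgv[rr], 1)
        gr <- .double_wilson_grad(F[rr], Fp, r_val, ctx$centric[rr],
                                  ctx$epsilonq[rr] * Sgv[rr], 1)
        gF[rr] <- gF[rr] + gr$child
        gp_acc <- rowsum(gr$parent, ctx$parent_qi[rr])
        tgt <- as.integer(rownames(gp_acc))
        gF[tgt] <- gF[tgt] + gp_acc[, 1L]
      }
    }
  }
  entropy <- sum(qpar$m + qpar$t) + nq * 0.5 * log(2 * pi * exp(1))
  g_row <- gI[ctx$obs_id] * s_row * ctx$pow * F[ctx$qi]^(ctx$pow - 1)
  gF_lik <- numeric(nq)
  acc <- rowsum(g_row, ctx$qi)
  gF_lik[as.integer(rownames(acc))] <- acc[, 1L]
  gFtot <- gF_lik + gF
  out <- list(elbo = data_term + sum(lp) + entropy,
              g_m = gFtot * F + 1,
              g_t = gFtot * F * eps_q * sdl + 1)
  if (ctx$learned) {
    g_srow <- gI[ctx$obs_id] * Fq_row
    out$g_p <- .scale_bwd(ctx$Z, ctx$img_idx, ctx$cfg_used, p, fw$acts,
                          g_srow * s_row, g_srow * s_row * eta * sigs)
  }
  out
}

# gcd of each row of an integer matrix
.row_gcd <- function(H) {
  g <- abs(H[, 1L])
  for (j in 2:3) {
    b <- abs(H[, j])
    nz <- TRUE
    while (any(nz)) {
      nz <- b != 0L
      if (!any(nz)) break
      r <- g[nz] %% b[nz]
      g[nz] <- b[nz]
      b[nz] <- r
    }
  }
  g
}

# Build the member table: one row per (observation, harmonic member). In
# poly mode every harmonic order whose wavelength falls inside the beam
# window and whose resolution passes the cutoff becomes a member; in mono
# mode each observation keeps only its recorded index.
.build_members <- function(df, crystal, mode, lambda_range, nmax = 8L) {
  n <- nrow(df)
  H <- cbind(df$h, df$k, df$l)
  if (mode == "mono") {
    d <- resolution(H, crystal$cell)
    return(data.frame(obs = seq_len(n), n_order = 1L,
                      h = H[, 1L], k = H[, 2L], l = H[, 3L],
                      lambda = if ("Wavelength" %in% names(df))
                        df$Wavelength else NA_real_,
                      d = d, primary = TRUE))
  }
  g <- .row_gcd(H)
  ray <- H / g
  lambda1 <- g * df$Wavelength
  nmax <- max(nmax, g) # the recorded order always participates
  out <- vector("list", nmax)
  for (nn in seq_len(nmax)) {
    lam <- lambda1 / nn
    Hn <- ray * nn
    d <- resolution(Hn, crystal$cell)
    keep <- lam >= lambda_range[1L] & lam <= lambda_range[2L] &
      d >= crystal$dmin
    keep <- keep | (nn == g) # the recorded reflection always participates
    if (!any(keep)) next
    out[[nn]] <- data.frame(obs = which(keep), n_order = nn,
                            h = Hn[keep, 1L], k = Hn[keep, 2L],
                            l = Hn[keep, 3L], lambda = lam[keep],
                            d = d[keep], primary = nn == g[keep])
  }
  mem <- do.call(rbind, out)
  mem[order(mem$obs, mem$n_order), ]
}

#' Merge reflections by variational inference
#'
#' The central model-fitting function: scales and merges one or more
#' datasets of unmerged reflection intensities, returning a posterior
#' distribution over merged structure-factor amplitudes per dataset together
#' with the fitted systematic-error model. Amplitudes are normalized to
#' Wilson scale Sigma = 1; resolution-dependent falloff and the global
#' intensity scale are absorbed by the scale model, which receives 1/d^2 as
#' a metadatum.
#'
#' @param table A [refl_table()] spanning all datasets (ASU mapping and
#'   indexing-ambiguity resolution are applied internally / beforehand as
#'   needed; see [resolve_indexing_ambiguity()]).
#' @param crystal A [crystal_form()].
#' @param prior A [prior_spec()]; default: independent Wilson priors.
#' @param likelihood A [likelihood_spec()]; default robust Student's t with
#'   nu = 32.
#' @param scale_config A [scale_model_config()].
#' @param mode `"poly"` (harmonic deconvolution, requires wavelengths) or
#'   `"mono"` (each observation is a single reflection).
#' @param steps Number of Adam steps (full-batch).
#' @param learning_rate Adam step size.
#' @param n_mc_samples Monte-Carlo samples per ELBO estimate (default 1;
#'   sampling is reparameterized).
#' @param test_fraction If positive and the table has no frozen split, a
#'   test partition is assigned with [split_test()].
#' @param seed Integer seed; fits are reproducible given the seed.
#' @param lambda_range Beam wavelength window for harmonic enumeration;
#'   default the observed wavelength range.
#' @param scale `"learned"` (neural scale model) or `"fixed"` (all scales
#'   frozen at 1; used for validation against conjugate posteriors).
#' @param forward `"intensity"` (I = sum s F^2, the physical forward model)
#'   or `"amplitude"` (I = sum s F, a linear relaxation for validation).
#' @param average_frac Fraction of final steps over which the surrogate
#'   parameters are Polyak-averaged to remove Monte-Carlo jitter.
#' @param n_pred_samples Posterior samples used for prediction records.
#' @param keep_data Keep the internal design (features, index maps) in the
#'   returned object, enabling [elbo()] recomputation.
#' @return An object of class `"vi_merge"`; see [coef.vi_merge()],
#'   [predict.vi_merge()], [residuals.vi_merge()], [plot.vi_merge()].
#' @export
vi_merge <- function(table, crystal, prior = NULL,
                     likelihood = likelihood_spec("studentt", 32),
                     scale_config = scale_model_config(),
                     mode = c("poly", "mono"),
                     steps = 10000L, learning_rate = 1e-3,
                     n_mc_samples = 1L, test_fraction = 0, seed = 1L,
                     lambda_range = NULL,
                     scale = c("learned", "fixed"),
                     forward = c("intensity", "amplitude"),
                     average_frac = 0.25, n_pred_samples = 32L,
                     keep_data = FALSE) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  forward <- match.arg(forward)
  stopifnot(inherits(crystal, "crystal_form"))
  t0 <- proc.time()[["elapsed"]]
  df <- as.data.frame(table)
  n_datasets <- max(df$dataset) + 1L
  if (is.null(prior)) prior <- prior_spec(rep(NA_integer_, n_datasets),
                                          rep(0, n_datasets))
  stopifnot(inherits(prior, "prior_spec"), inherits(likelihood,
                                                    "likelihood_spec"))
  if (length(prior$parents) < n_datasets) {
    stop("prior_spec covers ", length(prior$parents), " datasets but the ",
         "table has ", n_datasets)
  }
  if (mode == "poly" && !("Wavelength" %in% names(df))) {
    stop("poly mode requires a Wavelength column; use mode = 'mono'")
  }
  set.seed(seed)
  if (test_fraction > 0 && !("is_test" %in% names(df))) {
    df$is_test <- stats::runif(nrow(df)) < test_fraction
  }
  is_test <- df$is_test %||% rep(FALSE, nrow(df))
  if (mode == "poly" && is.null(lambda_range)) {
    lambda_range <- range(df$Wavelength)
  }

  # --- members and surrogate index set ---------------------------------------
  mem <- .build_members(df, crystal, mode, lambda_range)
  asu <- map_to_asu(cbind(mem$h, mem$k, mem$l), crystal$spacegroup)
  mem_ds <- df$dataset[mem$obs]
  qkey <- .miller_key(asu$h, asu$k, asu$l, mem_ds)
  qu <- !duplicated(qkey)
  qtab <- data.frame(dataset = mem_ds[qu], h = asu$h[qu], k = asu$k[qu],
                     l = asu$l[qu], centric = asu$centric[qu],
                     epsilon = asu$epsilon[qu], key = qkey[qu])
  qi <- match(qkey, qtab$key)
  nq <- nrow(qtab)
  nobs <- nrow(df)
  obs_id <- mem$obs
  test_row <- is_test[obs_id]

  # parent surrogate index per q entry (NA -> treated as a root)
  pds <- prior$parents[qtab$dataset + 1L]
  pkey <- .miller_key(qtab$h, qtab$k, qtab$l, pds)
  parent_qi <- ifelse(is.na(pds), NA_integer_, match(pkey, qtab$key))
  r_q <- ifelse(is.na(parent_qi), 0, prior$r[qtab$dataset + 1L])
  is_child <- !is.na(parent_qi) & r_q > 0
  Sg <- prior$wilson_sigma

  # --- naive merge initialization --------------------------------------------
  prim <- mem$primary & !test_row
  wi <- 1 / df$SigI[obs_id[prim]]^2
  num <- rowsum(df$I[obs_id[prim]] * wi, qi[prim])
  den <- rowsum(wi, qi[prim])
  Iw <- rep(NA_real_, nq)
  Iw[as.integer(rownames(num))] <- num[, 1L] / den[, 1L]
  medI <- stats::median(Iw[is.finite(Iw) & Iw > 0], na.rm = TRUE)
  if (!is.finite(medI) || medI <= 0) medI <- 1
  Iw[!is.finite(Iw)] <- medI
  F0 <- sqrt(pmax(Iw, medI * 1e-3))
  Sg_q <- Sg
  if (prior$family == "wilson") {
    F0 <- F0 / sqrt(mean(F0^2 / qtab$epsilon) / Sg)
    # shell-binned Wilson scale: the expected intensity falls with
    # resolution (Debye-Waller), and a flat Sigma would systematically
    # over-shrink low-resolution differences under a high-r prior
    q_d <- resolution(as.matrix(qtab[, c("h", "k", "l")]), crystal$cell)
    nb <- max(1L, min(10L, nq %/% 50L))
    qs <- unique(stats::quantile(q_d, seq(0, 1, length.out = nb + 1L)))
    qs[1L] <- qs[1L] - 1e-9
    bin <- cut(q_d, qs, labels = FALSE)
    Sb <- tapply(F0^2 / qtab$epsilon, bin, mean)
    Sg_q <- pmax(as.numeric(Sb[as.character(bin)]), 1e-6 * Sg)
  }
  sdlog0 <- 0.3
  q_m <- log(F0) - sdlog0^2 / 2
  q_t <- rep(log(sdlog0), nq)

  # --- features and scale model ----------------------------------------------
  pow <- if (forward == "intensity") 2 else 1
  learned <- scale == "learned"
  img_key <- df$dataset * 1e6 + df$image
  if (learned) {
    meta <- data.frame(row_id = seq_along(obs_id))
    for (v in c("X", "Y")) if (v %in% names(df)) meta[[v]] <- df[[v]][obs_id]
    meta$s2 <- 1 / mem$d^2
    if (!all(is.na(mem$lambda))) meta$Wavelength <- mem$lambda
    keys_used <- intersect(scale_config$metadata_keys, names(meta))
    if (length(keys_used) == 0L) stop("no usable metadata keys")
    cfg_used <- scale_config
    cfg_used$metadata_keys <- keys_used
    feats <- .build_features(meta, cfg_used)
    Z <- feats$features
    images <- sort(unique(img_key))
    img_idx <- if (scale_config$image_layers > 0L) {
      match(img_key[obs_id], images)
    } else NULL
    p <- .scale_init(cfg_used, ncol(Z), images, seed = seed)
    # calibrate the head bias so initial predicted intensities match the data
    Ip0 <- rowsum(F0[qi]^pow, obs_id)[, 1L]
    ok <- Ip0 > 0 & df$I > 0 & !is_test
    if (any(ok)) p$b_mu <- log(stats::median(df$I[ok] / Ip0[ok]))
    opt_p <- .adam_init(p)
  } else {
    Z <- NULL; img_idx <- NULL; p <- NULL; cfg_used <- NULL
    feats <- list(stats = NULL)
  }
  qpar <- list(m = q_m, t = q_t)
  opt_q <- .adam_init(qpar)

  # --- optimization ----------------------------------------------------------
  nrows <- nrow(mem)
  elbo_trace <- numeric(steps)
  bad_streak <- 0L
  avg_from <- max(1L, steps - ceiling(average_frac * steps) + 1L)
  avg_m <- numeric(nq); avg_t <- numeric(nq); avg_n <- 0L
  ctx <- list(Z = Z, qi = qi, obs_id = obs_id, img_idx = img_idx,
              centric = qtab$centric, epsilonq = qtab$epsilon,
              r_q = r_q, parent_qi = parent_qi, is_child = is_child,
              train_obs = !is_test, pow = pow, I = df$I, SigI = df$SigI,
              nrows = nrows, nq = nq, learned = learned,
              cfg_used = cfg_used, prior = prior, likelihood = likelihood,
              Sg = Sg_q)

  for (step in seq_len(steps)) {
    g_m <- numeric(nq); g_t <- numeric(nq); g_p <- NULL
    elbo_val <- 0
    for (mc in seq_len(n_mc_samples)) {
      gr1 <- .vi_grads(ctx, qpar, p)
      elbo_val <- elbo_val + gr1$elbo
      g_m <- g_m + gr1$g_m
      g_t <- g_t + gr1$g_t
      if (learned) {
        if (is.null(g_p)) g_p <- gr1$g_p
        else for (nm in names(gr1$g_p)) {
          g_p[[nm]] <- g_p[[nm]] + gr1$g_p[[nm]]
        }
      }
    }
    inv <- 1 / n_mc_samples
    elbo_val <- elbo_val * inv
    elbo_trace[step] <- elbo_val
    if (!is.finite(elbo_val)) {
      bad_streak <- bad_streak + 1L
      if (bad_streak >= 100L) {
        stop("optimization diverged: non-finite ELBO for 100 consecutive ",
             "steps (step ", step, "); try a smaller learning rate")
      }
    } else bad_streak <- 0L
    g_m <- g_m * inv; g_t <- g_t * inv
    g_m[!is.finite(g_m)] <- 0; g_t[!is.finite(g_t)] <- 0
    upd <- .adam_step(qpar, list(m = g_m, t = g_t), opt_q, learning_rate,
                      step)
    qpar <- upd$par; opt_q <- upd$st
    if (learned) {
      for (nm in names(g_p)) {
        g_p[[nm]] <- g_p[[nm]] * inv
        g_p[[nm]][!is.finite(g_p[[nm]])] <- 0
      }
      updp <- .adam_step(p, g_p, opt_p, learning_rate, step)
      imgs_attr <- attr(p, "images")
      p <- updp$par; opt_p <- updp$st
      attr(p, "images") <- imgs_attr
    }
    if (step >= avg_from) {
      avg_m <- avg_m + qpar$m; avg_t <- avg_t + qpar$t; avg_n <- avg_n + 1L
    }
  }
  if (avg_n > 0L) {
    qpar$m <- avg_m / avg_n
    qpar$t <- avg_t / avg_n
  }

  # --- outputs ----------------------------------------------------------------
  sdl <- exp(qpar$t)
  Fmean <- exp(qpar$m + sdl^2 / 2)
  Fsd <- Fmean * sqrt(expm1(sdl^2))
  merged <- merged_sf(data.frame(dataset = qtab$dataset, h = qtab$h,
                                 k = qtab$k, l = qtab$l, F = Fmean,
                                 SigF = pmax(Fsd, 1e-12)))

  # prediction records and fitted per-observation scale
  set.seed(seed + 777L)
  psum <- numeric(nobs); psq <- numeric(nobs)
  if (learned) {
    fw <- .scale_fwd(Z, img_idx, cfg_used, p)
    mu_row <- fw$mu; sigs <- exp(fw$log_sigma)
  }
  for (s in seq_len(n_pred_samples)) {
    eps_q <- stats::rnorm(nq)
    F <- exp(qpar$m + sdl * eps_q)
    s_row <- if (learned) exp(mu_row + sigs * stats::rnorm(nrows))
             else rep(1, nrows)
    I_pred <- rowsum(s_row * F[qi]^pow, obs_id)[, 1L]
    psum <- psum + I_pred
    psq <- psq + I_pred^2
  }
  pred_mean <- psum / n_pred_samples
  pred_var <- pmax(psq / n_pred_samples - pred_mean^2, 0)
  predictions <- data.frame(
    dataset = df$dataset, image = df$image, h = df$h, k = df$k, l = df$l,
    I = df$I, SigI = df$SigI,
    predicted_mean_I = pred_mean,
    predicted_std_I = pmax(sqrt(pred_var), 1e-12),
    is_test = is_test
  )
  obs_scale <- NULL
  if (learned) {
    pr <- which(mem$primary)
    obs_scale <- data.frame(dataset = df$dataset[obs_id[pr]],
                            image = df$image[obs_id[pr]],
                            wavelength = mem$lambda[pr],
                            scale_location = exp(mu_row[pr]))
  }
  n_members <- tabulate(obs_id, nbins = nobs)

  state <- list(q = qpar, params = p, opt_q = opt_q,
                opt_p = if (learned) opt_p else NULL,
                step = steps, seed = seed, feature_stats = feats$stats)
  if (keep_data) {
    state$data <- ctx
    state$qtab <- qtab
    state$mem <- mem
  }
  structure(
    list(merged = merged, predictions = predictions, state = state,
         elbo_trace = elbo_trace, crystal = crystal, prior = prior,
         likelihood = likelihood, scale_config = scale_config, mode = mode,
         forward = forward, scale = scale, obs_scale = obs_scale,
         n_members = n_members, n_datasets = n_datasets,
         steps = steps, learning_rate = learning_rate, seed = seed,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "vi_merge"
  )
}

#' Recompute a Monte-Carlo ELBO estimate for a fitted model
#'
#' Unbiased reparameterized estimate of the evidence lower bound,
#' E_q[log p(data | F, scales)] + E_q[log p(F)] + H(q), at the fitted
#' surrogate. The fit must have been run with `keep_data = TRUE`.
#'
#' @param fit A [vi_merge()] object.
#' @param n_mc_samples Monte-Carlo samples.
#' @param seed Optional seed.
#' @return Scalar ELBO estimate.
#' @export
elbo <- function(fit, n_mc_samples = 1L, seed = NULL) {
  stopifnot(inherits(fit, "vi_merge"))
  ctx <- fit$state$data
  if (is.null(ctx)) stop("fit was not run with keep_data = TRUE")
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(n_mc_samples), function(i) {
    .vi_grads(ctx, fit$state$q, fit$state$params)$elbo
  }, numeric(1)))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.vi_merge <- function(x, ...) {
  cat("Variational merge (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  %d dataset(s), %d merged amplitudes, %d observations\n",
              x$n_datasets, nrow(x$merged), nrow(x$predictions)))
  cat(sprintf("  likelihood: %s%s; prior: %s\n", x$likelihood$family,
              if (x$likelihood$family == "studentt")
                sprintf(" (nu = %g)", x$likelihood$dof) else "",
              if (any(x$prior$r > 0))
                sprintf("double-Wilson (r = %s)",
                        paste(unique(x$prior$r[x$prior$r > 0]),
                              collapse = ", "))
              else x$prior$family))
  cat(sprintf("  %d steps, final ELBO %.1f (%.1fs)\n", x$steps,
              mean(utils::tail(x$elbo_trace, 50L)), x$elapsed))
  invisible(x)
}

#' @export
summary.vi_merge <- function(object, ...) {
  m <- object$merged
  per <- do.call(rbind, lapply(split(m, m$dataset), function(s) {
    data.frame(dataset = s$dataset[1L], n = nrow(s),
               mean_F = mean(s$F), mean_SigF = mean(s$SigF))
  }))
  cc <- tryCatch(cc_pred(object$predictions, "pearson_weighted"),
                 error = function(e) NULL)
  out <- list(per_dataset = per, cc_pred = cc,
              elbo = mean(utils::tail(object$elbo_trace, 50L)),
              call_mode = object$mode)
  class(out) <- "summary.vi_merge"
  out
}

#' @export
print.summary.vi_merge <- function(x, ...) {
  cat("Per-dataset merged amplitudes:\n")
  print(x$per_dataset, row.names = FALSE)
  if (!is.null(x$cc_pred)) {
    cat(sprintf("CC_pred (weighted Pearson): train %.4f / test %s\n",
                x$cc_pred["train"],
                ifelse(is.na(x$cc_pred["test"]), "-",
                       sprintf("%.4f", x$cc_pred["test"]))))
  }
  cat(sprintf("final ELBO: %.1f\n", x$elbo))
  invisible(x)
}

#' Merged amplitudes of a variational merge
#' @param object A [vi_merge()] fit.
#' @param ... Unused.
#' @return The [merged_sf()] table of posterior means/stds.
#' @export
coef.vi_merge <- function(object, ...) object$merged

#' Posterior predictions for the training observations
#' @param object A [vi_merge()] fit.
#' @param ... Unused.
#' @return Data frame of per-observation predicted intensity mean/std with
#'   the train/test flag (the prediction records).
#' @export
predict.vi_merge <- function(object, ...) object$predictions

#' @export
fitted.vi_merge <- function(object, ...) object$predictions$predicted_mean_I

#' Standardized intensity residuals
#' @param object A [vi_merge()] fit.
#' @param ... Unused.
#' @return (I_obs - I_pred) / SigI per observation.
#' @export
residuals.vi_merge <- function(object, ...) {
  with(object$predictions, (I - predicted_mean_I) / SigI)
}

#' Draw merged-amplitude posterior samples
#' @param object A [vi_merge()] fit.
#' @param nsim Number of posterior draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Matrix (amplitudes x nsim) of posterior samples, rows aligned
#'   with `coef(object)`.
#' @export
simulate.vi_merge <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  q <- object$state$q
  sdl <- exp(q$t)
  matrix(exp(stats::rnorm(length(q$m) * nsim, mean = rep(q$m, nsim),
                          sd = rep(sdl, nsim))),
         ncol = nsim)
}

#' Diagnostic plots for a variational merge
#'
#' Left: ELBO optimization trace. Right: observed vs posterior-predicted
#' intensities colored by train/test partition.
#' @param x A [vi_merge()] fit.
#' @param ... Passed to plotting functions.
#' @export
plot.vi_merge <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$elbo_trace, type = "l", xlab = "step", ylab = "ELBO",
                 main = "optimization trace", ...)
  pr <- x$predictions
  graphics::plot(pr$predicted_mean_I, pr$I,
                 col = ifelse(pr$is_test, 2L, 1L), pch = 16L, cex = 0.4,
                 xlab = "predicted intensity", ylab = "observed intensity",
                 main = "predictions", ...)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}
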