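# The learnable systematic-error (scale) model: metadata standardization,
# sinusoidal positional encoding, a residual multilayer perceptron shared
# across all observations, per-image affine layers with separate parameters
# for each diffraction image, and a log-normal output head. Forward and
# backward passes are written directly in base R; gradients are exact and are
# checked against finite differences in the test suite. No prior or penalty
# of any kind is placed on the network parameters or outputs: the training
# objective contains likelihood, amplitude-prior, and entropy terms only.

#' Scale-model configuration
#'
#' @param metadata_keys Metadata columns fed to the network. `"X"`, `"Y"`
#'   are detector coordinates, `"Wavelength"` the assigned peak wavelength
#'   (member-specific for harmonics), and `"s2"` the inverse squared
#'   resolution 1/d^2 (always computable; absorbs Wilson falloff).
#' @param mlp_layers Trunk depth (default 20).
#' @param mlp_width Trunk width (default 10).
#' @param image_layers Number of per-image affine layers appended after the
#'   shared trunk (default 2; 0 disables local parameters).
#' @param positional_encoding_keys Subset of `metadata_keys` expanded with
#'   sinusoidal features (default detector coordinates).
#' @param positional_encoding_frequencies Number of octave frequencies L in
#'   the encoding (default 8; 0 disables).
#' @return Object of class `"scale_model_config"`.
#' @export
scale_model_config <- function(metadata_keys = c("X", "Y", "s2", "Wavelength"),
                               mlp_layers = 20L, mlp_width = 10L,
                               image_layers = 2L,
                               positional_encoding_keys = c("X", "Y"),
                               positional_encoding_frequencies = 8L) {
  stopifnot(mlp_layers >= 1L, mlp_width >= 1L, image_layers >= 0L,
            positional_encoding_frequencies >= 0L)
  if (!all(positional_encoding_keys %in% metadata_keys)) {
    positional_encoding_keys <- intersect(positional_encoding_keys,
                                          metadata_keys)
  }
  structure(
    list(metadata_keys = metadata_keys,
         mlp_layers = as.integer(mlp_layers),
         mlp_width = as.integer(mlp_width),
         image_layers = as.integer(image_layers),
         positional_encoding_keys = positional_encoding_keys,
         positional_encoding_frequencies =
           as.integer(positional_encoding_frequencies)),
    class = "scale_model_config"
  )
}

#' Standardize metadata columns
#'
#' Shifts and scales each selected column to mean 0, standard deviation 1
#' over the rows provided, returning the fitted statistics so held-out
#' observations can be transformed identically. Constant columns are dropped
#' with a warning.
#'
#' @param df Data frame (e.g. a [refl_table()]).
#' @param keys Columns to standardize; must exist in `df` with at least two
#'   distinct values.
#' @param stats Optional previously fitted statistics (as returned in
#'   `$stats`); when given, they are applied unchanged.
#' @return List with `features` (numeric matrix) and `stats` (data frame of
#'   center/scale per retained column).
#' @export
standardize <- function(df, keys, stats = NULL) {
  df <- as.data.frame(df)
  missing_keys <- setdiff(keys, names(df))
  if (length(missing_keys) > 0L) {
    stop("metadata key(s) not present: ", paste(missing_keys, collapse = ", "))
  }
  if (is.null(stats)) {
    center <- vapply(keys, function(k) mean(df[[k]]), numeric(1))
    scale <- vapply(keys, function(k) stats::sd(df[[k]]), numeric(1))
    keep <- is.finite(scale) & scale > 0
    if (any(!keep)) {
      warning("dropping constant metadata column(s): ",
              paste(keys[!keep], collapse = ", "))
    }
    stats <- data.frame(key = keys[keep], center = center[keep],
                        scale = scale[keep], stringsAsFactors = FALSE)
  }
  X <- vapply(seq_len(nrow(stats)), function(j) {
    (df[[stats$key[j]]] - stats$center[j]) / stats$scale[j]
  }, numeric(nrow(df)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(df))
  colnames(X) <- stats$key
  list(features = X, stats = stats)
}

#' Sinusoidal positional encoding
#'
#' Maps each input value x to `[x, sin(2^k pi x), cos(2^k pi x)]` for
#' k = 0..L-1, so the network can represent high-frequency spatial variation
#' (detector shadows, panel gaps). Output dimensionality is 1 + 2L per input
#' column.
#'
#' @param x Numeric vector or matrix of (standardized) values.
#' @param L Number of octave frequencies (>= 0; 0 passes the raw value
#'   through).
#' @return Numeric matrix of encoded features.
#' @export
positional_encode <- function(x, L) {
  stopifnot(L >= 0)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (L == 0L) return(x)
  blocks <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    enc <- matrix(0, nrow = length(v), ncol = 1L + 2L * L)
    enc[, 1L] <- v
    for (k in seq_len(L) - 1L) {
      enc[, 2L + 2L * k] <- sin(2^k * pi * v)
      enc[, 3L + 2L * k] <- cos(2^k * pi * v)
    }
    cn <- colnames(x)[j]
    if (!is.null(cn)) {
      colnames(enc) <- c(cn, as.vector(rbind(
        paste0(cn, "_sin", seq_len(L) - 1L),
        paste0(cn, "_cos", seq_len(L) - 1L))))
    }
    enc
  })
  do.call(cbind, blocks)
}

# Build the encoded feature matrix for scale-model input: standardize the
# configured metadata keys (fitting or reusing stats), then positionally
# encode the configured subset.
.build_features <- function(df, config, stats = NULL) {
  std <- standardize(df, config$metadata_keys, stats = stats)
  keys <- std$stats$key
  pe_keys <- intersect(config$positional_encoding_keys, keys)
  plain <- setdiff(keys, pe_keys)
  parts <- list()
  if (length(pe_keys) > 0L) {
    parts$pe <- positional_encode(std$features[, pe_keys, drop = FALSE],
                                  config$positional_encoding_frequencies)
  }
  if (length(plain) > 0L) {
    parts$plain <- std$features[, plain, drop = FALSE]
  }
  X <- do.call(cbind, parts)
  list(features = X, stats = std$stats)
}

# ---- parameters -------------------------------------------------------------

# Initialize scale-model parameters as a flat named list of arrays.
# Trunk layers are residual with small-variance init; the output head weights
# start at zero so the initial scale distribution has location exactly 1.
.scale_init <- function(config, d_in, images, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- config$mlp_width
  p <- list()
  p$W1 <- matrix(stats::rnorm(d_in * W, sd = 1 / sqrt(d_in)), d_in, W)
  p$b1 <- numeric(W)
  if (config$mlp_layers >= 2L) {
    for (l in 2:config$mlp_layers) {
      p[[paste0("W", l)]] <- matrix(stats::rnorm(W * W, sd = 0.3 / sqrt(W)),
                                    W, W)
      p[[paste0("b", l)]] <- numeric(W)
    }
  }
  nimg <- length(images)
  if (config$image_layers > 0L) {
    # per-image weights stored as (nimg x W^2) matrices, entry (k + (j-1)W)
    # holding W[k, j] of that image's affine map
    for (l in seq_len(config$image_layers)) {
      p[[paste0("A", l)]] <- matrix(
        stats::rnorm(W * W * nimg, sd = 0.3 / sqrt(W)), nimg, W * W)
      p[[paste0("Ab", l)]] <- matrix(0, nimg, W)
    }
  }
  p$w_mu <- numeric(W)
  p$b_mu <- 0
  p$w_ls <- numeric(W)
  p$b_ls <- log(0.05)
  attr(p, "images") <- images
  attr(p, "d_in") <- d_in
  p
}

# ---- forward / backward -----------------------------------------------------

# fast column-wise bias add (recycles b down columns)
.addbias <- function(M, b) M + rep(b, rep.int(nrow(M), length(b)))

# 0/1 block-sum matrices used to contract the gathered per-image weights:
# S_out[(j-1)W+k, j] = 1 (output contraction), S_in[(j-1)W+k, k] = 1 (input
# contraction in the backward pass)
.blocksum <- function(W) {
  S_out <- matrix(0, W * W, W)
  S_in <- matrix(0, W * W, W)
  for (j in seq_len(W)) for (k in seq_len(W)) {
    S_out[(j - 1L) * W + k, j] <- 1
    S_in[(j - 1L) * W + k, k] <- 1
  }
  list(out = S_out, inp = S_in,
       rep_t = rep(seq_len(W), times = W), rep_e = rep(seq_len(W), each = W))
}

# Forward pass. Z: n x d_in encoded features; img_idx: 1-based index into the
# image universe (NULL allowed when image_layers = 0). Returns mu, log_sigma
# and (optionally) the activation cache for the backward pass.
.scale_fwd <- function(Z, img_idx, config, p, cache = FALSE) {
  W <- config$mlp_width
  acts <- if (cache) list() else NULL
  H <- tanh(.addbias(Z %*% p$W1, p$b1))
  if (cache) acts$H1 <- H
  if (config$mlp_layers >= 2L) {
    for (l in 2:config$mlp_layers) {
      pre <- .addbias(H %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
      T_ <- tanh(pre)
      if (cache) { acts[[paste0("Hin", l)]] <- H; acts[[paste0("T", l)]] <- T_ }
      H <- H + T_
    }
  }
  if (config$image_layers > 0L) {
    bs <- .blocksum(W)
    for (l in seq_len(config$image_layers)) {
      G <- p[[paste0("A", l)]][img_idx, , drop = FALSE] # n x W^2
      pre <- (H[, bs$rep_t, drop = FALSE] * G) %*% bs$out +
        p[[paste0("Ab", l)]][img_idx, , drop = FALSE]
      T_ <- tanh(pre)
      if (cache) {
        acts[[paste0("AHin", l)]] <- H
        acts[[paste0("AT", l)]] <- T_
        acts[[paste0("AG", l)]] <- G
      }
      H <- H + T_
    }
  }
  if (cache) acts$Hout <- H
  mu <- as.vector(H %*% p$w_mu) + p$b_mu
  log_sigma <- as.vector(H %*% p$w_ls) + p$b_ls
  list(mu = mu, log_sigma = log_sigma, acts = acts)
}

# Backward pass: given per-row gradients of the objective in mu and
# log_sigma, return the gradient list (same shape as p).
.scale_bwd <- function(Z, img_idx, config, p, acts, g_mu, g_ls) {
  W <- config$mlp_width
  g <- list()
  H <- acts$Hout
  g$w_mu <- as.vector(crossprod(H, g_mu))
  g$b_mu <- sum(g_mu)
  g$w_ls <- as.vector(crossprod(H, g_ls))
  g$b_ls <- sum(g_ls)
  gH <- tcrossprod(g_mu, p$w_mu) + tcrossprod(g_ls, p$w_ls)
  if (config$image_layers > 0L) {
    bs <- .blocksum(W)
    for (l in rev(seq_len(config$image_layers))) {
      T_ <- acts[[paste0("AT", l)]]
      Hin <- acts[[paste0("AHin", l)]]
      G <- acts[[paste0("AG", l)]]
      dpre <- gH * (1 - T_^2)
      nimg <- nrow(p[[paste0("A", l)]])
      # weight gradient: per-image outer products, accumulated via rowsum
      P <- Hin[, bs$rep_t, drop = FALSE] * dpre[, bs$rep_e, drop = FALSE]
      gA <- matrix(0, nimg, W * W)
      acc <- rowsum(P, img_idx)
      gA[as.integer(rownames(acc)), ] <- acc
      g[[paste0("A", l)]] <- gA
      gAb <- matrix(0, nimg, W)
      accb <- rowsum(dpre, img_idx)
      gAb[as.integer(rownames(accb)), ] <- accb
      g[[paste0("Ab", l)]] <- gAb
      # input gradient: gH_in = gH + dpre %*% t(W_img), gathered per row
      gH <- gH + (dpre[, bs$rep_e, drop = FALSE] * G) %*% bs$inp
    }
  }
  if (config$mlp_layers >= 2L) {
    for (l in rev(2:config$mlp_layers)) {
      T_ <- acts[[paste0("T", l)]]
      Hin <- acts[[paste0("Hin", l)]]
      dpre <- gH * (1 - T_^2)
      g[[paste0("W", l)]] <- crossprod(Hin, dpre)
      g[[paste0("b", l)]] <- colSums(dpre)
      gH <- gH + tcrossprod(dpre, p[[paste0("W", l)]])
    }
  }
  dpre1 <- gH * (1 - acts$H1^2)
  g$W1 <- crossprod(Z, dpre1)
  g$b1 <- colSums(dpre1)
  g
}

#' Evaluate the scale model
#'
#' Deterministic forward pass of the scale network: each observation's
#' metadata row is mapped to the location and spread of a log-normal
#' multiplicative scale. With `image_layers = 0` the output depends on
#' metadata only, so equal feature rows from different images receive equal
#' scales; with local layers, per-image parameters modulate the output.
#'
#' @param features Encoded feature matrix (see [standardize()] and
#'   [positional_encode()]).
#' @param image_ids Integer/character image identifiers, matched against the
#'   training image universe stored in `parameters`; an unseen id is an error
#'   when local layers are present.
#' @param config A [scale_model_config()].
#' @param parameters Parameter list from the fit (or a fresh
#'   initialization).
#' @return Data frame of class `"scale_distribution"` with columns
#'   `location` (median scale, strictly positive) and `spread` (log-normal
#'   sdlog).
#' @export
scale_forward <- function(features, image_ids, config, parameters) {
  img_idx <- NULL
  if (config$image_layers > 0L) {
    universe <- attr(parameters, "images")
    img_idx <- match(image_ids, universe)
    if (anyNA(img_idx)) {
      stop("unseen image id(s): local image layers have per-training-image ",
           "parameters")
    }
  }
  fw <- .scale_fwd(as.matrix(features), img_idx, config, parameters)
  structure(data.frame(location = exp(fw$mu), spread = exp(fw$log_sigma)),
            class = c("scale_distribution", "data.frame"))
}

#' Sample multiplicative scales
#' @param dist A `"scale_distribution"` from [scale_forward()].
#' @param n Draws per observation row (default 1).
#' @return Matrix (rows x n) of strictly positive scale samples.
#' @export
sample_scales <- function(dist, n = 1L) {
  m <- matrix(stats::rlnorm(nrow(dist) * n,
                            meanlog = rep(log(dist$location), n),
                            sdlog = rep(dist$spread, n)),
              nrow = nrow(dist), ncol = n)
  m
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(par) {
  list(m = rapply(par, function(x) x * 0, how = "replace"),
       v = rapply(par, function(x) x * 0, how = "replace"))
}

.adam_step <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(par)) {
    g <- grad[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] +
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, st = st)
}
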