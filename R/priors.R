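# Wilson and double-Wilson priors over structure-factor amplitudes, and the
# Gaussian / Student's t intensity error models. Each density comes with an
# analytic gradient in the amplitude (and parent amplitude), used by the
# reparameterized ELBO optimizer.

#' Wilson log-density of a structure-factor amplitude
#'
#' The prior over amplitudes under random atomic coordinates: acentric
#' reflections follow a Rayleigh-type density
#' p(F) = (2F / (eps Sigma)) exp(-F^2 / (eps Sigma)); centric reflections a
#' half-normal p(F) = sqrt(2 / (pi eps Sigma)) exp(-F^2 / (2 eps Sigma)).
#'
#' @param F Amplitudes (>= 0), vectorized.
#' @param centric Logical vector.
#' @param epsilon Integer multiplicities.
#' @param sigma Expected intensity scale Sigma (default 1; the merge
#'   normalizes amplitudes so resolution-dependent falloff is absorbed by the
#'   scale model).
#' @return Log-density values.
#' @export
wilson_logpdf <- function(F, centric = FALSE, epsilon = 1L, sigma = 1) {
  if (any(F < 0)) stop("amplitudes must be non-negative")
  stopifnot(sigma > 0)
  es <- epsilon * sigma
  out <- log(2 * F / es) - F^2 / es
  if (any(centric)) {
    cc <- rep_len(centric, length(F))
    esc <- rep_len(es, length(F))[cc]
    out[cc] <- 0.5 * log(2 / (pi * esc)) - F[cc]^2 / (2 * esc)
  }
  out
}

.wilson_grad <- function(F, centric, epsilon, sigma = 1) {
  es <- epsilon * sigma
  g <- 1 / F - 2 * F / es
  if (any(centric)) {
    cc <- rep_len(centric, length(F))
    g[cc] <- -F[cc] / rep_len(es, length(F))[cc]
  }
  g
}

# log I0(x) and the Bessel ratio I1/I0, numerically stable for large x via
# exponential scaling.
.log_bessel_i0 <- function(x) log(besselI(x, 0, expon.scaled = TRUE)) + x
.bessel_ratio_i1_i0 <- function(x) {
  r <- besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
  r[x == 0] <- 0
  r
}

#' Double-Wilson conditional log-density
#'
#' Conditional density of a child dataset's amplitude given its parent's,
#' under jointly Gaussian complex structure factors with correlation r:
#' acentric reflections follow a Rice density with noncentrality r * F_parent
#' and per-component variance (1 - r^2) eps Sigma / 2; centric reflections a
#' folded normal with mean r * F_parent and variance (1 - r^2) eps Sigma.
#' With r = 0 this reduces exactly to [wilson_logpdf()].
#'
#' @param F_child,F_parent Amplitudes (>= 0), vectorized.
#' @param r Correlation in `[0, 1)`.
#' @inheritParams wilson_logpdf
#' @return Log-density of the child amplitude.
#' @export
double_wilson_logpdf <- function(F_child, F_parent, r, centric = FALSE,
                                 epsilon = 1L, sigma = 1) {
  if (r < 0 || r >= 1) stop("r must lie in [0, 1)")
  if (any(F_child < 0) || any(F_parent < 0)) {
    stop("amplitudes must be non-negative")
  }
  if (r == 0) return(wilson_logpdf(F_child, centric, epsilon, sigma))
  es <- rep_len(epsilon * sigma, length(F_child))
  cc <- rep_len(centric, length(F_child))
  Fp <- rep_len(F_parent, length(F_child))
  out <- numeric(length(F_child))
  # acentric: Rice
  if (any(!cc)) {
    s2 <- (1 - r^2) * es[!cc] / 2
    nc <- r * Fp[!cc]
    Fa <- F_child[!cc]
    out[!cc] <- log(Fa / s2) - (Fa^2 + nc^2) / (2 * s2) +
      .log_bessel_i0(Fa * nc / s2)
  }
  # centric: folded normal
  if (any(cc)) {
    v <- (1 - r^2) * es[cc]
    mu <- r * Fp[cc]
    Fc <- F_child[cc]
    a <- -(Fc - mu)^2 / (2 * v)
    b <- -(Fc + mu)^2 / (2 * v)
    out[cc] <- -0.5 * log(2 * pi * v) + a + log1p(exp(b - a))
  }
  out
}

# Gradients of the double-Wilson conditional log-density with respect to the
# child and parent amplitudes. Returns list(child, parent).
.double_wilson_grad <- function(F_child, F_parent, r, centric, epsilon,
                                sigma = 1) {
  n <- length(F_child)
  if (r == 0) {
    return(list(child = .wilson_grad(F_child, centric, epsilon, sigma),
                parent = numeric(n)))
  }
  es <- rep_len(epsilon * sigma, n)
  cc <- rep_len(centric, n)
  Fp <- rep_len(F_parent, n)
  gc_ <- numeric(n); gp <- numeric(n)
  if (any(!cc)) {
    s2 <- (1 - r^2) * es[!cc] / 2
    nc <- r * Fp[!cc]
    Fa <- F_child[!cc]
    R <- .bessel_ratio_i1_i0(Fa * nc / s2)
    gc_[!cc] <- 1 / Fa - Fa / s2 + (nc / s2) * R
    gp[!cc] <- r * (-nc / s2 + (Fa / s2) * R)
  }
  if (any(cc)) {
    v <- (1 - r^2) * es[cc]
    mu <- r * Fp[cc]
    Fc <- F_child[cc]
    a <- -(Fc - mu)^2 / (2 * v)
    b <- -(Fc + mu)^2 / (2 * v)
    wb <- 1 / (1 + exp(a - b))
    wa <- 1 - wb
    gc_[cc] <- wa * (-(Fc - mu) / v) + wb * (-(Fc + mu) / v)
    gp[cc] <- r * (wa * ((Fc - mu) / v) - wb * ((Fc + mu) / v))
  }
  list(child = gc_, parent = gp)
}

#' Error-model log-density of observed intensities
#'
#' Gaussian or robust Student's t log-density of an observed intensity at the
#' model-predicted intensity, with scale given by the empirical uncertainty
#' from integration. As the t degrees of freedom grow the two families
#' coincide.
#'
#' @param I_obs,I_pred Observed and predicted intensities.
#' @param sigma_obs Positive uncertainty estimates.
#' @param spec A [likelihood_spec()].
#' @return Log-density values.
#' @export
likelihood_logpdf <- function(I_obs, sigma_obs, I_pred, spec) {
  stopifnot(inherits(spec, "likelihood_spec"))
  if (any(sigma_obs <= 0)) stop("sigma_obs must be positive")
  if (spec$family == "normal") {
    stats::dnorm(I_obs, mean = I_pred, sd = sigma_obs, log = TRUE)
  } else {
    z <- (I_obs - I_pred) / sigma_obs
    stats::dt(z, df = spec$dof, log = TRUE) - log(sigma_obs)
  }
}

# d log p / d I_pred
.likelihood_grad <- function(I_obs, sigma_obs, I_pred, spec) {
  if (spec$family == "normal") {
    (I_obs - I_pred) / sigma_obs^2
  } else {
    z <- (I_obs - I_pred) / sigma_obs
    ((spec$dof + 1) * z / (spec$dof + z^2)) / sigma_obs
  }
}

#' Specify the error model
#'
#' @param family `"normal"` or `"studentt"`.
#' @param dof Degrees of freedom nu (> 0), Student's t only; smaller values
#'   tolerate heavier-tailed outliers. nu = 32 is a robust default for serial
#'   data.
#' @return Object of class `"likelihood_spec"`.
#' @export
likelihood_spec <- function(family = c("normal", "studentt"), dof = 32) {
  family <- match.arg(family)
  if (family == "studentt") {
    if (!is.finite(dof) || dof <= 0) {
      stop("Student's t degrees of freedom must be finite and positive")
    }
  }
  structure(list(family = family, dof = dof), class = "likelihood_spec")
}

#' Specify the prior over structure-factor amplitudes
#'
#' Describes the per-dataset prior: a parent graph (a forest; each dataset
#' has at most one parent) and per-dataset double-Wilson correlations r.
#' Root datasets take the univariate Wilson prior; children are conditioned
#' on their parent's sampled amplitude through the double-Wilson density. The
#' `"gaussian"` family replaces the Wilson prior by an independent Gaussian
#' over amplitudes, a relaxation used to validate the inference engine
#' against closed-form conjugate posteriors.
#'
#' @param parents Integer vector of parent dataset ids (NA for roots), one
#'   entry per dataset. Default: a single root dataset.
#' @param r Per-dataset correlation in `[0, 1)`; must be 0 wherever the
#'   dataset is a root.
#' @param wilson_sigma Expected intensity scale Sigma (default 1).
#' @param family `"wilson"` (default) or `"gaussian"`.
#' @param mean,sd Gaussian-family location and spread.
#' @return Object of class `"prior_spec"`.
#' @export
prior_spec <- function(parents = NA_integer_, r = 0, wilson_sigma = 1,
                       family = c("wilson", "gaussian"), mean = 1, sd = 1) {
  family <- match.arg(family)
  n <- max(length(parents), length(r))
  parents <- rep_len(as.integer(parents), n)
  r <- rep_len(r, n)
  if (any(r < 0 | r >= 1)) stop("r must lie in [0, 1)")
  if (any(!is.na(parents) & (parents < 0L | parents >= n))) {
    stop("parent indices must reference datasets 0..", n - 1L)
  }
  if (any(is.na(parents) & r != 0)) {
    stop("r must be 0 for root datasets (no parent)")
  }
  # forest check: following parents must terminate
  for (d in seq_len(n)) {
    seen <- logical(n); cur <- d
    while (!is.na(parents[cur])) {
      cur <- parents[cur] + 1L
      if (seen[cur]) stop("parent graph contains a cycle")
      seen[cur] <- TRUE
    }
  }
  stopifnot(wilson_sigma > 0)
  structure(list(parents = parents, r = r, wilson_sigma = wilson_sigma,
                 family = family, mean = mean, sd = sd),
            class = "prior_spec")
}

#' Mix-and-inject prior: all time points referenced to dataset 0
#'
#' Convenience constructor for the usual time-series topology in which every
#' post-mix dataset is a child of the unmixed reference dataset, all sharing
#' one correlation r.
#'
#' @param n_datasets Number of datasets.
#' @param r Shared child-parent correlation.
#' @inheritParams prior_spec
#' @return A [prior_spec()].
#' @export
prior_spec_reference <- function(n_datasets, r = 0.99, wilson_sigma = 1) {
  prior_spec(parents = c(NA_integer_, rep(0L, n_datasets - 1L)),
             r = c(0, rep(r, n_datasets - 1L)),
             wilson_sigma = wilson_sigma)
}

#' Predicted intensity of a (possibly harmonic) observation
#'
#' The harmonic forward model: the predicted intensity of an observation is
#' the sum over the members of its harmonic group of that member's scale
#' times its squared amplitude.
#'
#' @param scales Per-member scale samples.
#' @param amplitudes Per-member amplitude samples.
#' @param groups Optional integer/factor of group labels (one per member);
#'   when given, returns one intensity per group in label-sorted order.
#' @return Predicted intensity (scalar, or one per group).
#' @export
predicted_intensity <- function(scales, amplitudes, groups = NULL) {
  if (length(amplitudes) == 0L) stop("harmonic group must be non-empty")
  contrib <- scales * amplitudes^2
  if (is.null(groups)) return(sum(contrib))
  out <- rowsum(contrib, groups)
  stats::setNames(out[, 1L], rownames(out))
}
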