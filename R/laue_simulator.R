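# Synthetic pink-beam serial-crystallography generator with known ground
# truth. Emulates the statistical features the merging model addresses:
# Wilson-scale amplitudes on a correlated time-point chain with one localized
# occupancy perturbation, per-image multiplicative scales, a skewed
# few-percent-bandwidth spectrum modulating intensity by wavelength, rare
# harmonic overlaps, heavy-tailed outliers, high-frequency detector response,
# and per-image indexing-ambiguity flips.

# ---- spectrum ---------------------------------------------------------------

#' Pink-beam spectrum model
#'
#' A right-skewed unimodal spectral density: a gamma core shifted so its mode
#' sits at `lambda_peak` with full width at half maximum
#' `bandwidth_frac * lambda_peak`, plus a weak flat wing extending to
#' `lambda_max` that carries the long-wavelength tail responsible for rare
#' harmonic overlaps. Smaller `skew` (the gamma shape) gives a stronger right
#' skew.
#'
#' @param lambda_peak Peak wavelength in Angstrom.
#' @param bandwidth_frac FWHM divided by `lambda_peak` (default 0.05, a
#'   ~5 percent bandwidth beam).
#' @param skew Gamma shape parameter (> 1); default 3.
#' @param tail_flux Fraction of total flux in the flat long-wavelength wing.
#' @param lambda_max Upper edge of the beam window, Angstrom.
#' @return Object of class `"spectrum_model"` with derived fields
#'   `lambda_min` (window lower edge) and `theta` (gamma scale).
#' @export
spectrum_model <- function(lambda_peak = 1.04, bandwidth_frac = 0.05,
                           skew = 3, tail_flux = 0.02,
                           lambda_max = 2.2 * lambda_peak) {
  stopifnot(lambda_peak > 0, bandwidth_frac >= 0, skew > 1,
            tail_flux >= 0, tail_flux < 1)
  if (bandwidth_frac == 0) {
    theta <- 0
    shift <- lambda_peak
  } else {
    fwhm1 <- .gamma_fwhm(skew)
    theta <- bandwidth_frac * lambda_peak / fwhm1
    shift <- lambda_peak - (skew - 1) * theta
  }
  structure(
    list(lambda_peak = lambda_peak, bandwidth_frac = bandwidth_frac,
         skew = skew, tail_flux = tail_flux, theta = theta,
         lambda_min = shift, lambda_max = lambda_max),
    class = "spectrum_model"
  )
}

# FWHM of the gamma(shape, scale = 1) density, by bisection on each side of
# the mode.
.gamma_fwhm <- function(shape) {
  mode <- shape - 1
  half <- stats::dgamma(mode, shape) / 2
  f <- function(x) stats::dgamma(x, shape) - half
  lo <- stats::uniroot(f, c(1e-9, mode))$root
  hi <- stats::uniroot(f, c(mode, mode + 20 * sqrt(shape)))$root
  hi - lo
}

#' Spectral density of a spectrum model
#'
#' @param spectrum A [spectrum_model()].
#' @param lambda Wavelengths in Angstrom.
#' @return Density values (arbitrary normalization over the beam window).
#' @export
spectrum_density <- function(spectrum, lambda) {
  s <- spectrum
  if (s$bandwidth_frac == 0) {
    return(as.numeric(lambda == s$lambda_peak))
  }
  core <- stats::dgamma(lambda - s$lambda_min, shape = s$skew,
                        scale = s$theta)
  wing <- stats::dunif(lambda, s$lambda_min, s$lambda_max)
  (1 - s$tail_flux) * core + s$tail_flux * wing
}

#' Sample wavelengths from a spectrum
#'
#' Draws are unimodal and right-skewed; each draw is returned with a relative
#' flux weight proportional to the spectral density (normalized to 1 at the
#' peak).
#'
#' @param spectrum A [spectrum_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return List with `wavelength` and `flux_weight`, each length n.
#' @export
sample_spectrum <- function(spectrum, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- spectrum
  if (s$bandwidth_frac == 0) {
    return(list(wavelength = rep(s$lambda_peak, n),
                flux_weight = rep(1, n)))
  }
  from_wing <- stats::runif(n) < s$tail_flux
  lam <- numeric(n)
  nw <- sum(from_wing)
  if (nw > 0L) lam[from_wing] <- stats::runif(nw, s$lambda_min, s$lambda_max)
  nc <- n - nw
  if (nc > 0L) {
    draws <- s$lambda_min +
      stats::rgamma(nc, shape = s$skew, scale = s$theta)
    # keep draws inside the declared beam window
    while (any(bad <- draws > s$lambda_max)) {
      draws[bad] <- s$lambda_min +
        stats::rgamma(sum(bad), shape = s$skew, scale = s$theta)
    }
    lam[!from_wing] <- draws
  }
  peak <- spectrum_density(s, s$lambda_peak)
  list(wavelength = lam, flux_weight = spectrum_density(s, lam) / peak)
}

# ---- toy atomic model -------------------------------------------------------

#' Toy atomic model
#'
#' A handful of point scatterers in fractional coordinates. Supplies the
#' reference phases that real analyses would take from a refined model, and
#' the ground-truth structure factors of the synthetic crystal.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` (fractional, in
#'   `[0, 1)`) and `weight` (> 0); an optional `b` column gives per-atom
#'   Debye-Waller factors in Angstrom^2 (amplitude attenuation
#'   exp(-B / (4 d^2)), default 0).
#' @return Object of class `"toy_model"`.
#' @export
toy_model <- function(atoms) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("x", "y", "z", "weight") %in% names(atoms)))
  co <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(co < 0 | co >= 1)) stop("fractional coordinates must lie in [0,1)")
  if (any(atoms$weight <= 0)) stop("scattering weights must be positive")
  if (is.null(atoms$b)) atoms$b <- rep(0, nrow(atoms))
  if (any(atoms$b < 0)) stop("B-factors must be non-negative")
  structure(list(atoms = atoms), class = "toy_model")
}

#' Expand a toy model by the space-group symmetry
#'
#' Applies every real-space symmetry operation (rotation plus screw
#' translation) of the space group to each atom, producing a model whose
#' structure factors genuinely obey the crystal symmetry: every Miller index
#' in a point-group orbit then carries the same amplitude, and model phases
#' are consistent at all orbit members. Images of atom j occupy consecutive
#' rows, so the orbit of atom 1 is rows 1..n_ops.
#'
#' @param model A [toy_model()] of unique atoms.
#' @param spacegroup Space-group symbol.
#' @return A symmetrized [toy_model()].
#' @export
expand_model_symmetry <- function(model, spacegroup) {
  ops <- .sg_get(spacegroup)$realspace_ops
  at <- model$atoms
  rows <- lapply(seq_len(nrow(at)), function(j) {
    x <- as.numeric(at[j, c("x", "y", "z")])
    do.call(rbind, lapply(ops, function(op) {
      xx <- (op$R %*% x + op$t) %% 1
      data.frame(x = xx[1], y = xx[2], z = xx[3], weight = at$weight[j],
                 b = at$b[j])
    }))
  })
  toy_model(do.call(rbind, rows))
}

#' Structure factors of a toy model
#'
#' Direct summation F(h) = sum_j w_j occ_j exp(2 pi i h . x_j) over the model
#' atoms, evaluated on a set of Miller indices.
#'
#' @param model A [toy_model()].
#' @param crystal A [crystal_form()]; used to enumerate the ASU index set
#'   when `hkl` is not given.
#' @param occupancy Per-atom occupancies (default all 1).
#' @param hkl Optional integer matrix / data frame of indices (columns
#'   h, k, l); defaults to [asu_indices()] of the crystal.
#' @return Complex vector of structure factors, one per row of `hkl`.
#' @export
structure_factors_from_model <- function(model, crystal, occupancy = NULL,
                                         hkl = NULL) {
  stopifnot(inherits(model, "toy_model"))
  at <- model$atoms
  if (nrow(at) == 0L) stop("toy model has no atoms")
  if (is.null(occupancy)) occupancy <- rep(1, nrow(at))
  stopifnot(length(occupancy) == nrow(at))
  if (is.null(hkl)) hkl <- asu_indices(crystal)
  H <- as.matrix(as.data.frame(hkl)[, c("h", "k", "l")])
  phase <- 2 * pi * (H %*% t(as.matrix(at[, c("x", "y", "z")])))
  W <- matrix(at$weight * occupancy, nrow(H), nrow(at), byrow = TRUE)
  if (any(at$b > 0)) {
    inv4d2 <- 1 / (4 * resolution(H, crystal$cell)^2)
    W <- W * exp(-outer(inv4d2, at$b))
  }
  rowSums((cos(phase) + 1i * sin(phase)) * W)
}

# ---- ground truth -----------------------------------------------------------

#' Generate ground-truth structure factors for a time series
#'
#' Dataset 0 takes its complex structure factors from the toy model. Each
#' child dataset c with parent p is generated as
#' F_c = r F_p + sqrt(1 - r^2) eps, with eps a complex Gaussian innovation on
#' the Wilson scale (variance epsilon_h * Sigma per index), the generative
#' counterpart of the double-Wilson prior. The perturbation-site atom's
#' occupancy is then reduced by `perturbation_fraction` in every post-mix
#' dataset and the structure factors updated additively, planting a localized
#' time-resolved difference signal.
#'
#' @param crystal A [crystal_form()].
#' @param n_datasets Number of time points (dataset 0 is the reference).
#' @param true_r Generative correlation in `[0, 1)` between child and parent.
#' @param model A [toy_model()].
#' @param perturbation_fraction Occupancy reduction applied to the perturbed
#'   atom in post-mix datasets.
#' @param seed Integer seed.
#' @param parents Optional per-dataset parent index (NA for the root);
#'   defaults to all children hanging off dataset 0, the topology of a
#'   mix-and-inject series referenced to the unmixed state.
#' @param perturb_atom Row index (or indices, e.g. a symmetry orbit) of the
#'   perturbed atom(s) in the model; the recorded site is the first one.
#' @return Object of class `"ground_truth"`: the ASU index table, complex
#'   structure factors and amplitudes per dataset, the Wilson scale, the
#'   planted perturbation (site, fraction, complex delta), and the generative
#'   parameters.
#' @export
generate_ground_truth <- function(crystal, n_datasets, true_r, model,
                                  perturbation_fraction = 0.2, seed = 1L,
                                  parents = NULL, perturb_atom = 1L) {
  stopifnot(n_datasets >= 1L, true_r >= 0, true_r < 1)
  set.seed(seed)
  hkl <- asu_indices(crystal)
  nh <- nrow(hkl)
  F0 <- structure_factors_from_model(model, crystal, hkl = hkl)
  # Wilson scale per index: resolution-binned mean of epsilon-normalized
  # intensity, so innovations follow the model's falloff
  nb <- min(8L, max(1L, nh %/% 25L))
  qs <- unique(stats::quantile(hkl$d, seq(0, 1, length.out = nb + 1L)))
  qs[1L] <- qs[1L] - 1e-9
  bin <- cut(hkl$d, qs, labels = FALSE)
  Sb <- tapply(Mod(F0)^2 / hkl$epsilon, bin, mean)
  Sigma_h <- as.numeric(Sb[as.character(bin)])
  Sigma <- mean(Mod(F0)^2 / hkl$epsilon)
  if (is.null(parents)) {
    parents <- c(NA_integer_, rep(0L, max(0L, n_datasets - 1L)))
  }
  stopifnot(length(parents) == n_datasets, is.na(parents[1L]) ||
              n_datasets == 1L)
  Fc <- matrix(0 + 0i, nh, n_datasets)
  Fc[, 1L] <- F0
  if (n_datasets > 1L) {
    for (d in 2:n_datasets) {
      p <- parents[d] + 1L
      sd_comp <- sqrt(hkl$epsilon * Sigma_h / 2)
      eps <- complex(real = stats::rnorm(nh, sd = sd_comp),
                     imaginary = stats::rnorm(nh, sd = sd_comp))
      Fc[, d] <- true_r * Fc[, p] + sqrt(1 - true_r^2) * eps
    }
  }
  site <- as.numeric(model$atoms[perturb_atom[1L], c("x", "y", "z")])
  H <- as.matrix(hkl[, c("h", "k", "l")])
  delta <- 0 + 0i
  for (j in perturb_atom) {
    xs <- as.numeric(model$atoms[j, c("x", "y", "z")])
    w_j <- model$atoms$weight[j] * exp(-model$atoms$b[j] / (4 * hkl$d^2))
    ph <- 2 * pi * as.vector(H %*% xs)
    delta <- delta - perturbation_fraction * w_j * (cos(ph) + 1i * sin(ph))
  }
  if (n_datasets > 1L && perturbation_fraction != 0) {
    for (d in 2:n_datasets) Fc[, d] <- Fc[, d] + delta
  }
  structure(
    list(crystal = crystal, model = model, hkl = hkl,
         F_complex = Fc, true_F = Mod(Fc), sigma_wilson = Sigma,
         sigma_wilson_h = Sigma_h,
         true_r = true_r, parents = parents,
         perturbation_site = site, perturbation_fraction = perturbation_fraction,
         perturbation_delta = delta, seed = seed),
    class = "ground_truth"
  )
}

# ---- observation simulation -------------------------------------------------

#' Simulate unmerged pink-beam observations
#'
#' Produces a reflection table per the generative model: each observation's
#' ideal intensity is image_scale times the sum over stimulated harmonic
#' members of flux_weight(lambda_member) * |F_member|^2, optionally modulated
#' by a high-frequency detector response. A second-order harmonic member is
#' included with probability `harmonic_prob` (such observations are recorded
#' at a long-wavelength tail position so the overlap is geometrically
#' consistent with [harmonic_candidates()]). Gaussian noise with standard
#' deviation `noise_frac * I + noise_floor` is added; outliers multiply the
#' ideal intensity by `outlier_factor` with probability `outlier_frac`
#' (`SigI` always reports the noise level actually used, never the outlier
#' inflation); whole images are reindexed by the ambiguity operator with
#' probability `flip_prob`. Recorded Miller indices are random point-group
#' plus Friedel mates of the sampled ASU index.
#'
#' With every corruption disabled (zero noise, jitter range c(1,1), flat
#' spectrum, no harmonics, no outliers, no flips, no detector modulation) the
#' recorded intensity equals |F|^2 exactly.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param spectrum A [spectrum_model()].
#' @param n_images_per_dataset,obs_per_image Scene size; sampling an image's
#'   Miller indices is without replacement, so `obs_per_image` must not
#'   exceed the ASU count.
#' @param scale_jitter_range Range of per-image multiplicative scales
#'   (log-uniform draw).
#' @param noise_frac,noise_floor Relative and additive components of the
#'   Gaussian noise standard deviation.
#' @param outlier_frac,outlier_factor Outlier rate and multiplier.
#' @param harmonic_prob Probability that an observation is a harmonic
#'   overlap.
#' @param flip_prob Probability that an image is indexed in the alternative
#'   convention.
#' @param detector_modulation Amplitude of a fixed high-frequency sinusoidal
#'   detector response in X/Y (0 disables).
#' @param intensity_scale Global beam-flux multiplier on clean intensities;
#'   small values put the data in the weak, noise-floor-dominated regime of
#'   real serial experiments.
#' @param seed Integer seed; identical seed and parameters give identical
#'   tables.
#' @return List with `table` (a [refl_table()] spanning all datasets) and
#'   `truth` (the input augmented with `image_scales`, `flip_ops`, and a
#'   per-observation `obs` record: ASU row, harmonic partner, clean
#'   intensity, flux, outlier and harmonic flags).
#' @export
simulate_observations <- function(truth, spectrum,
                                  n_images_per_dataset = 100L,
                                  obs_per_image = 50L,
                                  scale_jitter_range = c(0.5, 2),
                                  noise_frac = 0.05, noise_floor = 1,
                                  outlier_frac = 0.02, outlier_factor = 10,
                                  harmonic_prob = 0.01, flip_prob = 0,
                                  detector_modulation = 0.2,
                                  intensity_scale = 1, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            all(c(noise_frac, outlier_frac, harmonic_prob, flip_prob) >= 0),
            all(c(outlier_frac, harmonic_prob, flip_prob) <= 1))
  set.seed(seed)
  crystal <- truth$crystal
  hkl <- truth$hkl
  nh <- nrow(hkl)
  if (obs_per_image > nh) {
    stop("obs_per_image (", obs_per_image, ") exceeds the ", nh,
         " available ASU reflections; sampling with replacement is refused")
  }
  nd <- ncol(truth$F_complex)
  key <- .miller_key(hkl$h, hkl$k, hkl$l)
  partner <- match(.miller_key(2L * hkl$h, 2L * hkl$k, 2L * hkl$l), key)
  # observation sampling is restricted to primitive (gcd 1) indices so that
  # an observation carries a harmonic overlap exactly when flagged: the
  # order-2 member of a primitive main-band reflection falls below the beam
  # window, while flagged observations are recorded in the long-wavelength
  # tail where the order-2 member lands back inside the window
  gcd1 <- apply(as.matrix(hkl[, c("h", "k", "l")]), 1L, .gcd3) == 1L
  pool <- which(gcd1)
  eligible <- which(gcd1 & !is.na(partner))
  if (obs_per_image > length(pool)) {
    stop("obs_per_image (", obs_per_image, ") exceeds the ", length(pool),
         " available primitive ASU reflections; sampling with replacement ",
         "is refused")
  }
  ops <- .sg_get(crystal$spacegroup)$ops
  amb <- .sg_get(crystal$spacegroup)$ambiguity_op
  lam_harm_lo <- 2 * spectrum$lambda_min

  rows <- vector("list", nd * n_images_per_dataset)
  obs_rows <- vector("list", nd * n_images_per_dataset)
  img_scales <- numeric(nd * n_images_per_dataset)
  flip_ops <- logical(nd * n_images_per_dataset)
  ii <- 0L
  for (d in seq_len(nd) - 1L) {
    Fd2 <- truth$true_F[, d + 1L]^2
    for (im in seq_len(n_images_per_dataset) - 1L) {
      ii <- ii + 1L
      sc <- exp(stats::runif(1, log(scale_jitter_range[1L]),
                             log(scale_jitter_range[2L])))
      img_scales[ii] <- sc
      flip <- flip_prob > 0 && stats::runif(1) < flip_prob
      flip_ops[ii] <- flip
      idx <- pool[sample.int(length(pool), obs_per_image)]
      harm <- stats::runif(obs_per_image) < harmonic_prob
      if (any(harm)) {
        need <- which(harm & !(idx %in% eligible))
        avail <- setdiff(eligible, idx)
        n_take <- min(length(need), length(avail))
        if (n_take < length(need)) harm[need[-seq_len(n_take)]] <- FALSE
        if (n_take > 0L) {
          idx[need[seq_len(n_take)]] <-
            if (length(avail) == 1L) avail else sample(avail, n_take)
        }
      }
      sp <- sample_spectrum(spectrum, obs_per_image)
      lam <- sp$wavelength
      if (spectrum$bandwidth_frac > 0) {
        # main-band observations stay below the harmonic-capable tail;
        # harmonic overlaps are recorded in the tail window
        while (any(bad <- !harm & lam >= lam_harm_lo)) {
          lam[bad] <- sample_spectrum(spectrum, sum(bad))$wavelength
        }
        nhm <- sum(harm)
        if (nhm > 0L) {
          lam[harm] <- stats::runif(nhm, lam_harm_lo, spectrum$lambda_max)
        }
      }
      peak <- spectrum_density(spectrum, spectrum$lambda_peak)
      flux <- if (spectrum$bandwidth_frac > 0) {
        spectrum_density(spectrum, lam) / peak
      } else rep(1, obs_per_image)
      contrib <- flux * Fd2[idx]
      if (any(harm)) {
        flux2 <- spectrum_density(spectrum, lam[harm] / 2) / peak
        contrib[harm] <- contrib[harm] + flux2 * Fd2[partner[idx[harm]]]
      }
      X <- stats::runif(obs_per_image, 0, 100)
      Y <- stats::runif(obs_per_image, 0, 100)
      det <- if (detector_modulation > 0) {
        1 + detector_modulation *
          sin(2 * pi * 3 * X / 100) * sin(2 * pi * 3 * Y / 100)
      } else 1
      I_clean <- intensity_scale * sc * det * contrib
      sd_noise <- noise_frac * I_clean + noise_floor
      outl <- stats::runif(obs_per_image) < outlier_frac
      I_out <- ifelse(outl, I_clean * outlier_factor, I_clean)
      I_obs <- I_out + if (any(sd_noise > 0)) {
        stats::rnorm(obs_per_image, sd = sd_noise)
      } else 0
      # record a random symmetry mate of the ASU index
      M <- ops[[sample.int(length(ops), 1L)]]
      Hrec <- as.matrix(hkl[idx, c("h", "k", "l")]) %*% t(M)
      neg <- stats::runif(obs_per_image) < 0.5
      Hrec[neg, ] <- -Hrec[neg, , drop = FALSE]
      if (flip && !is.null(amb)) Hrec <- Hrec %*% t(amb)
      rows[[ii]] <- data.frame(
        dataset = d, image = im,
        h = Hrec[, 1L], k = Hrec[, 2L], l = Hrec[, 3L],
        I = I_obs, SigI = pmax(sd_noise, 1e-8),
        X = X, Y = Y, Wavelength = lam
      )
      obs_rows[[ii]] <- data.frame(
        dataset = d, image = im, asu_row = idx,
        partner_row = ifelse(harm, partner[idx], NA_integer_),
        harmonic = harm, outlier = outl, clean_I = I_clean, flux = flux
      )
    }
  }
  df <- do.call(rbind, rows)
  truth$image_scales <- data.frame(
    dataset = rep(seq_len(nd) - 1L, each = n_images_per_dataset),
    image = rep(seq_len(n_images_per_dataset) - 1L, times = nd),
    scale = img_scales
  )
  truth$flip_ops <- data.frame(
    dataset = truth$image_scales$dataset,
    image = truth$image_scales$image,
    flipped = flip_ops
  )
  truth$obs <- do.call(rbind, obs_rows)
  truth$outlier_flags <- truth$obs$outlier
  truth$spectrum <- spectrum
  list(table = refl_table(df), truth = truth)
}

#' Write ground truth as a text sidecar
#'
#' Tab-separated amplitude table (one column per dataset) preceded by
#' commented header lines recording the generative parameters; intended as a
#' recovery oracle alongside simulator output.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param path Output file path.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# true_r\t%.9g", truth$true_r),
    sprintf("# perturbation_fraction\t%.9g", truth$perturbation_fraction),
    sprintf("# perturbation_site\t%s",
            paste(.fmt_real(truth$perturbation_site), collapse = "\t")),
    sprintf("# sigma_wilson\t%.9g", truth$sigma_wilson),
    sprintf("# parents\t%s", paste(truth$parents, collapse = "\t"))
  ), con, sep = "\n")
  nd <- ncol(truth$F_complex)
  out <- data.frame(truth$hkl[, c("h", "k", "l")])
  for (d in seq_len(nd)) {
    out[[paste0("F_", d - 1L)]] <- .fmt_real(truth$true_F[, d])
  }
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con,
             sep = "\n")
  invisible(path)
}
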