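# Preset synthetic scenes: the study conditions used throughout the test
# suite and the worked examples. Sizes are chosen so a full fit runs in
# seconds on one CPU while preserving every statistical feature of the
# generative model (correlated time series, planted perturbation, per-image
# scales, skewed spectrum, harmonics, outliers).

# fixed toy crystal: P3121-like hexagonal cell, ~200 ASU reflections to 2 A
.scene_crystal <- function(dmin = 2) {
  crystal_form(c(16, 16, 22, 90, 90, 120), "P3121", dmin = dmin)
}

# fixed 10-atom toy model (deterministic coordinates); atom 1 is the
# perturbation site and scatters strongly (weight 15 vs 5), emulating the
# appearance/loss of a well-ordered ligand moiety whose difference signal
# dominates the stochastic time-point differences. B = 30 A^2 gives a
# realistic Wilson falloff so high-resolution shells sink toward the noise
# floor.
.scene_model <- function() {
  set.seed(420042L)
  n <- 10L
  base <- toy_model(data.frame(x = stats::runif(n), y = stats::runif(n),
                               z = stats::runif(n),
                               weight = c(15, rep(5, n - 1L)),
                               b = rep(30, n)))
  # symmetrize so amplitudes genuinely obey P3121 and model phases are
  # consistent at every orbit member
  expand_model_symmetry(base, "P3121")
}

# row indices of the perturbed atom's symmetry orbit in the scene model
.scene_perturb_rows <- function() {
  seq_len(length(.sg_get("P3121")$realspace_ops))
}

#' Desk-scale scale-model configuration
#'
#' The network size used by the preset scenes: depth 3, width 6 (the width
#' used for the seven-dataset serial study), 2 image layers, positional
#' encoding with 4 frequencies on the detector coordinates.
#' @return A [scale_model_config()].
#' @export
desk_scale_config <- function() {
  scale_model_config(mlp_layers = 3L, mlp_width = 6L, image_layers = 2L,
                     positional_encoding_frequencies = 4L)
}

#' Build a preset synthetic scene
#'
#' Generates ground truth and unmerged observations for one of three preset
#' study conditions:
#' \describe{
#'   \item{default}{Seven datasets (one reference + six time points), 100
#'     images per dataset, 50 observations per image; generative correlation
#'     r = 0.99, 20 percent occupancy perturbation at the planted site, 5
#'     percent noise, 2 percent x10 outliers, 1 percent harmonics, image
#'     scale jitter 0.5-2.}
#'   \item{small}{Three datasets, 30 images, 40 observations per image;
#'     otherwise as default. Used where a full seven-dataset scene is not
#'     needed.}
#'   \item{stress}{Three datasets, 40 images, 40 observations per image,
#'     5 percent x10 outliers and stronger detector modulation; the scene
#'     used for ablation-ordering comparisons.}
#' }
#'
#' @param preset `"default"`, `"small"`, or `"stress"`.
#' @param seed Integer seed controlling both ground truth and observations.
#' @param ... Overrides passed to [simulate_observations()] (e.g.
#'   `harmonic_prob`, `outlier_frac`, `flip_prob`) or to
#'   [generate_ground_truth()] via `true_r`, `perturbation_fraction`,
#'   `n_datasets`.
#' @return List with `crystal`, `model`, `spectrum`, `truth`, `table`,
#'   `site` (planted perturbation site), and `prior` (the matching
#'   reference-topology [prior_spec()]).
#' @export
build_scene <- function(preset = c("default", "small", "stress"), seed = 1L,
                        ...) {
  preset <- match.arg(preset)
  dots <- list(...)
  take <- function(name, default) {
    if (!is.null(dots[[name]])) dots[[name]] else default
  }
  sizes <- switch(preset,
    default = list(nd = 7L, ni = 100L, no = 50L, outl = 0.02, det = 0.2,
                   iscale = 1),
    small = list(nd = 3L, ni = 30L, no = 40L, outl = 0.02, det = 0.2,
                 iscale = 1),
    # the stress scene sits in the weak-data, low-redundancy regime of real
    # serial experiments, where the multivariate prior carries the load
    stress = list(nd = 4L, ni = 20L, no = 25L, outl = 0.05, det = 0.3,
                  iscale = 0.012))
  crystal <- .scene_crystal(take("dmin", 2))
  model <- .scene_model()
  spectrum <- spectrum_model()
  n_datasets <- take("n_datasets", sizes$nd)
  true_r <- take("true_r", 0.99)
  truth <- generate_ground_truth(
    crystal, n_datasets, true_r, model,
    perturbation_fraction = take("perturbation_fraction", 0.2),
    seed = seed, perturb_atom = .scene_perturb_rows())
  sim <- simulate_observations(
    truth, spectrum,
    n_images_per_dataset = take("n_images_per_dataset", sizes$ni),
    obs_per_image = take("obs_per_image", sizes$no),
    scale_jitter_range = take("scale_jitter_range", c(0.5, 2)),
    noise_frac = take("noise_frac", 0.05),
    noise_floor = take("noise_floor", 1),
    outlier_frac = take("outlier_frac", sizes$outl),
    outlier_factor = take("outlier_factor", 10),
    harmonic_prob = take("harmonic_prob", 0.01),
    flip_prob = take("flip_prob", 0),
    detector_modulation = take("detector_modulation", sizes$det),
    intensity_scale = take("intensity_scale", sizes$iscale),
    seed = seed + 1000L)
  list(crystal = crystal, model = model, spectrum = spectrum,
       truth = sim$truth, table = sim$table, site = truth$perturbation_site,
       prior = prior_spec_reference(n_datasets, r = 0.99))
}
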