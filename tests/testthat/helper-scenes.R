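# Shared fixtures: scenes and fits are built once per test run and reused
# across test files (everything is generated in code; nothing is stored).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# a small 3-dataset scene with default corruptions
small_scene <- function(seed = 1) {
  fixture(paste0("scene_small_", seed), build_scene("small", seed = seed))
}

# the shared baseline fit on the small scene
small_fit <- function(seed = 1) {
  fixture(paste0("fit_small_", seed), {
    sc <- small_scene(seed)
    vi_merge(sc$table, sc$crystal, prior = sc$prior,
             scale_config = desk_scale_config(), mode = "poly",
             steps = 400, learning_rate = 0.03, test_fraction = 0.1,
             seed = 100 + seed)
  })
}

# a tiny 2-dataset scene for fast structural tests
tiny_scene <- function(seed = 2) {
  fixture(paste0("scene_tiny_", seed),
          build_scene("small", seed = seed, n_datasets = 2,
                      n_images_per_dataset = 6, obs_per_image = 15))
}

# random reflection-table data frame for I/O tests
random_refl_df <- function(n = 100, n_datasets = 1, seed = 7) {
  set.seed(seed)
  data.frame(
    dataset = sample(seq_len(n_datasets) - 1L, n, replace = TRUE),
    image = sample(0:9, n, replace = TRUE),
    h = sample(-6:6, n, replace = TRUE),
    k = sample(-6:6, n, replace = TRUE),
    l = sample(c(-5:-1, 1:5), n, replace = TRUE),
    I = rlnorm(n, 3), SigI = runif(n, 0.5, 2),
    X = runif(n, 0, 100), Y = runif(n, 0, 100),
    Wavelength = runif(n, 1, 1.2)
  )
}

# correlation between merged amplitudes of a fit and the generator's truth
truth_cor <- function(fit, scene, dataset) {
  key <- with(scene$truth$hkl, h * 1e6 + k * 1e3 + l + 5e8)
  md <- merged_subset(coef(fit), dataset)
  idx <- match(md$h * 1e6 + md$k * 1e3 + md$l + 5e8, key)
  stats::cor(md$F, scene$truth$true_F[idx, dataset + 1L])
}

# minimum periodic cartesian distance (A) from a point to the planted
# site's symmetry orbit
site_orbit_dist <- function(pt, scene) {
  mates <- site_symmetry_mates(scene$site, scene$crystal$spacegroup)
  min(apply(mates, 1, function(s) {
    dd <- abs(pt - s)
    sqrt(sum((pmin(dd, 1 - dd) * scene$crystal$cell[1:3])^2))
  }))
}

# mean |difference-map value| at the planted site across post-mix datasets
planted_peaks <- function(fit, scene) {
  m <- coef(fit)
  m0 <- merged_subset(m, 0L)
  vapply(setdiff(sort(unique(m$dataset)), 0L), function(d) {
    co <- difference_coefficients(merged_subset(m, d), m0, scene$model,
                                  scene$crystal)
    map <- compute_map(co, scene$crystal)
    abs(pinkmerge:::.site_peak_height(map, scene$site))
  }, numeric(1))
}
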