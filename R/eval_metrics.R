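# Figures of merit: half-dataset correlation (CC_half) per resolution bin,
# observed-vs-predicted correlation (CC_pred, weighted Pearson and Spearman)
# with bootstrap, sigma-scaled difference electron-density maps, peak
# extraction, real-space correlation (RSCC), and the fitted-scale versus
# wavelength diagnostic.

# ---- correlation figures of merit -------------------------------------------

#' Half-dataset correlation per resolution bin
#'
#' Observations are randomly halved within each (dataset, ASU index) group;
#' each half is merged by inverse-variance-weighted mean intensity, and the
#' two half-dataset merges are correlated (Pearson) within
#' equal-population resolution bins. A CC_half of about 0.3 in the highest
#' resolution shell is the conventional cutoff criterion.
#'
#' @param table A [refl_table()].
#' @param crystal A [crystal_form()].
#' @param merged_fn Optional function(I, SigI) -> scalar used to merge each
#'   half; default inverse-variance-weighted mean.
#' @param n_bins Number of equal-population resolution bins (default 10).
#' @param seed Seed for the random half split.
#' @param scales Optional per-observation multiplicative scale corrections
#'   (e.g. the fitted scale locations of a [vi_merge()]); intensities and
#'   uncertainties are divided by them before merging. Unscaled
#'   polychromatic intensities vary by orders of magnitude with wavelength,
#'   so CC_half is only meaningful after scale correction.
#' @return Data frame (class `"cc_half"`) with one row per bin, ordered from
#'   low to high resolution: `d_max`, `d_min`, `n`, `cc_half` (NA where
#'   fewer than 3 indices were usable). The final row is the highest
#'   resolution shell.
#' @export
cc_half <- function(table, crystal, merged_fn = NULL, n_bins = 10L,
                    seed = 1L, scales = NULL) {
  df <- as.data.frame(table)
  if (!is.null(scales)) {
    stopifnot(length(scales) == nrow(df), all(scales > 0))
    df$I <- df$I / scales
    df$SigI <- df$SigI / scales
  }
  asu <- map_to_asu(cbind(df$h, df$k, df$l), crystal$spacegroup)
  key <- .miller_key(asu$h, asu$k, asu$l, df$dataset)
  d <- resolution(cbind(asu$h, asu$k, asu$l), crystal$cell)
  set.seed(seed)
  perm <- sample.int(nrow(df))
  ord <- perm[order(key[perm])] # original row ids, random within each group
  kk <- key[ord]
  pos <- sequence(rle(kk)$lengths)
  grp_n <- stats::ave(pos, kk, FUN = max)
  usable <- grp_n >= 2L
  half <- pos <= grp_n / 2
  merge_half <- function(rows) {
    if (is.null(merged_fn)) {
      w <- 1 / df$SigI[rows]^2
      num <- rowsum(df$I[rows] * w, key[rows])
      den <- rowsum(w, key[rows])
      stats::setNames(num[, 1L] / den[, 1L], rownames(num))
    } else {
      vapply(split(rows, key[rows]),
             function(rr) merged_fn(df$I[rr], df$SigI[rr]), numeric(1))
    }
  }
  IA <- merge_half(ord[usable & half])
  IB <- merge_half(ord[usable & !half])
  common <- intersect(names(IA), names(IB))
  if (length(common) < 3L) stop("fewer than 3 usable ASU indices")
  dA <- d[match(as.numeric(common), key)]
  qs <- unique(stats::quantile(dA, probs = seq(0, 1,
                                               length.out = n_bins + 1L)))
  qs[1L] <- qs[1L] - 1e-9
  n_bins <- length(qs) - 1L # ties in d can merge bins
  bin <- cut(dA, breaks = qs, labels = FALSE)
  # bin 1 holds the largest d (lowest resolution) after reversing
  bin <- n_bins + 1L - bin
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    cc <- if (sum(sel) >= 3L &&
              stats::sd(IA[common][sel]) > 0 &&
              stats::sd(IB[common][sel]) > 0) {
      stats::cor(IA[common][sel], IB[common][sel])
    } else NA_real_
    data.frame(bin = b, d_max = max(dA[sel]), d_min = min(dA[sel]),
               n = sum(sel), cc_half = cc)
  }))
  structure(out, class = c("cc_half", "data.frame"))
}

#' CC_half of the highest resolution shell
#' @param cc A [cc_half()] table.
#' @return Scalar correlation (possibly NA).
#' @export
cc_half_highest <- function(cc) cc$cc_half[nrow(cc)]

.weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx <= 0 || cyy <= 0) return(NA_real_)
  cxy / sqrt(cxx * cyy)
}

#' Observed-versus-predicted correlation (CC_pred)
#'
#' Correlation between observed and model-predicted intensities on the train
#' and test partitions: either Pearson's correlation with inverse-variance
#' weights 1/SigI^2, or Spearman's unweighted rank correlation.
#'
#' @param predictions Prediction records (see [predict.vi_merge()]): columns
#'   `I`, `SigI`, `predicted_mean_I`, `is_test`.
#' @param method `"pearson_weighted"` or `"spearman"`.
#' @return Named numeric `c(train =, test =)`; NA where a partition is empty
#'   or degenerate.
#' @export
cc_pred <- function(predictions, method = c("pearson_weighted", "spearman")) {
  method <- match.arg(method)
  if (nrow(predictions) == 0L) stop("empty prediction records")
  one <- function(sel) {
    if (sum(sel) < 2L) return(NA_real_)
    x <- predictions$I[sel]
    y <- predictions$predicted_mean_I[sel]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    if (method == "pearson_weighted") {
      .weighted_pearson(x, y, 1 / predictions$SigI[sel]^2)
    } else {
      stats::cor(x, y, method = "spearman")
    }
  }
  c(train = one(!predictions$is_test), test = one(predictions$is_test))
}

#' Bootstrap distribution of CC_pred
#'
#' Resamples the prediction records with replacement (within each partition)
#' and recomputes the correlation, yielding an uncertainty distribution.
#'
#' @inheritParams cc_pred
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Seed.
#' @return List with numeric vectors `train` and `test` of length
#'   `n_resamples` (NA entries flag degenerate resamples).
#' @export
bootstrap_cc <- function(predictions, method = c("pearson_weighted",
                                                 "spearman"),
                         n_resamples = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_resamples >= 2L)
  set.seed(seed)
  idx_tr <- which(!predictions$is_test)
  idx_te <- which(predictions$is_test)
  draw <- function(idx) {
    if (length(idx) < 2L) return(rep(NA_real_, n_resamples))
    vapply(seq_len(n_resamples), function(i) {
      rs <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
      p <- predictions[rs, , drop = FALSE]
      p$is_test <- FALSE
      unname(cc_pred(p, method)["train"])
    }, numeric(1))
  }
  list(train = draw(idx_tr), test = draw(idx_te))
}

# ---- difference maps --------------------------------------------------------

#' Subset a merged table to one dataset
#' @param m A [merged_sf()] table.
#' @param dataset Dataset id.
#' @return A [merged_sf()] table for that dataset.
#' @export
merged_subset <- function(m, dataset) {
  out <- m[m$dataset == dataset, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("merged_sf", "data.frame"))
}

#' Difference-map Fourier coefficients
#'
#' Coefficients of the isomorphous difference map between two merged
#' datasets: (F_t(h) - F_0(h)) exp(i phi_ref(h)), with reference phases from
#' a toy atomic model standing in for a refined reference structure. Indices
#' missing from either dataset are omitted.
#'
#' @param merged_t,merged_0 [merged_sf()] tables (e.g. from
#'   [merged_subset()]).
#' @param model A [toy_model()] supplying reference phases (expected to obey
#'   the crystal symmetry, see [expand_model_symmetry()], when
#'   `expand_symmetry` is used).
#' @param crystal A [crystal_form()].
#' @param expand_symmetry Expand each ASU coefficient over its full
#'   point-group orbit (amplitude difference from the ASU entry, phase from
#'   the model at each orbit member), so the synthesized map covers the
#'   whole reciprocal sphere rather than the asymmetric wedge (default
#'   TRUE; ASU-only synthesis has strong point-spread sidelobes).
#' @return Data frame of class `"map_coefficients"`: `h`, `k`, `l`,
#'   `coefficient` (complex), with the crystal attached as an attribute.
#' @export
difference_coefficients <- function(merged_t, merged_0, model, crystal,
                                    expand_symmetry = TRUE) {
  kt <- .miller_key(merged_t$h, merged_t$k, merged_t$l)
  k0 <- .miller_key(merged_0$h, merged_0$k, merged_0$l)
  m <- match(kt, k0)
  ok <- !is.na(m)
  if (!any(ok)) stop("no common ASU indices between the two datasets")
  hkl <- merged_t[ok, c("h", "k", "l")]
  dF <- merged_t$F[ok] - merged_0$F[m[ok]]
  if (expand_symmetry) {
    ops <- .sg_get(crystal$spacegroup)$ops
    H0 <- as.matrix(hkl)
    He <- do.call(rbind, lapply(ops, function(M) H0 %*% t(M)))
    dFe <- rep(dF, times = length(ops))
    keep <- !duplicated(.miller_key(He[, 1L], He[, 2L], He[, 3L]))
    hkl <- data.frame(h = He[keep, 1L], k = He[keep, 2L], l = He[keep, 3L])
    dF <- dFe[keep]
  }
  Fc <- structure_factors_from_model(model, crystal, hkl = hkl)
  phi <- Arg(Fc)
  out <- data.frame(h = hkl$h, k = hkl$k, l = hkl$l)
  out$coefficient <- dF * complex(modulus = 1, argument = phi)
  attr(out, "crystal") <- crystal
  class(out) <- c("map_coefficients", "data.frame")
  out
}

#' Real-space map synthesis
#'
#' Inverse Fourier synthesis of map coefficients on a regular grid over the
#' unit cell, with Friedel completion so the map is real, followed by sigma
#' scaling (mean 0, standard deviation 1). An all-zero coefficient set gives
#' a flat map, flagged rather than scaled.
#'
#' @param coefficients A [difference_coefficients()] table (or any data
#'   frame with `h`, `k`, `l`, complex `coefficient` plus a `crystal`
#'   attribute or explicit `crystal` argument).
#' @param crystal A [crystal_form()]; defaults to the attribute.
#' @param grid_spacing Target grid spacing in Angstrom; must not exceed
#'   dmin / 2 (sampling theorem).
#' @param sigma_scale Standardize the map to sigma units (default TRUE).
#' @return Object of class `"density_map"`: `grid` (3-D numeric array),
#'   `spacing` (Angstrom per axis), `crystal`, `flat` flag, and the raw
#'   mean/sd removed by scaling.
#' @export
compute_map <- function(coefficients, crystal = attr(coefficients, "crystal"),
                        grid_spacing = NULL, sigma_scale = TRUE) {
  stopifnot(inherits(crystal, "crystal_form"))
  if (is.null(grid_spacing)) grid_spacing <- crystal$dmin / 3
  if (grid_spacing > crystal$dmin / 2 + 1e-12) {
    stop("grid_spacing ", grid_spacing, " A aliases data at dmin ",
         crystal$dmin, " A; need spacing <= dmin/2")
  }
  H <- cbind(coefficients$h, coefficients$k, coefficients$l)
  Fv <- coefficients$coefficient
  nd <- vapply(1:3, function(a) {
    as.integer(max(2L * max(abs(H[, a])) + 2L,
                   ceiling(crystal$cell[a] / grid_spacing)))
  }, integer(1))
  A <- array(0 + 0i, dim = nd)
  idx <- function(Hm) {
    cbind(Hm[, 1L] %% nd[1L], Hm[, 2L] %% nd[2L], Hm[, 3L] %% nd[3L]) + 1L
  }
  ip <- idx(H); im <- idx(-H)
  for (r in seq_len(nrow(H))) {
    A[ip[r, 1L], ip[r, 2L], ip[r, 3L]] <-
      A[ip[r, 1L], ip[r, 2L], ip[r, 3L]] + Fv[r]
    A[im[r, 1L], im[r, 2L], im[r, 3L]] <-
      A[im[r, 1L], im[r, 2L], im[r, 3L]] + Conj(Fv[r])
  }
  rho <- Re(stats::fft(A))
  mu <- mean(rho)
  sdv <- stats::sd(rho)
  flat <- !is.finite(sdv) || sdv < 1e-12
  grid <- if (sigma_scale && !flat) (rho - mu) / sdv else rho
  structure(list(grid = grid, spacing = crystal$cell[1:3] / nd,
                 crystal = crystal, flat = flat, raw_mean = mu,
                 raw_sd = sdv, sigma_scaled = sigma_scale && !flat),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map %s grid, spacing %.2f/%.2f/%.2f A%s\n",
              paste(dim(x$grid), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              if (x$flat) " (flat)" else
                if (x$sigma_scaled) ", sigma-scaled" else " (unscaled)"))
  invisible(x)
}

# periodic shift of a 3-D array by integer offsets
.shift3 <- function(arr, off) {
  d <- dim(arr)
  ix <- lapply(1:3, function(a) ((seq_len(d[a]) - 1L - off[a]) %% d[a]) + 1L)
  arr[ix[[1L]], ix[[2L]], ix[[3L]]]
}

#' Extract difference-map peaks
#'
#' Local extrema of a sigma-scaled map with |height| at or above a
#' threshold, positions refined by a quadratic fit over the 3x3x3
#' neighborhood of the extremal voxel (periodic boundary). Peak finding is
#' symmetric under sign flip of the map.
#'
#' @param map A [compute_map()] result (sigma-scaled).
#' @param threshold_sigma Minimum |height| in sigma units (default 3, the
#'   conventional noise standard).
#' @return Data frame of class `"peak_list"`: fractional `x`, `y`, `z`,
#'   `height` (sigma units, signed), `sign`; sorted by |height| descending.
#' @export
find_peaks <- function(map, threshold_sigma = 3.0) {
  g <- map$grid
  if (map$flat) {
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), height = numeric(0),
                                sign = integer(0)),
                     class = c("peak_list", "data.frame")))
  }
  d <- dim(g)
  find_side <- function(arr, sgn) {
    is_max <- array(TRUE, dim = d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0L && dy == 0L && dz == 0L) next
      is_max <- is_max & (arr >= .shift3(arr, c(dx, dy, dz)))
    }
    sel <- which(is_max & arr >= threshold_sigma, arr.ind = TRUE)
    if (nrow(sel) == 0L) return(NULL)
    out <- lapply(seq_len(nrow(sel)), function(i) {
      v <- sel[i, ]
      v0 <- arr[v[1L], v[2L], v[3L]]
      pos <- numeric(3); hadd <- 0
      for (a in 1:3) {
        vm <- v; vm[a] <- ((vm[a] - 2L) %% d[a]) + 1L
        vp <- v; vp[a] <- (vp[a] %% d[a]) + 1L
        fm <- arr[vm[1L], vm[2L], vm[3L]]
        fp <- arr[vp[1L], vp[2L], vp[3L]]
        den <- fm - 2 * v0 + fp
        del <- if (den < 0) max(-0.5, min(0.5, 0.5 * (fm - fp) / den)) else 0
        pos[a] <- (v[a] - 1 + del) / d[a]
        hadd <- hadd + 0.5 * (fp - fm) * del + 0.5 * (fp + fm - 2 * v0) * del^2
      }
      data.frame(x = pos[1L], y = pos[2L], z = pos[3L],
                 height = sgn * (v0 + hadd), sign = sgn)
    })
    do.call(rbind, out)
  }
  res <- rbind(find_side(g, 1L), find_side(-g, -1L))
  if (is.null(res)) {
    res <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      height = numeric(0), sign = integer(0))
  } else {
    res <- res[order(-abs(res$height)), ]
    rownames(res) <- NULL
  }
  structure(res, class = c("peak_list", "data.frame"))
}

# fractional -> cartesian orthogonalization matrix of a cell
.frac_to_cart <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  rbind(
    c(a, b * cos(ga), cc * cos(be)),
    c(0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)),
    c(0, 0, cc * v / sin(ga))
  )
}

# minimum-image cartesian distance of all voxels to a fractional site
.voxel_dist <- function(map, center) {
  d <- dim(map$grid)
  fr <- lapply(1:3, function(a) (seq_len(d[a]) - 1) / d[a])
  M <- .frac_to_cart(map$crystal$cell)
  dx <- lapply(1:3, function(a) {
    del <- fr[[a]] - center[a]
    del - round(del)
  })
  D2 <- array(0, dim = d)
  # cartesian distance via metric tensor on fractional deltas
  G <- crossprod(M)
  del1 <- dx[[1L]]; del2 <- dx[[2L]]; del3 <- dx[[3L]]
  A1 <- array(rep(del1, times = d[2L] * d[3L]), dim = d)
  A2 <- array(rep(rep(del2, each = d[1L]), times = d[3L]), dim = d)
  A3 <- array(rep(del3, each = d[1L] * d[2L]), dim = d)
  D2 <- G[1, 1] * A1^2 + G[2, 2] * A2^2 + G[3, 3] * A3^2 +
    2 * G[1, 2] * A1 * A2 + 2 * G[1, 3] * A1 * A3 + 2 * G[2, 3] * A2 * A3
  sqrt(pmax(D2, 0))
}

#' Spherical mask about a site
#' @param map A [compute_map()] result.
#' @param center Fractional coordinates of the site.
#' @param radius Radius in Angstrom.
#' @return Logical array over the map grid.
#' @export
mask_sphere <- function(map, center, radius = 2.0) {
  .voxel_dist(map, center) <= radius
}

#' Union-of-atom-spheres mask
#' @param map A [compute_map()] result.
#' @param model A [toy_model()].
#' @param radius Per-atom radius in Angstrom.
#' @return Logical array over the map grid.
#' @export
mask_atoms <- function(map, model, radius = 2.0) {
  m <- array(FALSE, dim = dim(map$grid))
  for (i in seq_len(nrow(model$atoms))) {
    m <- m | mask_sphere(map, as.numeric(model$atoms[i, c("x", "y", "z")]),
                         radius)
  }
  m
}

#' Real-space correlation coefficient
#'
#' Pearson correlation of two maps over a masked region.
#' @param map_a,map_b [compute_map()] results on identical grids.
#' @param mask Logical array (e.g. [mask_sphere()], [mask_atoms()]); default
#'   all voxels.
#' @return Scalar correlation (NA, with a warning, if a map is constant
#'   within the mask).
#' @export
rscc <- function(map_a, map_b, mask = NULL) {
  stopifnot(identical(dim(map_a$grid), dim(map_b$grid)))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(map_a$grid))
  if (!any(mask)) stop("mask is empty")
  x <- map_a$grid[mask]; y <- map_b$grid[mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant map within mask; RSCC undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Map value at a fractional position (trilinear interpolation)
#' @param map A [compute_map()] result.
#' @param pos Fractional coordinates.
#' @return Interpolated map value.
#' @export
map_value_at <- function(map, pos) {
  d <- dim(map$grid)
  val <- 0
  base <- pos * d
  i0 <- floor(base)
  fr <- base - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    ii <- (c(i0[1L] + dx, i0[2L] + dy, i0[3L] + dz)) %% d + 1L
    val <- val + w * map$grid[ii[1L], ii[2L], ii[3L]]
  }
  val
}

# ---- scale vs wavelength ----------------------------------------------------

#' Fitted scale versus wavelength diagnostic
#'
#' Two-dimensional histogram of the fitted per-observation scale location
#' against the observation's peak wavelength, with a per-wavelength-bin
#' median summary curve. When the scale model is given the wavelength
#' metadatum, the curve reproduces the beam's spectral shape; when the
#' wavelength is withheld, the curve is flat.
#'
#' @param fit A poly-mode [vi_merge()] fit.
#' @param n_bins Number of bins per axis (default 20).
#' @param normalize_images Divide each observation's scale by its image's
#'   median scale before binning (default TRUE), so the wavelength profile
#'   is not blurred by per-crystal scale variation.
#' @param partition Which observations enter the diagnostic: `"all"`,
#'   `"train"`, or `"test"`. On small scenes an expressive scale model can
#'   partially memorize per-observation intensity variation through the
#'   detector-position and image features, which re-creates a spectrum-like
#'   profile even without the wavelength metadatum; the held-out partition
#'   is immune to this and is the honest choice for the flatness contrast.
#' @return List of class `"scale_wavelength"`: `hist` (counts matrix),
#'   `lambda_breaks`, `scale_breaks`, `curve` (data frame of bin-mid
#'   wavelength and median scale).
#' @export
scale_vs_wavelength <- function(fit, n_bins = 20L,
                                partition = c("all", "train", "test"),
                                normalize_images = TRUE) {
  stopifnot(inherits(fit, "vi_merge"))
  partition <- match.arg(partition)
  if (fit$mode != "poly") {
    stop("scale_vs_wavelength requires a poly-mode fit (no wavelength axis ",
         "in mono mode)")
  }
  os <- fit$obs_scale
  if (is.null(os) || all(is.na(os$wavelength))) {
    stop("fit has no recoverable per-observation scales with wavelengths")
  }
  if (normalize_images) {
    # remove the per-image scale component (crystal size/quality), which is
    # nuisance variance for the wavelength profile
    imed <- stats::ave(os$scale_location,
                       paste(os$dataset, os$image), FUN = stats::median)
    os$scale_location <- os$scale_location / imed
  }
  if (partition != "all") {
    keep <- if (partition == "train") !fit$predictions$is_test
            else fit$predictions$is_test
    os <- os[keep, , drop = FALSE]
  }
  lb <- seq(min(os$wavelength), max(os$wavelength), length.out = n_bins + 1L)
  sb <- seq(min(os$scale_location), max(os$scale_location),
            length.out = n_bins + 1L)
  li <- pmin(pmax(findInterval(os$wavelength, lb, all.inside = TRUE), 1L),
             n_bins)
  si <- pmin(pmax(findInterval(os$scale_location, sb, all.inside = TRUE), 1L),
             n_bins)
  h <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(li)) h[si[i], li[i]] <- h[si[i], li[i]] + 1L
  # summary curve over equal-population wavelength bins: a few-percent
  # bandwidth beam concentrates nearly all observations near the peak, so
  # equal-width bins would be empty or noise-dominated in the tail
  qb <- unique(stats::quantile(os$wavelength,
                               probs = seq(0, 1, length.out = n_bins + 1L)))
  qb[1L] <- qb[1L] - 1e-12
  qi_ <- cut(os$wavelength, qb, labels = FALSE)
  med <- tapply(os$scale_location, qi_, stats::median)
  lam_med <- tapply(os$wavelength, qi_, stats::median)
  curve <- data.frame(lambda = as.numeric(lam_med),
                      median_scale = as.numeric(med))
  curve <- curve[order(curve$lambda), ]
  structure(list(hist = h, lambda_breaks = lb, scale_breaks = sb,
                 curve = curve),
            class = "scale_wavelength")
}

#' @export
plot.scale_wavelength <- function(x, ...) {
  graphics::image(x$lambda_breaks, x$scale_breaks, t(x$hist),
                  xlab = "wavelength (A)", ylab = "fitted scale",
                  main = "scale vs wavelength", ...)
  graphics::lines(x$curve$lambda, x$curve$median_scale, col = 2, lwd = 2)
  invisible(x)
}

# ---- cross-validation report ------------------------------------------------

#' Full cross-validation report for a fit
#'
#' Bundles the observed-versus-predicted correlations (weighted Pearson and
#' Spearman, train and test), their bootstrap distributions, and the
#' per-resolution-shell CC_half of the scale-corrected data.
#'
#' @param fit A [vi_merge()] fit.
#' @param table The reflection table the fit was trained on.
#' @param crystal A [crystal_form()].
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap and the CC_half half-split.
#' @return List of class `"cross_validation_report"` with elements
#'   `cc_pred_pearson`, `cc_pred_spearman` (each `c(train, test)`),
#'   `bootstrap_pearson`, `bootstrap_spearman` (each a list of train/test
#'   vectors), and `cc_half` (per-bin table).
#' @export
cross_validation_report <- function(fit, table, crystal,
                                    n_resamples = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "vi_merge"))
  scales <- if (!is.null(fit$obs_scale)) fit$obs_scale$scale_location
  out <- list(
    cc_pred_pearson = cc_pred(fit$predictions, "pearson_weighted"),
    cc_pred_spearman = cc_pred(fit$predictions, "spearman"),
    bootstrap_pearson = bootstrap_cc(fit$predictions, "pearson_weighted",
                                     n_resamples, seed),
    bootstrap_spearman = bootstrap_cc(fit$predictions, "spearman",
                                      n_resamples, seed),
    cc_half = tryCatch(cc_half(table, crystal, seed = seed,
                               scales = scales),
                       error = function(e) NULL)
  )
  class(out) <- "cross_validation_report"
  out
}

#' @export
print.cross_validation_report <- function(x, ...) {
  f3 <- function(v) ifelse(is.na(v), "-", sprintf("%.3f", v))
  cat(sprintf("CC_pred (weighted Pearson): train %s / test %s\n",
              f3(x$cc_pred_pearson["train"]), f3(x$cc_pred_pearson["test"])))
  cat(sprintf("CC_pred (Spearman):         train %s / test %s\n",
              f3(x$cc_pred_spearman["train"]),
              f3(x$cc_pred_spearman["test"])))
  cat(sprintf("bootstrap (n = %d): Pearson train sd %s, test sd %s\n",
              length(x$bootstrap_pearson$train),
              f3(stats::sd(x$bootstrap_pearson$train, na.rm = TRUE)),
              f3(stats::sd(x$bootstrap_pearson$test, na.rm = TRUE))))
  if (!is.null(x$cc_half)) {
    cat(sprintf("CC_half: %d shells, highest-resolution shell %s\n",
                nrow(x$cc_half), f3(cc_half_highest(x$cc_half))))
  }
  invisible(x)
}

# ---- map export -------------------------------------------------------------

#' Write a map in CCP4/MRC format
#'
#' Minimal CCP4 map writer (mode 2, float32, full cell, axis order x y z)
#' for visual inspection in standard viewers.
#' @param map A [compute_map()] result.
#' @param path Output file path.
#' @export
write_ccp4_map <- function(map, path) {
  g <- map$grid
  d <- dim(g)
  cell <- map$crystal$cell
  con <- file(path, open = "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(d)                    # NC NR NS
  wi(2L)                   # MODE float32
  wi(c(0L, 0L, 0L))        # start
  wi(d)                    # intervals
  wf(cell)                 # cell
  wi(c(1L, 2L, 3L))        # axis order
  wf(c(min(g), max(g), mean(g)))
  wi(1L)                   # ISPG
  wi(0L)                   # NSYMBT
  wi(integer(25L))         # extra
  wi(c(0L, 0L, 0L))        # origin (words 50-52)
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(stats::sd(g))         # RMS
  wi(1L)                   # NLABL
  writeChar(formatC("difference map", width = -800), con, 800L, eos = NULL)
  wf(as.numeric(g))
  invisible(path)
}
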