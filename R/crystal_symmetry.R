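# Crystal-form bookkeeping: unit-cell geometry, point-group symmetry, mapping
# of Miller indices to the asymmetric unit, centricity/multiplicity, central-ray
# harmonic enumeration, and reconciliation of merohedral indexing ambiguities.

# ---- space-group registry ---------------------------------------------------

# Point-group operations are stored as 3x3 integer matrices M acting on Miller
# index column vectors, h' = M h. Groups are generated by closure from a small
# generator set rather than hard-coded tables.
.sg_close_group <- function(gens) {
  key <- function(M) paste(as.integer(M), collapse = ",")
  ops <- list(diag(3L))
  names(ops) <- key(ops[[1L]])
  repeat {
    added <- FALSE
    for (a in ops) for (g in gens) {
      M <- a %*% g
      k <- key(M)
      if (is.null(ops[[k]])) {
        ops[[k]] <- M
        added <- TRUE
      }
    }
    if (!added) break
  }
  unname(ops)
}

.sg_registry <- local({
  reg <- list()

  rs <- function(R, t) list(R = R, t = t)
  reg[["P1"]] <- list(
    ops = list(diag(3L)),
    ambiguity_op = NULL,
    realspace_ops = list(rs(diag(3), c(0, 0, 0)))
  )

  # monoclinic, unique axis b: two-fold screw
  reg[["P21"]] <- list(
    ops = .sg_close_group(list(diag(c(-1L, 1L, -1L)))),
    ambiguity_op = NULL,
    realspace_ops = list(
      rs(diag(3), c(0, 0, 0)),
      rs(diag(c(-1, 1, -1)), c(0, 0.5, 0))
    )
  )

  # trigonal point group 321 (hexagonal axes): generated by the three-fold
  # (h,k,l) -> (k,-h-k,l) and the two-fold (h,k,l) -> (k,h,-l).
  g3 <- rbind(c(0L, 1L, 0L), c(-1L, -1L, 0L), c(0L, 0L, 1L))
  g2 <- rbind(c(0L, 1L, 0L), c(1L, 0L, 0L), c(0L, 0L, -1L))
  R3 <- rbind(c(0, -1, 0), c(1, -1, 0), c(0, 0, 1))
  R2 <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1))
  reg[["P3121"]] <- list(
    ops = .sg_close_group(list(g3, g2)),
    # merohedral twin law of the hexagonal lattice: two-fold about c
    ambiguity_op = diag(c(-1L, -1L, 1L)),
    # general positions of the 3_1 21 group (screw translations along c)
    realspace_ops = list(
      rs(diag(3), c(0, 0, 0)),
      rs(R3, c(0, 0, 1 / 3)),
      rs(R3 %*% R3, c(0, 0, 2 / 3)),
      rs(R2, c(0, 0, 0)),
      rs(R3 %*% R2, c(0, 0, 1 / 3)),
      rs(R3 %*% R3 %*% R2, c(0, 0, 2 / 3))
    )
  )

  reg
})

.sg_get <- function(spacegroup) {
  entry <- .sg_registry[[spacegroup]]
  if (is.null(entry)) {
    stop("unsupported space group '", spacegroup, "'; supported: ",
         paste(names(.sg_registry), collapse = ", "), call. = FALSE)
  }
  entry
}

#' Supported space-group symbols
#' @return Character vector of space-group symbols the package understands.
#' @export
supported_spacegroups <- function() names(.sg_registry)

# ---- crystal form -----------------------------------------------------------

#' Define a crystal form
#'
#' Bundles the unit cell, space group, and resolution cutoff that together
#' define the reciprocal-space bookkeeping for a merging run.
#'
#' @param cell Numeric length-6: a, b, c in Angstrom; alpha, beta, gamma in
#'   degrees.
#' @param spacegroup Space-group symbol; see [supported_spacegroups()].
#' @param dmin High-resolution cutoff in Angstrom.
#' @return An object of class `"crystal_form"`.
#' @examples
#' crystal_form(c(10, 10, 14, 90, 90, 120), "P3121", dmin = 2)
#' @export
crystal_form <- function(cell, spacegroup = "P1", dmin = 2) {
  cell <- as.numeric(cell)
  if (length(cell) != 6L) stop("cell must have 6 components")
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  if (!is.numeric(dmin) || dmin <= 0) stop("dmin must be positive")
  .sg_get(spacegroup)
  structure(
    list(cell = cell, spacegroup = spacegroup, dmin = dmin),
    class = "crystal_form"
  )
}

#' @export
print.crystal_form <- function(x, ...) {
  cat(sprintf(
    "Crystal form: %s, cell %.3f %.3f %.3f / %.2f %.2f %.2f, dmin %.2f A\n",
    x$spacegroup, x$cell[1], x$cell[2], x$cell[3],
    x$cell[4], x$cell[5], x$cell[6], x$dmin
  ))
  invisible(x)
}

# Direct-space metric tensor (A^2) of a unit cell.
.cell_metric <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  rbind(
    c(a * a, a * b * cos(ga), a * cc * cos(be)),
    c(a * b * cos(ga), b * b, b * cc * cos(al)),
    c(a * cc * cos(be), b * cc * cos(al), cc * cc)
  )
}

# Reciprocal metric tensor (A^-2).
.cell_recip_metric <- function(cell) solve(.cell_metric(cell))

.as_miller_matrix <- function(miller) {
  if (is.null(dim(miller))) miller <- matrix(miller, nrow = 1L)
  miller <- as.matrix(miller)
  if (ncol(miller) != 3L) stop("miller must have three columns (h, k, l)")
  storage.mode(miller) <- "integer"
  miller
}

#' Resolution of reflections
#'
#' d-spacing of one or more Miller indices, computed from the reciprocal
#' metric tensor of the cell.
#'
#' @param miller Integer vector (h, k, l) or an n-by-3 matrix of indices.
#' @param cell Length-6 cell, or a [crystal_form()].
#' @return Numeric vector of d-spacings in Angstrom.
#' @examples
#' resolution(c(1, 0, 0), c(10, 20, 30, 90, 90, 90)) # 10 A
#' @export
resolution <- function(miller, cell) {
  if (inherits(cell, "crystal_form")) cell <- cell$cell
  H <- .as_miller_matrix(miller)
  if (any(rowSums(abs(H)) == 0L)) stop("miller index (0,0,0) has no resolution")
  Gs <- .cell_recip_metric(cell)
  q <- rowSums((H %*% Gs) * H)
  1 / sqrt(q)
}

# ---- ASU mapping ------------------------------------------------------------

# Lexicographic comparison helper: TRUE where tuple A > tuple B.
.lex_gt <- function(A, B) {
  (A[, 1L] > B[, 1L]) |
    (A[, 1L] == B[, 1L] & (A[, 2L] > B[, 2L] |
      (A[, 2L] == B[, 2L] & A[, 3L] > B[, 3L])))
}

#' Map Miller indices to the asymmetric unit
#'
#' Canonicalizes Miller indices under the point group of the space group plus
#' Friedel inversion, and reports centricity and the orbit multiplicity
#' epsilon. The canonical representative is the lexicographically greatest
#' (h, k, l) tuple in the Friedel-expanded orbit; this convention is arbitrary
#' but fixed.
#'
#' @param miller Integer (h, k, l) vector or n-by-3 matrix.
#' @param spacegroup Space-group symbol.
#' @return A data frame with columns `h`, `k`, `l` (the ASU representative),
#'   `centric` (logical: -h lies in the point-group orbit of h), and
#'   `epsilon` (integer stabilizer multiplicity).
#' @examples
#' map_to_asu(c(-1, 2, 3), "P1")
#' @export
map_to_asu <- function(miller, spacegroup = "P1") {
  H <- .as_miller_matrix(miller)
  ops <- .sg_get(spacegroup)$ops
  n <- nrow(H)
  best <- H
  centric <- rep(FALSE, n)
  epsilon <- rep(0L, n)
  for (M in ops) {
    Hm <- H %*% t(M)
    epsilon <- epsilon + as.integer(rowSums(Hm == H) == 3L)
    centric <- centric | rowSums(Hm == -H) == 3L
    upd <- .lex_gt(Hm, best)
    best[upd, ] <- Hm[upd, , drop = FALSE]
    upd <- .lex_gt(-Hm, best)
    best[upd, ] <- -Hm[upd, , drop = FALSE]
  }
  out <- data.frame(h = unname(best[, 1L]), k = unname(best[, 2L]),
                    l = unname(best[, 3L]), centric = centric,
                    epsilon = epsilon)
  rownames(out) <- NULL
  out
}

# Integer key for (dataset, h, k, l) grouping; assumes |index| < 512.
.miller_key <- function(h, k, l, dataset = NULL) {
  base <- 1024L
  key <- ((h + 512L) * base + (k + 512L)) * base + (l + 512L)
  if (!is.null(dataset)) key <- key + as.numeric(dataset) * base^3
  key
}

#' Enumerate the asymmetric-unit index set of a crystal form
#'
#' All unique ASU Miller indices with d-spacing at or beyond the crystal's
#' resolution cutoff, together with centricity, epsilon, and resolution.
#'
#' @param crystal A [crystal_form()].
#' @return Data frame with columns `h`, `k`, `l`, `d`, `centric`, `epsilon`.
#' @export
asu_indices <- function(crystal) {
  stopifnot(inherits(crystal, "crystal_form"))
  hmax <- ceiling(max(crystal$cell[1:3]) / crystal$dmin) + 1L
  rng <- -hmax:hmax
  grid <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  grid <- grid[rowSums(abs(grid)) > 0L, , drop = FALSE]
  d <- resolution(grid, crystal$cell)
  keep <- d >= crystal$dmin
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  asu <- map_to_asu(grid, crystal$spacegroup)
  own <- asu$h == grid[, 1L] & asu$k == grid[, 2L] & asu$l == grid[, 3L]
  out <- data.frame(h = asu$h[own], k = asu$k[own], l = asu$l[own],
                    d = d[own], centric = asu$centric[own],
                    epsilon = asu$epsilon[own])
  out <- out[!duplicated(.miller_key(out$h, out$k, out$l)), ]
  out <- out[order(-out$h, -out$k, -out$l), ]
  rownames(out) <- NULL
  out
}

# ---- harmonics --------------------------------------------------------------

.gcd2 <- function(a, b) { while (b != 0L) { t <- b; b <- a %% b; a <- t }; a }
.gcd3 <- function(v) .gcd2(.gcd2(abs(v[1L]), abs(v[2L])), abs(v[3L]))

#' Enumerate harmonic candidates on a central ray
#'
#' Reflections n * (h0, k0, l0) on one central ray of reciprocal space arrive
#' at the same detector position; order n diffracts at wavelength lambda/n
#' relative to the order-1 member. Given an observation of `miller` at
#' `lambda_obs`, this enumerates every order whose diffraction wavelength lies
#' within the beam's wavelength window and whose resolution is within the
#' crystal's cutoff.
#'
#' @param miller Integer (h, k, l) as recorded at integration.
#' @param lambda_obs Observed (assigned) wavelength in Angstrom.
#' @param cell Length-6 cell or [crystal_form()].
#' @param lambda_min,lambda_max Beam wavelength window in Angstrom.
#' @param dmin Resolution cutoff in Angstrom.
#' @param nmax Maximum harmonic order considered (default 8; higher orders are
#'   unreachable for realistic few-percent-bandwidth spectra).
#' @return A list of class `"harmonic_group"` with `primitive_ray` (integer
#'   triple, gcd 1) and `members`, a data frame of `n`, `h`, `k`, `l`,
#'   `wavelength`, `d` ordered by n.
#' @examples
#' harmonic_candidates(c(1, 1, 1), 2.0, c(30, 30, 30, 90, 90, 90),
#'                     lambda_min = 0.95, lambda_max = 2.1, dmin = 1)
#' @export
harmonic_candidates <- function(miller, lambda_obs, cell,
                                lambda_min, lambda_max, dmin, nmax = 8L) {
  if (inherits(cell, "crystal_form")) {
    if (missing(dmin)) dmin <- cell$dmin
    cell <- cell$cell
  }
  stopifnot(lambda_min < lambda_max, lambda_obs > 0)
  m <- as.integer(miller)
  if (all(m == 0L)) stop("miller index (0,0,0) is not a reflection")
  g <- .gcd3(m)
  ray <- m %/% g
  lambda1 <- g * lambda_obs # order-1 wavelength of this ray
  n <- seq_len(nmax)
  lam <- lambda1 / n
  H <- outer(n, ray)
  d <- resolution(H, cell)
  keep <- lam >= lambda_min & lam <= lambda_max & d >= dmin
  if (!any(keep)) {
    stop("no harmonic member of ray (", paste(ray, collapse = ","),
         ") lies inside the wavelength window and resolution cutoff")
  }
  members <- data.frame(n = n[keep], h = H[keep, 1L], k = H[keep, 2L],
                        l = H[keep, 3L], wavelength = lam[keep], d = d[keep])
  structure(list(primitive_ray = ray, members = members),
            class = "harmonic_group")
}

# ---- indexing-ambiguity resolution ------------------------------------------

# Merge an image's observations against a consensus and compute the Pearson
# correlation under both indexing conventions. Returns c(cor_identity, cor_alt)
# with NA where fewer than 2 common reflections exist.
.image_corrs <- function(I, key_id, key_alt, cons_key, cons_I) {
  out <- c(NA_real_, NA_real_)
  for (j in 1:2) {
    keys <- if (j == 1L) key_id else key_alt
    idx <- match(keys, cons_key)
    ok <- !is.na(idx)
    if (sum(ok) >= 2L) {
      x <- I[ok]; y <- cons_I[idx[ok]]
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        # rank correlation: robust to the order-of-magnitude flux and
        # per-image scale variation of unscaled pink-beam intensities
        out[j] <- stats::cor(x, y, method = "spearman")
      }
    }
  }
  out
}

#' Resolve a two-fold indexing ambiguity across images and datasets
#'
#' For space groups whose point-group symmetry is lower than the lattice
#' symmetry (e.g. P3121), each image can be indexed in one of two equivalent
#' conventions. This routine assigns each image the identity or the
#' alternative (twin) operator by iteratively maximizing the Pearson
#' correlation between the image's intensities and the consensus merged
#' intensities of its dataset, sweeping until no assignment changes; each
#' dataset's global convention is then aligned to a reference dataset by the
#' same criterion. The iterative correlation sweep is this package's own
#' algorithm (the programs used for the original data are unpublished).
#'
#' @param table A reflection table (see [refl_table()]), possibly spanning
#'   several datasets.
#' @param crystal A [crystal_form()] whose space group carries the ambiguity.
#' @param reference_dataset Dataset id whose convention is kept fixed.
#' @param max_sweeps Maximum image-sweep iterations per dataset.
#' @param margin Hysteresis: an image is flipped only when the alternative
#'   convention's correlation exceeds the current one by this much,
#'   preventing noise-driven flips on images with few observations.
#' @return A list with `table` (the reindexed reflection table), `assignment`
#'   (data frame: dataset, image, operator "identity"/"alternative"), and
#'   `flagged` (images with fewer than 2 reflections in common with the
#'   consensus, left on identity).
#' @export
resolve_indexing_ambiguity <- function(table, crystal, reference_dataset = 0L,
                                       max_sweeps = 20L, margin = 0.02) {
  stopifnot(inherits(crystal, "crystal_form"))
  op <- .sg_get(crystal$spacegroup)$ambiguity_op
  if (is.null(op)) {
    stop("space group ", crystal$spacegroup, " has no indexing ambiguity")
  }
  df <- as.data.frame(table)
  H <- cbind(df$h, df$k, df$l)
  asu_id <- map_to_asu(H, crystal$spacegroup)
  asu_alt <- map_to_asu(H %*% t(op), crystal$spacegroup)
  key_id <- .miller_key(asu_id$h, asu_id$k, asu_id$l)
  key_alt <- .miller_key(asu_alt$h, asu_alt$k, asu_alt$l)

  img_key <- paste(df$dataset, df$image, sep = ":")
  imgs <- unique(img_key)
  flip <- stats::setNames(rep(FALSE, length(imgs)), imgs)
  flagged <- character(0)
  img_rows <- split(seq_len(nrow(df)), img_key)

  datasets <- sort(unique(df$dataset))
  for (ds in datasets) {
    ds_imgs <- imgs[startsWith(imgs, paste0(ds, ":"))]
    if (length(ds_imgs) == 0L) next
    rows_ds <- unlist(img_rows[ds_imgs], use.names = FALSE)
    # seed the consensus with the first image, then grow it image by image
    cons_rows <- img_rows[[ds_imgs[1L]]]
    cons <- rowsum(df$I[cons_rows], key_id[cons_rows])
    cnt <- rowsum(rep(1, length(cons_rows)), key_id[cons_rows])
    cons_key <- as.numeric(rownames(cons))
    cons_I <- cons[, 1L] / cnt[, 1L]
    for (im in ds_imgs[-1L]) {
      r <- img_rows[[im]]
      cc <- .image_corrs(df$I[r], key_id[r], key_alt[r], cons_key, cons_I)
      if (!all(is.na(cc)) &&
          isTRUE(cc[2L] > cc[1L] + margin || is.na(cc[1L]))) {
        flip[im] <- TRUE
      }
      keys <- if (flip[im]) key_alt[r] else key_id[r]
      add <- rowsum(df$I[r], keys)
      addc <- rowsum(rep(1, length(r)), keys)
      m <- match(as.numeric(rownames(add)), cons_key)
      new <- is.na(m)
      if (any(!new)) {
        tot <- cons_I[m[!new]] * cnt[m[!new]] + add[!new, 1L]
        cnt[m[!new]] <- cnt[m[!new]] + addc[!new, 1L]
        cons_I[m[!new]] <- tot / cnt[m[!new]]
      }
      if (any(new)) {
        cons_key <- c(cons_key, as.numeric(rownames(add))[new])
        cons_I <- c(cons_I, add[new, 1L] / addc[new, 1L])
        cnt <- c(cnt, addc[new, 1L])
      }
    }
    # batch sweeps against the full-dataset consensus until stable
    for (sweep in seq_len(max_sweeps)) {
      keys_cur <- ifelse(flip[img_key[rows_ds]], key_alt[rows_ds],
                         key_id[rows_ds])
      cons <- rowsum(df$I[rows_ds], keys_cur)
      cnt2 <- rowsum(rep(1, length(rows_ds)), keys_cur)
      cons_key <- as.numeric(rownames(cons))
      cons_I <- cons[, 1L] / cnt2[, 1L]
      changed <- FALSE
      for (im in ds_imgs) {
        r <- img_rows[[im]]
        cc <- .image_corrs(df$I[r], key_id[r], key_alt[r], cons_key, cons_I)
        if (all(is.na(cc))) {
          if (sweep == max_sweeps && flip[im]) { flip[im] <- FALSE }
          if (!(im %in% flagged)) flagged <- c(flagged, im)
          next
        }
        # flip only when the other convention clearly beats the current one
        cur <- flip[im]
        sc_cur <- if (cur) cc[2L] else cc[1L]
        sc_oth <- if (cur) cc[1L] else cc[2L]
        if ((is.na(sc_cur) && !is.na(sc_oth)) ||
            isTRUE(sc_oth > sc_cur + margin)) {
          flip[im] <- !cur
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  # align each dataset's global convention to the reference dataset
  ref_rows <- which(df$dataset == reference_dataset)
  if (length(ref_rows) > 0L) {
    keys_ref <- ifelse(flip[img_key[ref_rows]], key_alt[ref_rows],
                       key_id[ref_rows])
    cons <- rowsum(df$I[ref_rows], keys_ref)
    cnt <- rowsum(rep(1, length(ref_rows)), keys_ref)
    ref_key <- as.numeric(rownames(cons))
    ref_I <- cons[, 1L] / cnt[, 1L]
    for (ds in setdiff(datasets, reference_dataset)) {
      rows_ds <- which(df$dataset == ds)
      fl <- flip[img_key[rows_ds]]
      k1 <- ifelse(fl, key_alt[rows_ds], key_id[rows_ds])
      k2 <- ifelse(fl, key_id[rows_ds], key_alt[rows_ds])
      cc <- .image_corrs(df$I[rows_ds], k1, k2, ref_key, ref_I)
      if (isTRUE(cc[2L] > cc[1L])) {
        ds_imgs <- imgs[startsWith(imgs, paste0(ds, ":"))]
        flip[ds_imgs] <- !flip[ds_imgs]
      }
    }
  }

  # final polish: one sweep of every image against the cross-dataset global
  # consensus (time points are highly correlated, so pooling sharpens the
  # decision and dissolves mixed within-dataset local optima)
  gkey_id <- .miller_key(asu_id$h, asu_id$k, asu_id$l)
  gkey_alt <- .miller_key(asu_alt$h, asu_alt$k, asu_alt$l)
  for (sweep in seq_len(max_sweeps)) {
    keys_cur <- ifelse(flip[img_key], gkey_alt, gkey_id)
    cons <- rowsum(df$I, keys_cur)
    cnt <- rowsum(rep(1, nrow(df)), keys_cur)
    cons_key <- as.numeric(rownames(cons))
    cons_I <- cons[, 1L] / cnt[, 1L]
    changed <- FALSE
    for (im in imgs) {
      r <- img_rows[[im]]
      cc <- .image_corrs(df$I[r], gkey_id[r], gkey_alt[r], cons_key, cons_I)
      if (all(is.na(cc))) next
      cur <- flip[im]
      sc_cur <- if (cur) cc[2L] else cc[1L]
      sc_oth <- if (cur) cc[1L] else cc[2L]
      if ((is.na(sc_cur) && !is.na(sc_oth)) ||
          isTRUE(sc_oth > sc_cur + margin)) {
        flip[im] <- !cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  do_flip <- flip[img_key]
  if (any(do_flip)) {
    Hf <- H[do_flip, , drop = FALSE] %*% t(op)
    df$h[do_flip] <- Hf[, 1L]
    df$k[do_flip] <- Hf[, 2L]
    df$l[do_flip] <- Hf[, 3L]
  }
  parts <- do.call(rbind, strsplit(imgs, ":", fixed = TRUE))
  assignment <- data.frame(
    dataset = as.integer(parts[, 1L]),
    image = as.integer(parts[, 2L]),
    operator = ifelse(flip, "alternative", "identity")
  )
  assignment <- assignment[order(assignment$dataset, assignment$image), ]
  rownames(assignment) <- NULL
  list(table = refl_table(df, metadata_keys = attr(table, "metadata_keys")),
       assignment = assignment, flagged = flagged)
}

#' Symmetry mates of a real-space site
#'
#' Fractional coordinates of the orbit of a site under the space group's
#' real-space operations (rotations plus screw translations), wrapped into
#' the unit cell. A symmetric difference map peaks at every member of the
#' planted site's orbit.
#'
#' @param site Fractional coordinates (length 3).
#' @param spacegroup Space-group symbol.
#' @return Matrix with one row per (unique) mate.
#' @export
site_symmetry_mates <- function(site, spacegroup) {
  ops <- .sg_get(spacegroup)$realspace_ops
  m <- t(vapply(ops, function(op) {
    as.numeric((op$R %*% site + op$t) %% 1)
  }, numeric(3)))
  unique(round(m, 10))
}

#' Write an operator-assignment report
#'
#' Two-column text report (image id, operator) from the output of
#' [resolve_indexing_ambiguity()].
#' @param assignment The `assignment` data frame.
#' @param path Output file path.
#' @export
write_assignment_report <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
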