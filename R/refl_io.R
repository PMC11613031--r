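# Data model and readers/writers for unmerged reflection observations and
# merged structure-factor tables. Two dialects are supported: a tab-separated
# text dialect (reviewable fixtures, exact column vocabulary below) and the
# binary MTZ reflection format.

.refl_required <- c("dataset", "image", "h", "k", "l", "I", "SigI")
.refl_reals <- c("I", "SigI", "X", "Y", "Wavelength")

#' Construct a reflection table
#'
#' An unmerged reflection table holds one row per reflection observation:
#' dataset id (0-based time-point index), image id, Miller index as indexed,
#' intensity and its uncertainty from integration, detector position, and, in
#' polychromatic mode, the assigned peak wavelength. An optional logical
#' `is_test` column freezes a cross-validation split.
#'
#' @param df Data frame with columns `dataset`, `image`, `h`, `k`, `l`, `I`,
#'   `SigI`, and optionally `X`, `Y`, `Wavelength`, `is_test`.
#' @param metadata_keys Character vector naming the per-observation metadata
#'   columns available to the scale model; defaults to whichever of
#'   `X`, `Y`, `Wavelength` are present.
#' @return A data frame of class `"refl_table"` with a `metadata_keys`
#'   attribute.
#' @export
refl_table <- function(df, metadata_keys = NULL) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.refl_required, names(df))
  if (length(missing_cols) > 0L) {
    stop("reflection table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(df$SigI > 0))
  if (length(bad) > 0L) {
    stop("non-positive SigI at row ", bad[1L], call. = FALSE)
  }
  if ("Wavelength" %in% names(df)) {
    bad <- which(!(df$Wavelength > 0))
    if (length(bad) > 0L) {
      stop("non-positive Wavelength at row ", bad[1L], call. = FALSE)
    }
  }
  bad <- which(df$h == 0L & df$k == 0L & df$l == 0L)
  if (length(bad) > 0L) {
    stop("miller index (0,0,0) at row ", bad[1L], call. = FALSE)
  }
  ds <- sort(unique(as.integer(df$dataset)))
  if (!identical(ds, seq(0L, length.out = length(ds)))) {
    stop("dataset ids must form a contiguous 0-based range", call. = FALSE)
  }
  for (v in c("dataset", "image", "h", "k", "l")) {
    df[[v]] <- as.integer(df[[v]])
  }
  if (is.null(metadata_keys)) {
    metadata_keys <- intersect(c("X", "Y", "Wavelength"), names(df))
  }
  rownames(df) <- NULL
  structure(df, metadata_keys = metadata_keys,
            class = c("refl_table", "data.frame"))
}

#' @export
print.refl_table <- function(x, ...) {
  cat(sprintf("Reflection table: %d observations, %d dataset(s), %d image(s)\n",
              nrow(x), length(unique(x$dataset)),
              length(unique(paste(x$dataset, x$image)))))
  cat("metadata keys:", paste(attr(x, "metadata_keys"), collapse = ", "), "\n")
  NextMethod()
}

.fmt_real <- function(x) {
  # 9 significant digits: below the noise floor of every computation here
  formatC(x, digits = 9, format = "g")
}

#' Read a reflection table
#'
#' @param path Input file.
#' @param dialect `"text"` (tab-separated, one header line, UTF-8) or
#'   `"mtz"` (binary MTZ).
#' @param dataset_id Dataset id to assign when the file carries none
#'   (single-time-point MTZ files).
#' @param columns For the MTZ dialect, a named character vector mapping the
#'   internal names `h`, `k`, `l`, `I`, `SigI`, `X`, `Y`, `Wavelength`,
#'   `image`, `dataset`, `is_test` to MTZ column labels. The default matches
#'   the usual converted Laue-integration output (`H`, `K`, `L`, `I`,
#'   `SigI`, `X`, `Y`, `Wavelength`, `BATCH`).
#' @return A [refl_table()].
#' @export
read_table <- function(path, dialect = c("text", "mtz"), dataset_id = 0L,
                       columns = mtz_default_columns()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "text") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    if ("is_test" %in% names(df)) df$is_test <- as.logical(df$is_test)
    refl_table(df)
  } else {
    raw <- .mtz_read(path)
    lab <- colnames(raw)
    pick <- function(internal, required = FALSE) {
      cl <- columns[[internal]]
      if (!is.null(cl) && cl %in% lab) return(raw[, cl])
      if (required) {
        stop("MTZ file lacks mandatory column '", cl, "' (", internal, ")")
      }
      NULL
    }
    df <- data.frame(
      h = as.integer(round(pick("h", TRUE))),
      k = as.integer(round(pick("k", TRUE))),
      l = as.integer(round(pick("l", TRUE))),
      I = pick("I", TRUE),
      SigI = pick("SigI", TRUE)
    )
    img <- pick("image")
    df$image <- if (is.null(img)) 0L else as.integer(round(img))
    dsc <- pick("dataset")
    df$dataset <- if (is.null(dsc)) as.integer(dataset_id)
                  else as.integer(round(dsc))
    for (v in c("X", "Y", "Wavelength")) {
      val <- pick(v)
      if (!is.null(val)) df[[v]] <- val
    }
    tst <- pick("is_test")
    if (!is.null(tst)) df$is_test <- as.logical(round(tst))
    refl_table(df)
  }
}

#' Write a reflection table
#'
#' @param table A [refl_table()].
#' @param path Output file.
#' @param dialect `"text"` or `"mtz"`.
#' @inheritParams read_table
#' @return The path, invisibly.
#' @export
write_table <- function(table, path, dialect = c("text", "mtz"),
                        columns = mtz_default_columns()) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(table)
  if (dialect == "text") {
    out <- df
    for (v in intersect(.refl_reals, names(out))) {
      out[[v]] <- .fmt_real(out[[v]])
    }
    if ("is_test" %in% names(out)) {
      out$is_test <- ifelse(out$is_test, "TRUE", "FALSE")
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  } else {
    cols <- list()
    types <- character(0)
    add <- function(internal, values, type) {
      lbl <- columns[[internal]]
      cols[[lbl]] <<- as.numeric(values)
      types[lbl] <<- type
    }
    add("h", df$h, "H"); add("k", df$k, "H"); add("l", df$l, "H")
    add("I", df$I, "J"); add("SigI", df$SigI, "Q")
    add("image", df$image, "B")
    for (v in c("X", "Y", "Wavelength")) {
      if (v %in% names(df)) add(v, df[[v]], "R")
    }
    if (length(unique(df$dataset)) > 1L || any(df$dataset != 0L)) {
      add("dataset", df$dataset, "R")
    }
    if ("is_test" %in% names(df)) add("is_test", as.numeric(df$is_test), "I")
    .mtz_write(path, do.call(cbind, cols), types)
  }
  invisible(path)
}

#' Default MTZ column mapping
#'
#' The column vocabulary used when reading and writing MTZ files; override
#' entries to adapt to other conventions.
#' @return Named list mapping internal field names to MTZ column labels.
#' @export
mtz_default_columns <- function() {
  list(h = "H", k = "K", l = "L", I = "I", SigI = "SigI",
       X = "X", Y = "Y", Wavelength = "Wavelength",
       image = "BATCH", dataset = "DATASET", is_test = "TEST")
}

# ---- minimal MTZ binary I/O -------------------------------------------------
# MTZ v1.1 layout: 4-byte magic "MTZ ", int32 header location (in 4-byte
# words, 1-based), machine stamp, zero padding to word 21, float32 reflection
# records (row-major), then 80-character header records.

.mtz_pad80 <- function(s) formatC(s, width = -80)

.mtz_write <- function(path, data, types, cell = c(1, 1, 1, 90, 90, 90),
                       spacegroup = "P1") {
  ncolw <- ncol(data); nref <- nrow(data)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar("MTZ ", con, 4L, eos = NULL)
  writeBin(as.integer(21L + ncolw * nref), con, size = 4L, endian = "little")
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con) # little-endian stamp
  writeBin(integer(17L), con, size = 4L, endian = "little") # pad to word 21
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  rng <- apply(data, 2L, range)
  hdr <- c(
    "VERS MTZ:V1.1",
    "TITLE reflection data",
    sprintf("NCOL %8d %12d %8d", ncolw, nref, 0L),
    sprintf("CELL  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
            cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]),
    "SORT    0   0   0   0   0",
    sprintf("SYMINF %3d %2d %s %5d %22s %5s", 1L, 1L, "P", 1L,
            paste0("'", spacegroup, "'"), "'1'"),
    "SYMM X,  Y,  Z",
    "RESO 0.0000000 1.0000000",
    "VALM NAN",
    vapply(seq_len(ncolw), function(j) {
      sprintf("COLUMN %-30s %s %17.9g %17.9g    1",
              colnames(data)[j], types[colnames(data)[j]],
              rng[1L, j], rng[2L, j])
    }, character(1L)),
    "NDIF        1",
    "PROJECT       1 project",
    "CRYSTAL       1 crystal",
    "DATASET       1 dataset",
    sprintf("DCELL         1  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
            cell[1], cell[2], cell[3], cell[4], cell[5], cell[6]),
    "DWAVEL        1    0.00000",
    "END",
    "MTZENDOFHEADERS"
  )
  for (line in hdr) writeChar(.mtz_pad80(line), con, 80L, eos = NULL)
  invisible(path)
}

.mtz_read <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "MTZ ")) stop("not an MTZ file: ", path)
  hdr_loc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 80L)
  ndata <- hdr_loc - 21L
  data <- readBin(con, "numeric", ndata, size = 4L, endian = "little")
  seek(con, (hdr_loc - 1L) * 4L)
  nrec <- floor((sz - (hdr_loc - 1L) * 4L) / 80L)
  labels <- character(0); ncolw <- NA_integer_; nref <- NA_integer_
  for (i in seq_len(nrec)) {
    line <- readChar(con, 80L, useBytes = TRUE)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "NCOL") {
      ncolw <- as.integer(tok[2L]); nref <- as.integer(tok[3L])
    } else if (tok[1L] == "COLUMN") {
      labels <- c(labels, tok[2L])
    } else if (tok[1L] == "END") break
  }
  if (is.na(ncolw) || length(labels) != ncolw) {
    stop("malformed MTZ header in ", path)
  }
  m <- matrix(data[seq_len(ncolw * nref)], nrow = nref, ncol = ncolw,
              byrow = TRUE)
  colnames(m) <- labels
  m
}

# ---- merged structure factors -----------------------------------------------

#' Construct a merged structure-factor table
#'
#' Posterior mean and standard deviation of structure-factor amplitudes per
#' (dataset, ASU Miller index), the estimand of the variational merge.
#'
#' @param df Data frame with columns `dataset`, `h`, `k`, `l`, `F`, `SigF`.
#' @return Data frame of class `"merged_sf"`, ordered by dataset then (h,k,l)
#'   lexicographically descending (the ASU convention order).
#' @export
merged_sf <- function(df) {
  df <- as.data.frame(df)
  need <- c("dataset", "h", "k", "l", "F", "SigF")
  if (!all(need %in% names(df))) {
    stop("merged table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$F < 0)) stop("posterior mean amplitudes must be non-negative")
  if (any(df$SigF <= 0)) stop("posterior std of amplitudes must be positive")
  key <- .miller_key(df$h, df$k, df$l, df$dataset)
  if (anyDuplicated(key)) {
    stop("duplicate (dataset, h, k, l) entry in merged table")
  }
  df <- df[order(df$dataset, -df$h, -df$k, -df$l), ]
  rownames(df) <- NULL
  structure(df, class = c("merged_sf", "data.frame"))
}

#' Write merged structure factors
#'
#' One record per (dataset, ASU index), deterministically ordered by dataset
#' and then Miller index; tab-separated text.
#' @param m A [merged_sf()] table.
#' @param path Output file path.
#' @export
write_merged <- function(m, path) {
  stopifnot(inherits(m, "merged_sf"), nrow(m) > 0L)
  out <- as.data.frame(m)
  out$F <- .fmt_real(out$F)
  out$SigF <- .fmt_real(out$SigF)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con,
             sep = "\n")
  invisible(path)
}

#' Read merged structure factors
#' @param path File written by [write_merged()].
#' @return A [merged_sf()] table.
#' @export
read_merged <- function(path) {
  merged_sf(utils::read.delim(path, sep = "\t", header = TRUE))
}
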