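# Loading, validation and preprocessing of paired scRNA/scATAC matrices.

#' Construct a paired multimodal dataset
#'
#' Bundles an scRNA matrix and an scATAC matrix measured in the same cells
#' (rows in the same order), with optional ground-truth labels used only for
#' evaluation.
#'
#' @param x_rna numeric matrix, cells x RNA features.
#' @param x_atac numeric matrix, cells x ATAC features.
#' @param labels optional integer vector of ground-truth cluster ids
#'   (0-based); factors/characters are encoded to 0..k-1.
#' @param cell_ids optional character vector of cell identifiers.
#' @param n_clusters optional number of clusters k; inferred from `labels`
#'   when present.
#' @return An object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(x_rna, x_atac, labels = NULL, cell_ids = NULL,
                               n_clusters = NULL) {
  x_rna <- as.matrix(x_rna); storage.mode(x_rna) <- "double"
  x_atac <- as.matrix(x_atac); storage.mode(x_atac) <- "double"
  if (nrow(x_rna) != nrow(x_atac)) {
    stop(sprintf(
      "modalities disagree on cell count: scRNA is %d x %d but scATAC is %d x %d",
      nrow(x_rna), ncol(x_rna), nrow(x_atac), ncol(x_atac)), call. = FALSE)
  }
  if (anyNA(x_rna) || anyNA(x_atac) ||
      any(!is.finite(x_rna)) || any(!is.finite(x_atac))) {
    stop("input matrices contain NA/NaN/Inf entries", call. = FALSE)
  }
  n <- nrow(x_rna)
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(rownames(x_rna))) rownames(x_rna)
                else sprintf("cell_%d", seq_len(n))
  }
  if (length(cell_ids) != n) stop("cell_ids length does not match cell count",
                                  call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop(sprintf("labels length %d does not match %d cells",
                   length(labels), n), call. = FALSE)
    }
    if (is.character(labels) || is.factor(labels)) {
      labels <- as.integer(factor(labels)) - 1L
    } else {
      if (any(labels != round(labels)) || any(labels < 0)) {
        stop("labels must be non-negative integers", call. = FALSE)
      }
      labels <- as.integer(labels)
    }
    if (is.null(n_clusters)) n_clusters <- length(unique(labels))
  }
  structure(list(
    x_rna = x_rna, x_atac = x_atac, labels = labels,
    cell_ids = as.character(cell_ids),
    n_clusters = if (is.null(n_clusters)) NA_integer_ else as.integer(n_clusters),
    preprocessed = FALSE
  ), class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("multimodal_dataset: %d cells; scRNA %d features, scATAC %d features\n",
              nrow(x$x_rna), ncol(x$x_rna), ncol(x$x_atac)))
  cat(sprintf("  labels: %s; n_clusters: %s; preprocessed: %s\n",
              if (is.null(x$labels)) "absent" else "present",
              ifelse(is.na(x$n_clusters), "unknown", x$n_clusters),
              x$preprocessed))
  invisible(x)
}

#' @export
dim.multimodal_dataset <- function(x) {
  c(nrow(x$x_rna), ncol(x$x_rna), ncol(x$x_atac))
}

# Orient a matrix as cells x features using sidecar counts. MTX files in the
# 10x convention come features x cells; transpose when that matches.
orient_matrix <- function(m, n_barcodes, n_features, what) {
  if (nrow(m) == n_barcodes && ncol(m) == n_features) return(m)
  if (nrow(m) == n_features && ncol(m) == n_barcodes) {
    message(sprintf("%s: matrix is features x cells; transposing", what))
    return(t(m))
  }
  stop(sprintf(
    "%s: matrix is %d x %d but sidecars list %d barcodes and %d features",
    what, nrow(m), ncol(m), n_barcodes, n_features), call. = FALSE)
}

read_mtx_modality <- function(dir, what) {
  mtx <- file.path(dir, "matrix.mtx")
  bcf <- file.path(dir, "barcodes.tsv")
  ftf <- file.path(dir, "features.tsv")
  for (f in c(mtx, bcf, ftf)) {
    if (!file.exists(f)) stop(sprintf("%s: missing %s", what, f), call. = FALSE)
  }
  m <- tryCatch(as.matrix(Matrix::readMM(mtx)), error = function(e) {
    stop(sprintf("%s: cannot parse %s as MatrixMarket: %s", what, mtx,
                 conditionMessage(e)), call. = FALSE)
  })
  barcodes <- readLines(bcf)
  features <- readLines(ftf)
  m <- orient_matrix(m, length(barcodes), length(features), what)
  rownames(m) <- barcodes
  colnames(m) <- features
  m
}

read_csv_modality <- function(path, what) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) {
    stop(sprintf("%s: cannot parse %s as CSV: %s", what, path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (ncol(df) < 2L) stop(sprintf("%s: CSV %s needs a cell-id column plus features",
                                  what, path), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop(sprintf("%s: non-numeric entries in %s", what, path), call. = FALSE)
  }
  rownames(m) <- as.character(df[[1L]])
  m
}

read_h5ad_modality <- function(path, what) {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop(sprintf("%s: reading H5AD requires a `python` with anndata on PATH",
                 what), call. = FALSE)
  }
  out <- tempfile("h5ad2mtx_")
  dir.create(out)
  script <- c(
    "import sys",
    "import anndata, scipy.sparse as sp, scipy.io as sio",
    "ad = anndata.read_h5ad(sys.argv[1])",
    "x = ad.X",
    "x = sp.coo_matrix(x)",
    "sio.mmwrite(sys.argv[2] + '/matrix.mtx', x.T)",  # features x cells on disk
    "open(sys.argv[2] + '/barcodes.tsv', 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')",
    "open(sys.argv[2] + '/features.tsv', 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')"
  )
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  log <- suppressWarnings(system2(py, c(sf, shQuote(path), shQuote(out)),
                                  stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(log, "status"))) {
    stop(sprintf("%s: H5AD conversion of %s failed: %s", what, path,
                 paste(log, collapse = " ")), call. = FALSE)
  }
  read_mtx_modality(out, what)
}

read_labels_file <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    df[[ncol(df)]]
  } else {
    readLines(path)
  }
}

#' Load a paired scRNA/scATAC dataset from disk
#'
#' Supported formats: `"csv"` (first column = cell IDs, header = feature
#' names), `"mtx"` (a directory per modality holding `matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`; features x cells orientation is detected
#' and transposed), and `"h5ad"` (one file per modality; converted via the
#' system `python`/anndata).
#'
#' @param rna_path path to the scRNA file (or MTX directory).
#' @param atac_path path to the scATAC file (or MTX directory).
#' @param labels_path optional path to a one-label-per-cell text/CSV file.
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`.
#' @return A [multimodal_dataset()].
#' @export
load_dataset <- function(rna_path, atac_path, labels_path = NULL,
                         format = c("csv", "mtx", "h5ad")) {
  format <- match.arg(format)
  for (p in c(rna_path, atac_path, labels_path)) {
    if (!file.exists(p)) stop(sprintf("path does not exist: %s", p),
                              call. = FALSE)
  }
  reader <- switch(format,
    csv = read_csv_modality,
    mtx = read_mtx_modality,
    h5ad = read_h5ad_modality)
  x_rna <- reader(rna_path, "scRNA")
  x_atac <- reader(atac_path, "scATAC")
  labels <- if (!is.null(labels_path)) read_labels_file(labels_path)
  multimodal_dataset(x_rna, x_atac, labels = labels,
                     cell_ids = rownames(x_rna))
}

# Dispersion used to rank features: variance of the log1p of library-size
# normalized values. Ties broken by ascending column index.
feature_dispersion <- function(x) {
  lib <- pmax(rowSums(x), 1)
  target <- stats::median(lib)
  ln <- log1p(x / lib * target)
  apply(ln, 2L, stats::var)
}

select_top_features <- function(x, n_top) {
  if (ncol(x) <= n_top) return(seq_len(ncol(x)))
  disp <- feature_dispersion(x)
  order(-disp, seq_along(disp))[seq_len(n_top)]
}

normalize_log1p <- function(x, what) {
  lib <- rowSums(x)
  if (any(lib <= 0)) {
    warning(sprintf("%s: %d cell(s) with zero total counts; library size floored at 1",
                    what, sum(lib <= 0)), call. = FALSE)
  }
  lib <- pmax(lib, 1)
  target <- stats::median(lib)
  log1p(x / lib * target)
}

#' Preprocess a paired dataset (feature selection + normalization)
#'
#' Per modality: keep the `n_top_features` highest-dispersion features
#' (dispersion = variance of the log1p library-size-normalized values; ties
#' broken by column index; all features kept when there are fewer), then, if
#' `normalize`, library-size normalize each cell to the median library size
#' and apply `log1p`. Calling `preprocess` on an already preprocessed dataset
#' is a no-op, so the operation is idempotent.
#'
#' @param ds a [multimodal_dataset()].
#' @param n_top_features features to retain per modality (default 2000).
#' @param normalize apply library-size normalization + log1p (default TRUE).
#' @param binarize_atac binarize the accessibility matrix (> 0) before
#'   preprocessing (default FALSE; both modalities are treated symmetrically).
#' @return The preprocessed [multimodal_dataset()].
#' @export
preprocess <- function(ds, n_top_features = 2000, normalize = TRUE,
                       binarize_atac = FALSE) {
  stopifnot(inherits(ds, "multimodal_dataset"))
  if (isTRUE(ds$preprocessed)) return(ds)
  if (any(ds$x_rna < 0) || any(ds$x_atac < 0)) {
    stop("preprocess expects non-negative raw count matrices", call. = FALSE)
  }
  if (binarize_atac) ds$x_atac <- (ds$x_atac > 0) * 1
  for (mod in c("x_rna", "x_atac")) {
    x <- ds[[mod]]
    keep <- select_top_features(x, n_top_features)
    x <- x[, keep, drop = FALSE]
    if (normalize) x <- normalize_log1p(x, mod)
    ds[[mod]] <- x
  }
  ds$preprocessed <- TRUE
  ds
}

#' Write a dataset to disk in the formats [load_dataset()] reads
#'
#' @param ds a [multimodal_dataset()].
#' @param dir output directory (created if needed); modalities go to
#'   `rna`/`atac` subdirectories (MTX) or `rna.csv`/`atac.csv` (CSV), labels
#'   to `labels.txt` when present.
#' @param format `"csv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "multimodal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mod <- function(x, name) {
    if (format == "csv") {
      df <- data.frame(cell_id = ds$cell_ids, x, check.names = FALSE)
      colnames(df) <- c("cell_id",
                        if (!is.null(colnames(x))) colnames(x)
                        else sprintf("%s_f%d", name, seq_len(ncol(x))))
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    } else {
      sub <- file.path(dir, name)
      dir.create(sub, showWarnings = FALSE)
      Matrix::writeMM(methods::as(Matrix::Matrix(t(x), sparse = TRUE), "generalMatrix"),
                      file.path(sub, "matrix.mtx"))
      writeLines(ds$cell_ids, file.path(sub, "barcodes.tsv"))
      ftn <- if (!is.null(colnames(x))) colnames(x)
             else sprintf("%s_f%d", name, seq_len(ncol(x)))
      writeLines(ftn, file.path(sub, "features.tsv"))
    }
  }
  write_mod(ds$x_rna, "rna")
  write_mod(ds$x_atac, "atac")
  if (!is.null(ds$labels)) {
    writeLines(as.character(ds$labels), file.path(dir, "labels.txt"))
  }
  invisible(dir)
}
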