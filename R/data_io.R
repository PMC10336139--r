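# Reading count matrices and covariates, the encoder input transform,
# stratified splitting, and the chunked on-disk minibatch cache.

#' Construct a count-matrix container
#'
#' @param counts cells-by-features matrix (coerced to sparse); entries must be
#'   nonnegative. ATAC matrices are binarized (any positive entry becomes 1).
#' @param feature_ids,cell_ids optional label vectors matching the dimensions.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param feature_coords optional data frame of peak coordinates
#'   (`chrom`, `start`, `end`; 0-based half-open).
#' @param drop_empty drop cells with zero total counts (default TRUE, with a
#'   message).
#' @return an object of class `codal_counts`.
#' @export
codal_counts <- function(counts, feature_ids = NULL, cell_ids = NULL,
                         modality = c("RNA", "ATAC"), feature_coords = NULL,
                         drop_empty = TRUE) {
  modality <- match.arg(modality)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("negative entries in count matrix", call. = FALSE)
  feature_ids <- feature_ids %||% colnames(counts) %||% paste0("f", seq_len(ncol(counts)))
  cell_ids <- cell_ids %||% rownames(counts) %||% paste0("cell", seq_len(nrow(counts)))
  if (length(feature_ids) != ncol(counts) || length(cell_ids) != nrow(counts)) {
    stop("dimension mismatch between matrix and labels", call. = FALSE)
  }
  if (modality == "ATAC") counts@x <- pmin(counts@x, 1)
  tot <- Matrix::rowSums(counts)
  if (drop_empty && any(tot == 0)) {
    message(sum(tot == 0), " cell(s) with zero total counts dropped")
    keep <- tot > 0
    counts <- counts[keep, , drop = FALSE]
    cell_ids <- cell_ids[keep]
  }
  dimnames(counts) <- list(cell_ids, feature_ids)
  structure(list(counts = counts, feature_ids = feature_ids,
                 cell_ids = cell_ids, modality = modality,
                 feature_coords = feature_coords),
            class = "codal_counts")
}

#' @export
print.codal_counts <- function(x, ...) {
  cat(sprintf("<codal_counts> %s: %d cells x %d features, %.0f total counts\n",
              x$modality, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.codal_counts <- function(x) dim(x$counts)

#' Load a count matrix from disk
#'
#' Supported formats: `"mtx"` — a directory with `matrix.mtx`,
#' `barcodes.tsv` and `features.tsv` in the 10x dialect (features-by-cells on
#' disk, transposed on load); `"tsv"` — a dense cells-by-features table with
#' header and row names; `"h5"` — an HDF5 single-cell container (requires the
#' `hdf5r` package).
#'
#' @param path file or directory path.
#' @param format one of `"mtx"`, `"tsv"`, `"h5"`.
#' @inheritParams codal_counts
#' @return a `codal_counts`.
#' @export
load_counts <- function(path, format = c("mtx", "tsv", "h5"),
                        modality = c("RNA", "ATAC")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "mtx") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    feats <- read.delim(file.path(path, "features.tsv"), header = FALSE)[[1]]
    if (nrow(m) != length(feats) || ncol(m) != length(barcodes)) {
      stop("dimension mismatch between matrix and label files", call. = FALSE)
    }
    codal_counts(Matrix::t(m), feature_ids = as.character(feats),
                 cell_ids = barcodes, modality = modality)
  } else if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE)
    codal_counts(as.matrix(df), feature_ids = colnames(df),
                 cell_ids = rownames(df), modality = modality)
  } else {
    if (!requireNamespace("hdf5r", quietly = TRUE)) {
      stop("reading HDF5 containers requires the 'hdf5r' package", call. = FALSE)
    }
    h5 <- hdf5r::H5File$new(path, mode = "r")
    on.exit(h5$close_all())
    codal_counts(t(h5[["X"]]$read()),
                 feature_ids = h5[["var_names"]]$read(),
                 cell_ids = h5[["obs_names"]]$read(), modality = modality)
  }
}

#' Write a count matrix as a MatrixMarket triplet directory
#'
#' Inverse of [load_counts()] for the `"mtx"` format (10x dialect:
#' features-by-cells on disk).
#'
#' @param x a `codal_counts`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(path, "matrix.mtx"))
  writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  writeLines(x$feature_ids, file.path(path, "features.tsv"))
  invisible(path)
}

# ---- covariates -------------------------------------------------------------

#' Encode a covariate table into a model design
#'
#' Categorical covariates become one-hot groups (each row-group sums to 1);
#' continuous covariates are standardized to mean 0, sd 1 over the design
#' population. When `schema` from a previous design is supplied, the same
#' levels, centers and scales are reused; unseen categories raise an error.
#'
#' @param table data frame of per-cell covariates.
#' @param categorical,continuous character vectors of column names.
#' @param batch_key name of the categorical covariate marking batch identity
#'   (defaults to the first categorical column).
#' @param schema a schema from a previous `codal_design`, to re-apply.
#' @return an object of class `codal_design` with fields `matrix` and
#'   `schema`.
#' @export
encode_covariates <- function(table, categorical = character(),
                              continuous = character(), batch_key = NULL,
                              schema = NULL) {
  table <- as.data.frame(table)
  if (!is.null(schema)) {
    categorical <- names(schema$columns)[vapply(schema$columns, function(s) s$kind == "categorical", logical(1))]
    continuous <- names(schema$columns)[vapply(schema$columns, function(s) s$kind == "continuous", logical(1))]
    batch_key <- schema$batch_key
  }
  missing_cols <- setdiff(c(categorical, continuous), names(table))
  if (length(missing_cols)) stop("missing covariate column(s): ",
                                 paste(missing_cols, collapse = ", "), call. = FALSE)
  cols <- list(); blocks <- list()
  for (nm in categorical) {
    vals <- as.character(table[[nm]])
    if (!is.null(schema)) {
      levs <- schema$columns[[nm]]$levels
      bad <- setdiff(unique(vals), levs)
      if (length(bad)) stop("unseen category in '", nm, "': ",
                            paste(bad, collapse = ", "), call. = FALSE)
    } else levs <- sort(unique(vals))
    oh <- outer(vals, levs, `==`) * 1
    colnames(oh) <- paste0(nm, "=", levs)
    blocks[[nm]] <- oh
    cols[[nm]] <- list(kind = "categorical", levels = levs)
  }
  for (nm in continuous) {
    v <- as.numeric(table[[nm]])
    if (!is.null(schema)) {
      ctr <- schema$columns[[nm]]$center; scl <- schema$columns[[nm]]$scale
    } else {
      ctr <- mean(v); scl <- sd(v)
      if (!is.finite(scl) || scl == 0) scl <- 1
    }
    blocks[[nm]] <- matrix((v - ctr) / scl, ncol = 1,
                           dimnames = list(NULL, nm))
    cols[[nm]] <- list(kind = "continuous", center = ctr, scale = scl)
  }
  mat <- if (length(blocks)) do.call(cbind, blocks) else matrix(0, nrow(table), 0)
  structure(list(matrix = mat,
                 schema = list(columns = cols,
                               batch_key = batch_key %||%
                                 (if (length(categorical)) categorical[[1]] else NULL))),
            class = "codal_design")
}

#' @export
print.codal_design <- function(x, ...) {
  cat(sprintf("<codal_design> %d cells x %d columns (batch key: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$schema$batch_key %||% "none"))
  invisible(x)
}

design_batch_labels <- function(design) {
  key <- design$schema$batch_key
  if (is.null(key)) return(rep("all", nrow(design$matrix)))
  levs <- design$schema$columns[[key]]$levels
  block <- design$matrix[, paste0(key, "=", levs), drop = FALSE]
  levs[max.col(block)]
}

# joint level of all categorical covariates, used for stratification
design_strata <- function(design) {
  cats <- names(design$schema$columns)[
    vapply(design$schema$columns, function(s) s$kind == "categorical", logical(1))]
  if (!length(cats)) return(rep("all", nrow(design$matrix)))
  parts <- lapply(cats, function(nm) {
    levs <- design$schema$columns[[nm]]$levels
    block <- design$matrix[, paste0(nm, "=", levs), drop = FALSE]
    levs[max.col(block)]
  })
  do.call(paste, c(parts, sep = "|"))
}

# ---- deviance residuals -----------------------------------------------------

#' Deviance residuals of RNA counts
#'
#' Poisson deviance residuals under a constant-composition null: with
#' per-gene proportion `pi_j` (gene total over grand total) and expected count
#' `mu_ij = n_i * pi_j`, the residual is
#' `sign(x - mu) * sqrt(2 * (x * log(x / mu) - (x - mu)))` with
#' `0 * log(0) = 0`. Used as the variance-stabilized encoder input.
#'
#' @param X a `codal_counts` (RNA) or a cells-by-genes matrix.
#' @param pi_hat optional fixed gene-proportion vector (e.g. from the
#'   training population); computed from `X` when missing.
#' @return dense cells-by-genes residual matrix.
#' @export
deviance_residuals <- function(X, pi_hat = NULL) {
  if (inherits(X, "codal_counts")) {
    if (X$modality != "RNA") stop("deviance residuals are defined for RNA counts", call. = FALSE)
    X <- X$counts
  }
  deviance_residuals_matrix(X, pi_hat)
}

deviance_residuals_matrix <- function(X, pi_hat = NULL) {
  Xd <- as_dense(X)
  n_i <- rowSums(Xd)
  if (any(n_i == 0)) stop("all-zero cell; filter before computing residuals", call. = FALSE)
  if (is.null(pi_hat)) {
    pi_hat <- colSums(Xd) / sum(Xd)
    pi_hat <- pmax(pi_hat, 1e-12)
  }
  mu <- outer(n_i, pi_hat)
  dev <- 2 * (xlogy(Xd, Xd / mu) - (Xd - mu))
  sign(Xd - mu) * sqrt(pmax(dev, 0))
}

# ---- stratified split -------------------------------------------------------

#' Stratified train/test split
#'
#' Splits cells into train and test portions, stratified by the joint level
#' of all categorical covariates. Per stratum, `floor(ratio * n)` cells go to
#' train and the remainder to test; strata with fewer than 2 cells go to
#' train with a warning. Deterministic given `seed`.
#'
#' @param X a `codal_counts`.
#' @param design a `codal_design` with rows matching `X`.
#' @param ratio train fraction in (0, 1); default 0.8 (a 4:1 split).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(X, design, ratio = 0.8, seed = 0L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- nrow(X$counts)
  stopifnot(nrow(design$matrix) == n)
  strata <- design_strata(design)
  set.seed(derive_seed(seed, "split"))
  train <- integer(0); test <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2) {
      warning("stratum '", s, "' has fewer than 2 cells; placed in train", call. = FALSE)
      train <- c(train, idx)
      next
    }
    idx <- sample(idx)
    ntr <- floor(ratio * length(idx))
    train <- c(train, idx[seq_len(ntr)])
    test <- c(test, idx[-seq_len(ntr)])
  }
  list(train = sort(train), test = sort(test))
}

subset_counts <- function(X, idx) {
  codal_counts(X$counts[idx, , drop = FALSE], feature_ids = X$feature_ids,
               cell_ids = X$cell_ids[idx], modality = X$modality,
               feature_coords = X$feature_coords, drop_empty = FALSE)
}

subset_design <- function(design, idx) {
  design$matrix <- design$matrix[idx, , drop = FALSE]
  design
}

# ---- minibatch cache --------------------------------------------------------

#' Write a chunked on-disk minibatch cache
#'
#' Shuffles cells (deterministically by `order_seed`), splits them into
#' chunks of `chunk_size`, and writes each chunk as a MatrixMarket block plus
#' a covariate TSV, with a JSON manifest carrying md5 checksums. Peak memory
#' of streaming is bounded by the chunk size.
#'
#' @param X a `codal_counts`; `design` a matching `codal_design`.
#' @param design covariate design.
#' @param chunk_size cells per chunk (default 128).
#' @param dir cache directory (created).
#' @param order_seed shuffle seed.
#' @return an object of class `codal_stream`.
#' @export
write_cache <- function(X, design, chunk_size = 128, dir = tempfile("codal_cache_"),
                        order_seed = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(X$counts)
  set.seed(derive_seed(order_seed, "cache"))
  perm <- sample(n)
  starts <- seq(1, n, by = chunk_size)
  chunks <- list()
  for (ci in seq_along(starts)) {
    idx <- perm[starts[ci]:min(starts[ci] + chunk_size - 1, n)]
    mfile <- file.path(dir, sprintf("chunk%04d.mtx", ci))
    cfile <- file.path(dir, sprintf("chunk%04d.tsv", ci))
    Matrix::writeMM(X$counts[idx, , drop = FALSE], mfile)
    write.table(design$matrix[idx, , drop = FALSE], cfile, sep = "\t",
                row.names = FALSE, col.names = TRUE, quote = FALSE)
    chunks[[ci]] <- list(
      matrix = basename(mfile), covariates = basename(cfile),
      n_cells = length(idx), cells = X$cell_ids[idx],
      md5_matrix = unname(tools::md5sum(mfile)),
      md5_covariates = unname(tools::md5sum(cfile))
    )
  }
  manifest <- list(n_cells = n, n_features = ncol(X$counts),
                   modality = X$modality, chunk_size = chunk_size,
                   order_seed = order_seed, chunks = chunks)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(dir = dir, manifest = manifest), class = "codal_stream")
}

#' Stream minibatch chunks from a cache
#'
#' Returns an iterator closure; each call yields `list(X, C, cells)` for the
#' next chunk (in chunk order permuted by `epoch_seed`) or `NULL` when the
#' epoch is exhausted. Chunks are checksum-verified on read.
#'
#' @param stream a `codal_stream` from [write_cache()].
#' @param epoch_seed permutation seed for this pass.
#' @return a function yielding chunks.
#' @export
stream_minibatches <- function(stream, epoch_seed = 0L) {
  n_chunks <- length(stream$manifest$chunks)
  set.seed(derive_seed(epoch_seed, "stream"))
  order_ <- sample(n_chunks)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > n_chunks) return(NULL)
    ch <- stream$manifest$chunks[[order_[i]]]
    mfile <- file.path(stream$dir, ch$matrix)
    cfile <- file.path(stream$dir, ch$covariates)
    if (!identical(unname(tools::md5sum(mfile)), ch$md5_matrix) ||
        !identical(unname(tools::md5sum(cfile)), ch$md5_covariates)) {
      stop("corrupted cache chunk: ", ch$matrix, call. = FALSE)
    }
    list(X = methods::as(methods::as(Matrix::readMM(mfile), "generalMatrix"), "CsparseMatrix"),
         C = as.matrix(read.delim(cfile, check.names = FALSE)),
         cells = unlist(ch$cells))
  }
}
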