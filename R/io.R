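#' Read a clustered multi-sample dataset
#'
#' Supported formats:
#' * `csv` / `tsv`: one row per cell with columns `cell_id`, the sample
#'   column, the cluster column, and all remaining numeric columns treated
#'   as features.
#' * `mtx`: a directory containing `matrix.mtx` (cells x features,
#'   MatrixMarket triplets, 1-based indices as the format mandates),
#'   `cells.tsv` (columns `cell_id` + sample + cluster) and `features.tsv`
#'   (column `feature`). Sparse input is kept sparse.
#' * `h5ad`: an AnnData HDF5 file; `X` may be dense or CSR/CSC sparse,
#'   the sample and cluster columns are taken from `obs` (plain or
#'   categorical encoding), and `obsm/X_pca` is used as the embedding when
#'   present.
#'
#' Cells with missing sample or cluster labels are dropped with a message.
#' Sample ids and cluster names are sorted deterministically by the
#' [cell_dataset()] constructor.
#'
#' @param path file (csv/tsv/h5ad) or directory (mtx).
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`, `"h5ad"`;
#'   `"auto"` guesses from the file extension.
#' @param sample_col,cluster_col names of the sample / cluster columns.
#' @param cell_id_col name of the cell id column (csv/tsv only).
#' @return a [cell_dataset()].
#' @export
read_dataset <- function(path, format = "auto", sample_col = "sample",
                         cluster_col = "cluster", cell_id_col = "cell_id") {
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else switch(tolower(tools::file_ext(path)),
                csv = "csv", tsv = "tsv", txt = "tsv", h5ad = "h5ad",
                stop("cannot guess format from extension: ", path))
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
         csv = .read_cell_table(path, ",", sample_col, cluster_col, cell_id_col),
         tsv = .read_cell_table(path, "\t", sample_col, cluster_col, cell_id_col),
         mtx = .read_mtx_dir(path, sample_col, cluster_col, cell_id_col),
         h5ad = .read_h5ad(path, sample_col, cluster_col),
         stop("unknown format: ", format))
}

.read_cell_table <- function(path, sep, sample_col, cluster_col, cell_id_col) {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(sample_col, cluster_col))
    if (!col %in% names(tab))
      stop("column '", col, "' not found; available: ",
           paste(names(tab), collapse = ", "))
  keep <- !(is.na(tab[[sample_col]]) | is.na(tab[[cluster_col]]))
  if (any(!keep)) {
    message("dropping ", sum(!keep), " cell(s) with missing labels")
    tab <- tab[keep, , drop = FALSE]
  }
  meta_cols <- c(cell_id_col, sample_col, cluster_col)
  feat_cols <- setdiff(names(tab), meta_cols)
  feats <- as.matrix(tab[, feat_cols, drop = FALSE])
  storage.mode(feats) <- "double"
  if (cell_id_col %in% names(tab)) rownames(feats) <- tab[[cell_id_col]]
  cell_dataset(feats, tab[[sample_col]], tab[[cluster_col]])
}

.read_mtx_dir <- function(dir, sample_col, cluster_col, cell_id_col) {
  mtx <- file.path(dir, "matrix.mtx")
  cells <- file.path(dir, "cells.tsv")
  feats <- file.path(dir, "features.tsv")
  for (f in c(mtx, cells, feats))
    if (!file.exists(f)) stop("missing sidecar file: ", f)
  x <- Matrix::readMM(mtx)
  ctab <- utils::read.table(cells, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  ftab <- utils::read.table(feats, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  for (col in c(sample_col, cluster_col))
    if (!col %in% names(ctab))
      stop("column '", col, "' not found in cells.tsv; available: ",
           paste(names(ctab), collapse = ", "))
  if (nrow(ctab) != nrow(x)) stop("cells.tsv rows do not match matrix rows")
  if (nrow(ftab) != ncol(x)) stop("features.tsv rows do not match matrix columns")
  x <- methods::as(x, "CsparseMatrix")
  colnames(x) <- ftab[[1]]
  if (cell_id_col %in% names(ctab)) rownames(x) <- ctab[[cell_id_col]]
  keep <- !(is.na(ctab[[sample_col]]) | is.na(ctab[[cluster_col]]))
  if (any(!keep)) {
    message("dropping ", sum(!keep), " cell(s) with missing labels")
    x <- x[keep, , drop = FALSE]
    ctab <- ctab[keep, , drop = FALSE]
  }
  cell_dataset(x, ctab[[sample_col]], ctab[[cluster_col]])
}

.read_h5ad <- function(path, sample_col, cluster_col) {
  ls <- rhdf5::h5ls(path)
  X <- .h5ad_matrix(path, ls)
  smp <- .h5ad_obs_column(path, ls, sample_col)
  cl <- .h5ad_obs_column(path, ls, cluster_col)
  emb <- NULL
  if (any(ls$group == "/obsm" & ls$name == "X_pca"))
    emb <- t(rhdf5::h5read(path, "obsm/X_pca"))
  idx_attr <- rhdf5::h5readAttributes(path, "obs")[["_index"]]
  if (!is.null(idx_attr)) {
    ids <- as.character(rhdf5::h5read(path, paste0("obs/", idx_attr)))
    rownames(X) <- ids
  }
  var_ls <- ls[ls$group == "/var", , drop = FALSE]
  vidx <- rhdf5::h5readAttributes(path, "var")[["_index"]]
  if (!is.null(vidx) && vidx %in% var_ls$name)
    colnames(X) <- as.character(rhdf5::h5read(path, paste0("var/", vidx)))
  rhdf5::h5closeAll()
  keep <- !(is.na(smp) | is.na(cl))
  if (any(!keep)) {
    message("dropping ", sum(!keep), " cell(s) with missing labels")
    X <- X[keep, , drop = FALSE]
    if (!is.null(emb)) emb <- emb[keep, , drop = FALSE]
    smp <- smp[keep]; cl <- cl[keep]
  }
  cell_dataset(X, smp, cl, embedding = emb)
}

# AnnData stores X either dense (transposed by HDF5 column order) or as a
# CSR/CSC group with data/indices/indptr.
.h5ad_matrix <- function(path, ls) {
  x_rows <- ls[ls$group == "/X", , drop = FALSE]
  if (nrow(x_rows) == 0) {                      # dense dataset
    return(t(rhdf5::h5read(path, "X")))
  }
  at <- rhdf5::h5readAttributes(path, "X")
  enc <- at[["encoding-type"]]
  shape <- as.integer(at[["shape"]])
  data <- as.numeric(rhdf5::h5read(path, "X/data"))
  indices <- as.integer(rhdf5::h5read(path, "X/indices"))
  indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
  if (identical(enc, "csr_matrix")) {
    m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                              dims = c(shape[1], shape[2]), repr = "R")
  } else if (identical(enc, "csc_matrix")) {
    m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                              dims = c(shape[1], shape[2]), repr = "C")
  } else stop("unsupported X encoding in h5ad: ", enc)
  methods::as(m, "CsparseMatrix")
}

.h5ad_obs_column <- function(path, ls, col) {
  obs <- ls[ls$group == "/obs" | startsWith(ls$group, "/obs/"), , drop = FALSE]
  if (!col %in% obs$name[obs$group == "/obs"])
    stop("column '", col, "' not found in obs; available: ",
         paste(setdiff(obs$name[obs$group == "/obs"], "_index"),
               collapse = ", "))
  node <- paste0("obs/", col)
  is_group <- any(obs$group == "/obs" & obs$name == col &
                  obs$otype == "H5I_GROUP")
  if (is_group) {                                # categorical encoding
    codes <- as.integer(rhdf5::h5read(path, paste0(node, "/codes")))
    cats <- as.character(rhdf5::h5read(path, paste0(node, "/categories")))
    out <- ifelse(codes < 0, NA_character_, cats[codes + 1L])
    return(out)
  }
  val <- rhdf5::h5read(path, node)
  as.character(as.vector(val))
}

#' Write a dataset as a delimited cell table
#'
#' One row per cell: `cell_id`, `sample`, `cluster`, then the feature
#' columns. The round trip through [read_dataset()] preserves labels and
#' counts exactly.
#'
#' @param dataset a [cell_dataset()].
#' @param path output file; the separator follows the extension (`.csv`
#'   comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_dataset_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "cell_dataset"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  feats <- as.matrix(dataset$features)
  ids <- rownames(feats)
  if (is.null(ids)) ids <- sprintf("cell%07d", seq_len(nrow(feats)))
  tab <- data.frame(cell_id = ids,
                    sample = as.character(dataset$sample_of_cell),
                    cluster = as.character(dataset$cluster_of_cell),
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(feats, check.names = FALSE))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dataset as MatrixMarket triplets with sidecar tables
#'
#' Writes `matrix.mtx` (cells x features), `cells.tsv` and `features.tsv`
#' into `dir`, the layout [read_dataset()] expects for `format = "mtx"`.
#'
#' @param dataset a [cell_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_mtx <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- Matrix::Matrix(dataset$features, sparse = TRUE)
  x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(x, file.path(dir, "matrix.mtx"))
  ids <- rownames(dataset$features)
  if (is.null(ids)) ids <- sprintf("cell%07d", seq_len(nrow(x)))
  utils::write.table(
    data.frame(cell_id = ids,
               sample = as.character(dataset$sample_of_cell),
               cluster = as.character(dataset$cluster_of_cell)),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  feat <- colnames(dataset$features)
  if (is.null(feat)) feat <- paste0("feature", seq_len(ncol(x)))
  utils::write.table(data.frame(feature = feat),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write / read a sample distance matrix as TSV
#'
#' Full symmetric matrix with sample ids as header and first column;
#' values are written with full precision (`format(..., digits = 17)`), so
#' the round trip is exact to within 1e-12.
#'
#' @param distances a [sample_dist()].
#' @param path TSV file.
#' @return `path` invisibly (writer); a [sample_dist()] (reader).
#' @export
write_distance_matrix <- function(distances, path) {
  stopifnot(inherits(distances, "sample_dist"))
  v <- distances$values
  tab <- data.frame(sample = rownames(v),
                    format(v, digits = 17, trim = TRUE, scientific = TRUE),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- ids
  v <- (v + t(v)) / 2       # absorb last-digit asymmetry from text round trip
  diag(v) <- 0
  sample_dist(v, ids)
}

#' Write trajectory and clustering results as TSV
#'
#' `write_trajectory` writes `sample, dc1, dc2, progression_rank`;
#' `write_clustering` writes `sample, cluster`.
#'
#' @param result a `trajectory_result` or `sample_clustering`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "trajectory_result"))
  tab <- data.frame(sample = names(result$progression),
                    dc1 = result$coordinates[, 1],
                    dc2 = result$coordinates[, 2],
                    progression_rank = result$progression)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_clustering <- function(result, path) {
  stopifnot(inherits(result, "sample_clustering"))
  tab <- data.frame(sample = names(result$labels), cluster = result$labels)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the parameters, seed and package version of a run so the run can
#' be reproduced exactly.
#'
#' @param path output JSON file.
#' @param params named list of parameters (seeds, thresholds, inputs).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params) {
  manifest <- list(
    package = "sampleOT",
    version = as.character(utils::packageVersion("sampleOT")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
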