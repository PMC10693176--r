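#' Read a dense genes x samples matrix
#'
#' CSV/TSV with a header row of sample ids and the first column holding
#' gene ids; the separator is sniffed by [data.table::fread()].
#'
#' @param path file path.
#' @return Numeric matrix with dimnames.
#' @export
read_dense_matrix <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a dense matrix with row and column ids
#'
#' @param m matrix with dimnames.
#' @param path output path; separator chosen from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @export
write_dense_matrix <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  dt <- data.table::data.table(id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = sep, na = "")
  invisible(path)
}

#' Read a Matrix Market sparse matrix with sidecar id files
#'
#' CellRanger-style triplet: an `.mtx` coordinate file plus one id per
#' line in `features` (rows) and `barcodes` (columns).
#'
#' @param mtx,features,barcodes file paths.
#' @return A `dgCMatrix` with dimnames.
#' @export
read_mtx_triplet <- function(mtx, features, barcodes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- data.table::fread(features, header = FALSE)
  bc <- data.table::fread(barcodes, header = FALSE)
  if (nrow(feat) != nrow(m) || nrow(bc) != ncol(m))
    stop("sidecar id files do not match the matrix dimensions")
  dimnames(m) <- list(as.character(feat[[1]]), as.character(bc[[1]]))
  m
}

#' Read a drug viability CSV
#'
#' Rows = drugs, columns = cell lines, first column = drug ids, empty
#' cells = missing.
#'
#' @param path file path.
#' @param metric_tag `"AUC"` or `"IC50"`.
#' @return A [drug_viability].
#' @export
read_viability_csv <- function(path, metric_tag = "AUC") {
  drug_viability(read_dense_matrix(path), metric_tag = metric_tag)
}

#' Read single-cell counts from MTX triplet or dense CSV
#'
#' @param path `.mtx` path (with `features`/`barcodes` sidecars) or a
#'   dense CSV/TSV.
#' @param features,barcodes sidecar paths, required for MTX input.
#' @param ... passed to [cell_counts()].
#' @return A [cell_counts].
#' @export
read_sc_counts <- function(path, features = NULL, barcodes = NULL, ...) {
  m <- if (grepl("\\.mtx$", path)) {
    if (is.null(features) || is.null(barcodes))
      stop("MTX input needs features and barcodes files")
    read_mtx_triplet(path, features, barcodes)
  } else {
    read_dense_matrix(path)
  }
  cell_counts(m, ...)
}

#' Write relevant gene sets as long-format TSV
#'
#' Columns: `cell`, `rank`, `gene`.
#'
#' @param sets a `relevant_gene_sets`.
#' @param path output TSV.
#' @export
write_relevant_genes <- function(sets, path) {
  dt <- data.table::data.table(
    cell = rep(names(sets), lengths(sets)),
    rank = unlist(lapply(lengths(sets), seq_len), use.names = FALSE),
    gene = unlist(sets, use.names = FALSE))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
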