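#' Single-cell UMI counts container
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or any `Matrix` sparse class); rownames = genes, colnames =
#'   cell barcodes.
#' @param mito_flag logical per-gene vector marking mitochondrial genes;
#'   if `NULL`, genes matching `mito_pattern` are flagged.
#' @param mito_pattern regular expression applied to gene ids when
#'   `mito_flag` is missing.
#' @return An object of class `cell_counts`, holding a `dgCMatrix`.
#' @export
cell_counts <- function(counts, mito_flag = NULL, mito_pattern = "^MT-") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and cell identifiers as dimnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated cell ids")
  if (any(counts@x < 0)) stop("UMI counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("UMI counts must be integers")
  if (is.null(mito_flag))
    mito_flag <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  stopifnot(length(mito_flag) == nrow(counts))
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_ids = colnames(counts), mito_flag = mito_flag),
            class = "cell_counts")
}

#' @method print cell_counts
#' @export
print.cell_counts <- function(x, ...) {
  cat("cell_counts:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      sum(x$mito_flag), "mitochondrial gene(s)\n")
  invisible(x)
}

#' Quality-control filter on cells
#'
#' Keeps cells with at least `min_umi` total UMI and a mitochondrial UMI
#' fraction strictly below `max_mito_frac`.
#'
#' @param m a [cell_counts].
#' @param min_umi inclusive lower bound on total UMI per cell.
#' @param max_mito_frac exclusive upper bound on the mitochondrial
#'   fraction; set to 1 to disable (no mito annotation needed then).
#' @return The filtered [cell_counts]; errors if no cell survives.
#' @export
qc_filter_cells <- function(m, min_umi = 5000L, max_mito_frac = 0.10) {
  stopifnot(inherits(m, "cell_counts"))
  totals <- Matrix::colSums(m$counts)
  keep <- totals >= min_umi
  if (max_mito_frac < 1) {
    mito <- Matrix::colSums(m$counts[m$mito_flag, , drop = FALSE])
    keep <- keep & (mito / pmax(totals, 1)) < max_mito_frac
  }
  if (!any(keep))
    stop("no cell passed QC (min_umi = ", min_umi, ", max_mito_frac = ",
         max_mito_frac, "); median UMI = ", median(totals))
  cell_counts(m$counts[, keep, drop = FALSE], mito_flag = m$mito_flag)
}

#' Gene frequency - inverse cell frequency normalization
#'
#' TF-IDF-style relevance scoring of genes within cells:
#' `score(g, c) = GF(g, c) * ICF(g)` with `GF = count / cell total` and
#' `ICF = log(n_cells / n_cells_expressing(g))` (natural log, no
#' smoothing; `icf_smooth = 1` switches to
#' `log(1 + n_cells / n_expressing)`). Genes detected in every cell get
#' ICF 0 under the unsmoothed default and therefore never rank as
#' relevant; genes detected nowhere get ICF 0 by convention.
#'
#' @param m a [cell_counts]; every cell must have positive total.
#' @param icf_smooth 0 (canonical, default) or 1 (smoothed variant).
#' @return An object of class `gficf_matrix`: sparse genes x cells
#'   non-negative scores plus the normalization parameters.
#' @export
gficf_normalize <- function(m, icf_smooth = 0) {
  stopifnot(inherits(m, "cell_counts"), icf_smooth %in% c(0, 1))
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0))
    stop("empty cell(s): ", paste(m$cell_ids[totals == 0], collapse = ", "))
  n_cells <- ncol(m$counts)
  n_expr <- Matrix::rowSums(m$counts > 0)
  icf <- ifelse(n_expr == 0, 0, log(icf_smooth + n_cells / pmax(n_expr, 1)))
  gf <- m$counts %*% Matrix::Diagonal(x = 1 / totals)
  scores <- Matrix::Diagonal(x = icf) %*% gf
  scores <- methods::as(methods::as(scores, "CsparseMatrix"), "generalMatrix")
  dimnames(scores) <- dimnames(m$counts)
  structure(list(scores = Matrix::drop0(scores), gene_ids = m$gene_ids,
                 cell_ids = m$cell_ids,
                 provenance = list(icf_smooth = icf_smooth, log_base = "e")),
            class = "gficf_matrix")
}

#' @method print gficf_matrix
#' @export
print.gficf_matrix <- function(x, ...) {
  cat("gficf_matrix:", nrow(x$scores), "genes x", ncol(x$scores),
      "cells; icf_smooth =", x$provenance$icf_smooth, "\n")
  invisible(x)
}

#' Extract each cell's top relevant genes
#'
#' Per cell, the `N` genes with the highest strictly positive gf-icf
#' score, ties broken by lexicographic gene id. Cells with fewer than `N`
#' positive-score genes return all of them (no padding).
#'
#' @param g a `gficf_matrix`.
#' @param N maximum genes per cell (default 500).
#' @return A named list of character vectors (class
#'   `relevant_gene_sets`), one per cell, ordered by descending score;
#'   `N` is stored as an attribute.
#' @export
top_relevant_genes <- function(g, N = 500L) {
  stopifnot(inherits(g, "gficf_matrix"), N >= 1)
  trip <- Matrix::summary(g$scores)
  trip <- trip[trip$x > 0, , drop = FALSE]
  out <- rep(list(character(0)), length(g$cell_ids))
  names(out) <- g$cell_ids
  if (nrow(trip) > 0) {
    gene <- g$gene_ids[trip$i]
    ord <- order(trip$j, -trip$x, gene)
    by_cell <- split(gene[ord], factor(trip$j[ord], levels =
                                         seq_along(g$cell_ids)))
    out[] <- lapply(by_cell, head, n = N)
  }
  structure(out, N = as.integer(N), class = "relevant_gene_sets")
}

#' @method print relevant_gene_sets
#' @export
print.relevant_gene_sets <- function(x, ...) {
  sizes <- lengths(x)
  cat("relevant_gene_sets:", length(x), "cells; N =", attr(x, "N"),
      "; set sizes", min(sizes), "-", max(sizes), "\n")
  invisible(x)
}
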