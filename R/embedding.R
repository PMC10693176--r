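#' Fuzzy Jaccard Distance between cells
#'
#' Cell-cell dissimilarity over predicted drug-response sign profiles:
#' `FJD(x, y) = 1 - sum_j |sign(E_xj) + sign(E_yj)| / (2 m)`. Two cells
#' with identical nonzero predictions for every drug are at distance 0;
#' strictly opposite predictions give distance 1; zeros ("no evidence")
#' contribute half-weight disagreement.
#'
#' The formula is evaluated exactly as stated. One consequence worth
#' knowing: the self-distance is `1 - nnz(x)/m`, which is positive
#' whenever a cell has non-significant (zero) entries, so identity of
#' indiscernibles does not hold in the presence of zeros. On zero-free
#' matrices FJD reduces to the Hamming disagreement rate and is a true
#' metric. No normalized variant is silently substituted.
#'
#' @param E a [build_E_matrix()] result or any cells x drugs numeric
#'   matrix (only the signs of the entries are used).
#' @return Symmetric cells x cells matrix of class `fjd_matrix`, values
#'   in \[0, 1\].
#' @export
fuzzy_jaccard <- function(E) {
  E <- unclass(as.matrix(E))
  m <- ncol(E)
  stopifnot(m >= 1)
  S <- sign(E)
  A <- abs(S)
  nnz <- rowSums(A)
  # sum_j |s_x + s_y| = S S' + nnz_x + nnz_y - |S||S|'  (signs in {-1,0,1})
  D <- 1 - (S %*% t(S) - A %*% t(A) + outer(nnz, nnz, "+")) / (2 * m)
  D <- pmin(pmax(D, 0), 1)
  dimnames(D) <- list(rownames(E), rownames(E))
  structure(D, class = c("fjd_matrix", "matrix", "array"))
}

#' Two-dimensional drug-response embedding of cells
#'
#' Embeds cells in 2-D from the precomputed Fuzzy Jaccard Distance
#' matrix. The default backend is non-metric multidimensional scaling
#' ([vegan::monoMDS()]), a nonlinear method that accepts a precomputed
#' distance directly; `"cmdscale"` gives classical (metric) MDS. Both
#' are deterministic under a fixed seed. The diagonal of the distance
#' matrix is ignored, as for any dissimilarity-based embedding.
#'
#' @param D an `fjd_matrix` (or any symmetric distance matrix).
#' @param seed integer seed (RNG state is set locally and restored).
#' @param method `"nmds"` (default) or `"cmdscale"`.
#' @param ... passed to the backend ([vegan::monoMDS()] or
#'   [stats::cmdscale()]).
#' @return List of class `drug_embedding` with `coords` (n x 2, columns
#'   `dim1`, `dim2`), `seed`, `method`.
#' @export
run_drug_reduction <- function(D, seed = 42L,
                               method = c("nmds", "cmdscale"), ...) {
  method <- match.arg(method)
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 cells to embed")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- as.dist(D)
  coords <- if (method == "nmds") {
    fit <- vegan::monoMDS(d, k = 2, ...)
    fit$points
  } else {
    cmdscale(d, k = 2, ...)
  }
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- rownames(D)
  structure(list(coords = coords, seed = seed, method = method),
            class = "drug_embedding")
}

#' @method print drug_embedding
#' @export
print.drug_embedding <- function(x, ...) {
  cat("drug_embedding:", nrow(x$coords), "cells, method =", x$method,
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Write embedding coordinates as TSV
#'
#' @param x a `drug_embedding`.
#' @param path output TSV (columns `cell`, `x`, `y`).
#' @export
write_embedding <- function(x, path) {
  data.table::fwrite(data.table::data.table(
    cell = rownames(x$coords), x = x$coords[, 1], y = x$coords[, 2]),
    path, sep = "\t")
  invisible(path)
}
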