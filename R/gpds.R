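#' @useDynLib scdrugsea, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import Matrix
#' @importFrom stats cor cor.test median p.adjust pnorm quantile rbinom
#'   rlnorm rmultinom rnorm runif sd as.dist hclust cutree cmdscale
#' @importFrom stats setNames dist
#' @importFrom utils combn
"_PACKAGE"

#' Bulk expression container
#'
#' A genes x cell-lines matrix of log10(CPM + 1) values with ordered,
#' unique gene and line identifiers.
#'
#' @param values numeric matrix, genes in rows, cell lines in columns.
#' @param gene_ids,line_ids character vectors; default taken from dimnames.
#' @return An object of class `bulk_expression`.
#' @export
bulk_expression <- function(values, gene_ids = rownames(values),
                            line_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(line_ids))
    stop("gene and line identifiers are required")
  if (anyDuplicated(gene_ids)) stop("duplicated gene_ids")
  if (anyDuplicated(line_ids)) stop("duplicated line_ids")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(line_ids))
    stop("dimensions do not match identifier lists")
  if (any(values < 0)) stop("log10(CPM + 1) values must be non-negative")
  dimnames(values) <- list(gene_ids, line_ids)
  structure(list(values = values, gene_ids = gene_ids, line_ids = line_ids),
            class = "bulk_expression")
}

#' @method print bulk_expression
#' @export
print.bulk_expression <- function(x, ...) {
  cat("bulk_expression:", length(x$gene_ids), "genes x",
      length(x$line_ids), "cell lines\n")
  invisible(x)
}

#' Drug viability container
#'
#' A drugs x cell-lines potency table (dose-response AUC by default,
#' optionally IC50); missing entries are allowed and dropped pairwise.
#'
#' @param potency numeric matrix, drugs in rows, lines in columns; NA =
#'   not measured.
#' @param drug_ids,line_ids identifiers; default from dimnames.
#' @param metric_tag `"AUC"` or `"IC50"`.
#' @return An object of class `drug_viability`.
#' @export
drug_viability <- function(potency, drug_ids = rownames(potency),
                           line_ids = colnames(potency),
                           metric_tag = c("AUC", "IC50")) {
  metric_tag <- match.arg(metric_tag)
  potency <- as.matrix(potency)
  if (is.null(drug_ids) || is.null(line_ids))
    stop("drug and line identifiers are required")
  if (anyDuplicated(drug_ids)) stop("duplicated drug_ids")
  if (anyDuplicated(line_ids)) stop("duplicated line_ids")
  keep <- rowSums(!is.na(potency)) > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " drug(s) with no measured lines")
    potency <- potency[keep, , drop = FALSE]
    drug_ids <- drug_ids[keep]
  }
  dimnames(potency) <- list(drug_ids, line_ids)
  structure(list(potency = potency, drug_ids = drug_ids, line_ids = line_ids,
                 metric_tag = metric_tag),
            class = "drug_viability")
}

#' @method print drug_viability
#' @export
print.drug_viability <- function(x, ...) {
  cat("drug_viability:", length(x$drug_ids), "drugs x",
      length(x$line_ids), "lines (", x$metric_tag, ");",
      sum(is.na(x$potency)), "missing entries\n")
  invisible(x)
}

#' CPM-normalize raw bulk counts
#'
#' Scales each cell line (column) to counts-per-million and transforms to
#' log10(CPM + 1). Plain library-size scaling is used; pre-normalized
#' matrices may be supplied directly to [bulk_expression()].
#'
#' @param raw_counts non-negative integer matrix, genes x lines, with
#'   dimnames.
#' @return A [bulk_expression] object; gene/line order is preserved.
#' @export
normalize_bulk <- function(raw_counts) {
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  totals <- colSums(raw_counts)
  if (any(totals == 0)) {
    bad <- colnames(raw_counts)[totals == 0]
    stop("cell line(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(raw_counts, 2, totals, "/") * 1e6
  bulk_expression(log10(cpm + 1))
}

# Shannon entropy (nats) of one gene's values from a 10-bin equal-width
# histogram over its own [min, max] range; constant genes get 0.
gene_entropy <- function(x, n_bins = 10L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

#' Filter uninformative genes
#'
#' Removes poorly expressed genes (all-zero across lines by default, or
#' below `min_expr` in every line), then genes whose across-line
#' expression entropy falls at or below the `entropy_percentile` quantile.
#' Entropy is computed from a 10-bin equal-width histogram of each gene's
#' values over its own range (natural log).
#'
#' @param expr a [bulk_expression].
#' @param entropy_percentile fraction in \[0, 1\]; `0` skips the entropy
#'   step and removes only poorly expressed genes.
#' @param min_expr genes with all values <= `min_expr` are dropped first.
#' @param n_bins histogram bins for the entropy estimate.
#' @return A [bulk_expression] restricted to the retained genes.
#' @export
filter_genes <- function(expr, entropy_percentile = 0.05, min_expr = 0,
                         n_bins = 10L) {
  stopifnot(inherits(expr, "bulk_expression"))
  if (length(expr$line_ids) < 2) stop("need at least 2 cell lines")
  v <- expr$values
  expressed <- apply(v, 1, function(x) any(x > min_expr))
  v <- v[expressed, , drop = FALSE]
  if (nrow(v) == 0) stop("all genes removed by the expression filter")
  if (entropy_percentile > 0) {
    H <- apply(v, 1, gene_entropy, n_bins = n_bins)
    thr <- quantile(H, entropy_percentile, type = 7, names = FALSE)
    v <- v[H > thr, , drop = FALSE]
    if (nrow(v) == 0) stop("all genes removed by the entropy filter")
  }
  bulk_expression(v)
}

#' Build one Genomic Profile of Drug Sensitivity
#'
#' Ranks every gene by the Pearson correlation between its expression and
#' a drug's potency across the cell lines where potency was measured.
#' Because low AUC means sensitive, positive correlations mark resistance
#' biomarkers and rank at the top; sensitivity biomarkers rank at the
#' bottom.
#'
#' @param expr a [bulk_expression].
#' @param potency_row named numeric vector of potency per line (NA =
#'   missing); names resolved against `expr$line_ids`.
#' @param drug_id identifier stored in the result.
#' @param min_lines minimum lines with measured potency (default 100, as
#'   used for large screens; lower it for small cohorts).
#' @param source_tag free-text provenance tag.
#' @param metric_tag potency metric, `"AUC"` or `"IC50"`.
#' @return An object of class `gpds` with fields `drug_id`, `genes`,
#'   `scores` (non-increasing), `n_lines_used`, `source_tag`,
#'   `metric_tag`, or `NULL` (with a warning) when too few lines are
#'   measured. Zero-variance genes get r = 0; ties are broken by gene id.
#' @export
build_gpds <- function(expr, potency_row, drug_id, min_lines = 100L,
                       source_tag = "unknown", metric_tag = "AUC") {
  stopifnot(inherits(expr, "bulk_expression"))
  if (is.null(names(potency_row))) {
    if (length(potency_row) != length(expr$line_ids))
      stop("unnamed potency_row must match the number of lines")
    names(potency_row) <- expr$line_ids
  }
  potency_row <- potency_row[expr$line_ids]
  keep <- !is.na(potency_row)
  if (sum(keep) < min_lines) {
    warning("drug ", drug_id, " skipped: potency measured for ", sum(keep),
            " line(s) < min_lines = ", min_lines)
    return(NULL)
  }
  x <- t(expr$values[, keep, drop = FALSE])
  r <- suppressWarnings(as.vector(cor(x, potency_row[keep])))
  r[is.na(r)] <- 0
  ord <- order(-r, expr$gene_ids)
  structure(list(drug_id = drug_id, genes = expr$gene_ids[ord],
                 scores = r[ord], n_lines_used = sum(keep),
                 source_tag = source_tag, metric_tag = metric_tag),
            class = "gpds")
}

#' @method print gpds
#' @export
print.gpds <- function(x, ...) {
  cat("gpds:", x$drug_id, "(", x$metric_tag, ",", x$n_lines_used,
      "lines ) —", length(x$genes), "ranked genes; top r =",
      signif(x$scores[1], 3), ", bottom r =",
      signif(x$scores[length(x$scores)], 3), "\n")
  invisible(x)
}

#' Build a GPDS collection from a viability table
#'
#' Runs [build_gpds()] for every drug in a [drug_viability] table; drugs
#' measured in fewer than `min_lines` lines are skipped with a warning.
#'
#' @inheritParams build_gpds
#' @param viability a [drug_viability].
#' @return An object of class `gpds_collection`: a list of `gpds` sharing
#'   one `gene_universe`.
#' @export
build_gpds_collection <- function(expr, viability, min_lines = 100L,
                                  source_tag = "unknown") {
  stopifnot(inherits(expr, "bulk_expression"),
            inherits(viability, "drug_viability"))
  shared <- intersect(viability$line_ids, expr$line_ids)
  if (length(shared) == 0) stop("no cell lines shared with expression matrix")
  out <- list()
  for (d in viability$drug_ids) {
    g <- build_gpds(expr, viability$potency[d, shared], drug_id = d,
                    min_lines = min_lines, source_tag = source_tag,
                    metric_tag = viability$metric_tag)
    if (!is.null(g)) out[[d]] <- g
  }
  if (length(out) == 0) stop("no drug passed the min_lines filter")
  gpds_collection(out)
}

#' Assemble a GPDS collection
#'
#' @param gpds_list list of `gpds` objects sharing one gene universe.
#' @return A `gpds_collection`.
#' @export
gpds_collection <- function(gpds_list) {
  stopifnot(length(gpds_list) > 0,
            all(vapply(gpds_list, inherits, logical(1), "gpds")))
  universe <- sort(gpds_list[[1]]$genes)
  for (g in gpds_list)
    if (!identical(sort(g$genes), universe))
      stop("all GPDS in a collection must cover the same gene universe")
  names(gpds_list) <- vapply(gpds_list, `[[`, character(1), "drug_id")
  structure(list(gpds = gpds_list, gene_universe = universe),
            class = "gpds_collection")
}

#' @method print gpds_collection
#' @export
print.gpds_collection <- function(x, ...) {
  cat("gpds_collection:", length(x$gpds), "drugs over",
      length(x$gene_universe), "genes\n")
  invisible(x)
}

#' Compare two GPDS of the same drug
#'
#' Spearman correlation of the per-gene correlation scores over the
#' shared gene universe; used to check cross-dataset consistency of a
#' drug's ranking.
#'
#' @param a,b `gpds` objects.
#' @return Numeric scalar, the Spearman correlation; the number of shared
#'   genes is attached as attribute `n_shared`.
#' @export
compare_gpds <- function(a, b) {
  stopifnot(inherits(a, "gpds"), inherits(b, "gpds"))
  shared <- intersect(a$genes, b$genes)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  sa <- a$scores[match(shared, a$genes)]
  sb <- b$scores[match(shared, b$genes)]
  scc <- cor(sa, sb, method = "spearman")
  attr(scc, "n_shared") <- length(shared)
  scc
}

#' Serialize a GPDS collection
#'
#' Writes one TSV per drug (`<drug_id>.gpds.tsv`, columns `gene`,
#' `score`, full double precision) and a JSON `manifest.json` with
#' per-drug metadata. `read_gpds_collection()` restores the collection
#' bit-exactly.
#'
#' @param x a `gpds_collection`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gpds_collection <- function(x, dir) {
  stopifnot(inherits(x, "gpds_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(x$gpds, function(g)
    list(drug_id = g$drug_id, source_tag = g$source_tag,
         metric_tag = g$metric_tag, n_lines_used = g$n_lines_used))
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (g in x$gpds) {
    f <- file.path(dir, paste0(sanitize_id(g$drug_id), ".gpds.tsv"))
    dt <- data.table::data.table(gene = g$genes,
                                 score = sprintf("%.17g", g$scores))
    data.table::fwrite(dt, f, sep = "\t")
  }
  invisible(dir)
}

#' @rdname write_gpds_collection
#' @export
read_gpds_collection <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  gl <- lapply(manifest, function(m) {
    f <- file.path(dir, paste0(sanitize_id(m$drug_id), ".gpds.tsv"))
    dt <- data.table::fread(f, sep = "\t", colClasses =
                              list(character = "gene", numeric = "score"))
    structure(list(drug_id = m$drug_id, genes = dt$gene,
                   scores = dt$score, n_lines_used = m$n_lines_used,
                   source_tag = m$source_tag, metric_tag = m$metric_tag),
              class = "gpds")
  })
  gpds_collection(gl)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
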