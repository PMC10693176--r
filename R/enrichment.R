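#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic pre-ranked GSEA running sum of a query gene set against a
#' GPDS ranking. Walking the ranked list from top (resistance
#' biomarkers) to bottom (sensitivity biomarkers), a hit increments the
#' sum by `|score|^weight_exponent` normalized by the total over hits, a
#' miss decrements it by `1 / (L - k)`. The ES is the signed maximum
#' deviation from zero, in \[-1, +1\]: positive means the query
#' concentrates among resistance biomarkers (predicted tolerant),
#' negative among sensitivity biomarkers (predicted sensitive).
#'
#' Query genes absent from the ranking are dropped; the overlap size is
#' returned as attribute `n_overlap`. When all hit weights are zero the
#' hit steps fall back to equal increments `1/k`. If the positive and
#' negative extrema tie in magnitude, the positive one is returned.
#'
#' @param ranked a [build_gpds()] object (genes sorted by non-increasing
#'   score).
#' @param query character vector of gene ids (a per-cell relevant gene
#'   set).
#' @param weight_exponent exponent on `|score|` for hit increments;
#'   1 = canonical weighted GSEA (default), 0 = unweighted KS.
#' @return Numeric ES, or `NA` (with attribute `n_overlap = 0`) when the
#'   query is disjoint from the ranking.
#' @export
gsea_es <- function(ranked, query, weight_exponent = 1) {
  stopifnot(inherits(ranked, "gpds"))
  pos <- sort(match(unique(query), ranked$genes))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0)
    return(structure(NA_real_, n_overlap = 0L))
  w <- abs(ranked$scores)^weight_exponent
  structure(.es_from_positions(w, pos), n_overlap = length(pos))
}

# Plain-R reference of the same statistic; kept as the cross-check for
# the C++ kernel (tests compare both against a brute-force walk).
gsea_es_r <- function(scores, pos, weight_exponent = 1) {
  L <- length(scores)
  pos <- sort(pos)
  k <- length(pos)
  w <- abs(scores[pos])^weight_exponent
  NR <- sum(w)
  step_hit <- if (NR > 0) w / NR else rep(1 / k, k)
  miss <- if (L > k) 1 / (L - k) else 0
  bottom <- cumsum(c(0, step_hit[-k])) - (pos - 1 - (seq_len(k) - 1)) * miss
  top <- bottom + step_hit
  sup <- max(0, top)
  inf <- min(0, bottom)
  if (sup + inf >= -1e-9) sup else inf
}

#' Monte-Carlo p-value for an enrichment score
#'
#' Estimates how often a random gene set of the same size, drawn
#' uniformly from the ranking's universe, reaches an ES at least as
#' extreme (in the observed sign) as the observed one. The Monte-Carlo
#' estimator is `(x + 1) / (n + 1)`; sampling stops early once the tail
#' count reaches `early_stop_tail` (the estimate is then already
#' clearly non-significant). `method = "exact"` enumerates all
#' `choose(L, k)` sets instead and returns the exact tail fraction.
#'
#' @inheritParams gsea_es
#' @param query_size number of genes in the query set.
#' @param observed_ES the ES whose tail probability is wanted.
#' @param n_perm maximum random sets to draw.
#' @param seed optional integer; when given, the RNG state is set
#'   locally and restored on exit.
#' @param sided `"two.sided"` (observed-sign tail doubled, capped at 1;
#'   default) or `"one.sided"`.
#' @param early_stop_tail adaptive early-stop bound on the tail count
#'   (`Inf` disables).
#' @param method `"montecarlo"` or `"exact"` (enumeration, feasible for
#'   small `choose(L, k)`).
#' @return p-value in (0, 1]; attribute `n_used` reports how many sets
#'   were evaluated.
#' @export
es_pvalue <- function(ranked, query_size, observed_ES, n_perm = 1000L,
                      seed = NULL, weight_exponent = 1,
                      sided = c("two.sided", "one.sided"),
                      early_stop_tail = 50L,
                      method = c("montecarlo", "exact")) {
  stopifnot(inherits(ranked, "gpds"), query_size >= 1, n_perm >= 1)
  sided <- match.arg(sided)
  method <- match.arg(method)
  w <- abs(ranked$scores)^weight_exponent
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (method == "exact") {
    L <- length(w)
    if (choose(L, query_size) > 2e5)
      stop("exact enumeration infeasible for choose(", L, ", ",
           query_size, ") sets")
    es_all <- .es_for_sets(w, combn(L, query_size))
    x <- if (observed_ES >= 0) sum(es_all >= observed_ES - 1e-12)
         else sum(es_all <= observed_ES + 1e-12)
    p <- x / length(es_all)
    n_used <- length(es_all)
  } else {
    x <- 0L; n_used <- 0L
    block <- 100L
    while (n_used < n_perm) {
      nb <- min(block, n_perm - n_used)
      es_b <- .es_random_sets(w, as.integer(query_size), as.integer(nb))
      x <- x + if (observed_ES >= 0) sum(es_b >= observed_ES - 1e-12)
               else sum(es_b <= observed_ES + 1e-12)
      n_used <- n_used + nb
      if (x >= early_stop_tail) break
    }
    p <- (x + 1) / (n_used + 1)
  }
  if (sided == "two.sided") p <- min(1, 2 * p)
  structure(min(1, max(p, .Machine$double.xmin)), n_used = n_used)
}

#' Score every (cell, drug) pair
#'
#' Computes the GSEA enrichment score of each cell's relevant gene set
#' against each GPDS, with a Monte-Carlo p-value per pair. Cells whose
#' query set is disjoint from a drug's gene universe get a flagged
#' undefined record (`ES = NA`); cells disjoint from every GPDS are
#' reported in a message, never silently dropped.
#'
#' @param cells a [top_relevant_genes()] result (or plain named list of
#'   gene-id vectors).
#' @param gpds a `gpds_collection`.
#' @param n_perm Monte-Carlo budget per pair.
#' @param seed integer seed controlling all permutations.
#' @inheritParams es_pvalue
#' @return A `data.frame` of class `enrichment_records` with columns
#'   `cell_id`, `drug_id`, `ES`, `p_value`, `n_overlap` (and `FDR` after
#'   [fdr_correct()]).
#' @export
score_cells <- function(cells, gpds, n_perm = 500L, seed = 1L,
                        weight_exponent = 1, early_stop_tail = 25L) {
  stopifnot(inherits(gpds, "gpds_collection"), length(cells) > 0)
  cell_ids <- names(cells)
  if (is.null(cell_ids)) stop("cells must be a named list")
  set.seed(seed)
  res <- vector("list", length(gpds$gpds))
  for (d in seq_along(gpds$gpds)) {
    g <- gpds$gpds[[d]]
    w <- abs(g$scores)^weight_exponent
    es <- p <- rep(NA_real_, length(cells))
    nov <- integer(length(cells))
    for (ci in seq_along(cells)) {
      pos <- match(unique(cells[[ci]]), g$genes)
      pos <- sort(pos[!is.na(pos)])
      nov[ci] <- length(pos)
      if (nov[ci] == 0) next
      es[ci] <- .es_from_positions(w, pos)
      x <- 0L; n_used <- 0L
      while (n_used < n_perm) {
        nb <- min(100L, n_perm - n_used)
        es_b <- .es_random_sets(w, nov[ci], as.integer(nb))
        x <- x + if (es[ci] >= 0) sum(es_b >= es[ci] - 1e-12)
                 else sum(es_b <= es[ci] + 1e-12)
        n_used <- n_used + nb
        if (x >= early_stop_tail) break
      }
      p[ci] <- min(1, 2 * (x + 1) / (n_used + 1))
    }
    res[[d]] <- data.frame(cell_id = cell_ids, drug_id = g$drug_id,
                           ES = es, p_value = p, n_overlap = nov,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  lost <- tapply(out$n_overlap, out$cell_id, max) == 0
  if (any(lost))
    message(sum(lost), " cell(s) had zero overlap with every GPDS: ",
            paste(head(names(lost)[lost], 5), collapse = ", "))
  class(out) <- c("enrichment_records", "data.frame")
  attr(out, "params") <- list(n_perm = n_perm, seed = seed,
                              weight_exponent = weight_exponent,
                              early_stop_tail = early_stop_tail)
  out
}

#' Per-drug Benjamini-Hochberg correction
#'
#' Applies the BH step-up adjustment to the p-values of each drug across
#' its cells (not across the whole record table), adding/overwriting the
#' `FDR` column.
#'
#' @param records an `enrichment_records` data frame.
#' @return The records with an `FDR` column.
#' @export
fdr_correct <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("drug_id", "p_value") %in% names(records)))
  records$FDR <- stats::ave(records$p_value, records$drug_id,
                            FUN = function(p) p.adjust(p, method = "BH"))
  records
}

#' Assemble the drug-response matrix E
#'
#' Cells x drugs matrix holding the enrichment score wherever the
#' per-drug FDR is below `fdr_threshold` and 0 elsewhere (0 = "no
#' supporting evidence", including undefined zero-overlap pairs).
#' `E > 0` predicts resistance, `E < 0` sensitivity.
#'
#' @param records FDR-corrected `enrichment_records`.
#' @param fdr_threshold significance cutoff (strict `<`), default 0.1.
#' @return A numeric matrix of class `drug_response` with cells in rows,
#'   drugs in columns, and `fdr_threshold` as an attribute.
#' @export
build_E_matrix <- function(records, fdr_threshold = 0.1) {
  stopifnot(is.data.frame(records), "FDR" %in% names(records))
  cells <- unique(records$cell_id)
  drugs <- unique(records$drug_id)
  E <- matrix(0, length(cells), length(drugs),
              dimnames = list(cells, drugs))
  sig <- !is.na(records$ES) & !is.na(records$FDR) &
    records$FDR < fdr_threshold
  E[cbind(match(records$cell_id[sig], cells),
          match(records$drug_id[sig], drugs))] <- records$ES[sig]
  structure(E, fdr_threshold = fdr_threshold,
            class = c("drug_response", "matrix", "array"))
}

#' Write / read enrichment records as long-format TSV
#'
#' @param records `enrichment_records`.
#' @param path TSV path.
#' @return `path` / the records, invisibly for the writer.
#' @export
write_records <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("enrichment_records", "data.frame")
  out
}
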