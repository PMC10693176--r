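resolve_grouping <- function(records, grouping) {
  g <- grouping[records$cell_id]
  if (anyNA(g)) stop("grouping is missing for some cells: ",
                     paste(head(unique(records$cell_id[is.na(g)]), 5),
                           collapse = ", "))
  g
}

#' Median enrichment score per cell population
#'
#' Aggregates per-cell predictions to groups by the median ES per
#' (group, drug); undefined (zero-overlap) records are excluded, and a
#' (group, drug) with no defined record is `NA`, not 0.
#'
#' @param records `enrichment_records`.
#' @param grouping named character/factor vector, cell id -> group.
#' @return group x drug numeric matrix of median ES.
#' @export
median_es <- function(records, grouping) {
  stopifnot(is.data.frame(records))
  g <- resolve_grouping(records, grouping)
  groups <- unique(g)
  drugs <- unique(records$drug_id)
  out <- matrix(NA_real_, length(groups), length(drugs),
                dimnames = list(groups, drugs))
  ok <- !is.na(records$ES)
  agg <- tapply(records$ES[ok], list(g[ok], records$drug_id[ok]), median)
  out[rownames(agg), colnames(agg)] <- agg
  out
}

#' Fraction of cells predicted sensitive
#'
#' Per (group, drug), the fraction of the group's cells whose ES is
#' negative and significant under the chosen rule — either per-drug
#' `FDR < fdr_threshold` (default elsewhere in the pipeline) or raw
#' `p < p_threshold` (the rule used for the therapeutic landscape).
#' Undefined records count in the denominator but can never be called
#' sensitive.
#'
#' @inheritParams median_es
#' @param rule `"fdr"` or `"p"`; must be chosen explicitly by callers
#'   that care (the landscape uses `"p"`).
#' @param fdr_threshold,p_threshold cutoffs for the two rules.
#' @return group x drug matrix of fractions in \[0, 1\].
#' @export
percent_sensitive <- function(records, grouping, rule = c("fdr", "p"),
                              fdr_threshold = 0.1, p_threshold = 0.05) {
  rule <- match.arg(rule)
  if (rule == "fdr" && !"FDR" %in% names(records))
    stop("rule = 'fdr' requires fdr_correct() first")
  g <- resolve_grouping(records, grouping)
  sig <- if (rule == "fdr") records$FDR < fdr_threshold
         else records$p_value < p_threshold
  hit <- !is.na(records$ES) & records$ES < 0 & !is.na(sig) & sig
  num <- tapply(hit, list(g, records$drug_id), sum)
  den <- tapply(hit, list(g, records$drug_id), length)
  out <- num / den
  out[is.na(out)] <- 0
  out
}

#' Viability-derived gold standard of sensitive pairs
#'
#' Per drug, z-scores the potency (AUC) across measured lines and flags
#' as sensitive the lines whose z-score lies at or below the
#' `percentile` quantile (type-7) of that drug's z-scores — i.e. the
#' lowest-potency tail. Drugs with fewer than 2 measured lines or zero
#' variance flag nothing (with a warning for the latter).
#'
#' @param viability a [drug_viability].
#' @param percentile tail fraction, default 0.05.
#' @return Object of class `gold_standard` with a `sensitive_pairs`
#'   data frame (`line_id`, `drug_id`) and the percentile used.
#' @export
build_gold_standard <- function(viability, percentile = 0.05) {
  stopifnot(inherits(viability, "drug_viability"),
            percentile > 0, percentile < 1)
  pairs <- list()
  for (d in viability$drug_ids) {
    x <- viability$potency[d, ]
    x <- x[!is.na(x)]
    if (length(x) < 2) next
    if (sd(x) == 0) {
      warning("drug ", d, " has zero potency variance; no lines flagged")
      next
    }
    z <- (x - mean(x)) / sd(x)
    thr <- quantile(z, percentile, type = 7, names = FALSE)
    flagged <- names(z)[z <= thr]
    if (length(flagged))
      pairs[[d]] <- data.frame(line_id = flagged, drug_id = d,
                               stringsAsFactors = FALSE)
  }
  structure(list(sensitive_pairs = do.call(rbind, c(pairs, list(
                   data.frame(line_id = character(0),
                              drug_id = character(0))))),
                 percentile = percentile,
                 metric_tag = viability$metric_tag),
            class = "gold_standard")
}

#' @method print gold_standard
#' @export
print.gold_standard <- function(x, ...) {
  cat("gold_standard:", nrow(x$sensitive_pairs), "sensitive (line, drug)",
      "pairs at percentile", x$percentile, "\n")
  invisible(x)
}

# Rank-statistic ROC AUC (ties by average rank); equals the
# Mann-Whitney U / (n+ * n-) identity.
roc_auc_rank <- function(score, label) {
  n_pos <- sum(label); n_neg <- sum(!label)
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate median-ES predictions against a gold standard
#'
#' Ranks (group, drug) pairs by the median ES multiplied by minus one,
#' so predicted-sensitive pairs come first, and scores the ranking
#' against the gold standard: ROC curve and rank-statistic ROC AUC, PR
#' curve with step interpolation, plus per-drug and per-line ROC AUCs
#' (restricted gold standard; degenerate strata give `NA`).
#'
#' @param pred group x drug matrix of median ES (groups are cell lines
#'   here); `NA` entries are dropped.
#' @param gold a [build_gold_standard()] object.
#' @return List of class `drug_eval`: `roc` and `pr` data frames,
#'   `roc_auc`, `pr_auc`, `per_drug_auc`, `per_line_auc`, `n_pos`,
#'   `n_neg`.
#' @export
evaluate <- function(pred, gold) {
  stopifnot(is.matrix(pred), inherits(gold, "gold_standard"))
  df <- data.frame(line_id = rownames(pred)[row(pred)],
                   drug_id = colnames(pred)[col(pred)],
                   es = as.vector(pred), stringsAsFactors = FALSE)
  df <- df[!is.na(df$es), ]
  key <- paste(df$line_id, df$drug_id, sep = "\r")
  gold_key <- paste(gold$sensitive_pairs$line_id,
                    gold$sensitive_pairs$drug_id, sep = "\r")
  df$label <- key %in% gold_key
  if (!any(df$label) || all(df$label))
    stop("degenerate gold standard: need at least one positive and one ",
         "negative pair among predictions")
  df$score <- -df$es
  ord <- order(-df$score)
  tp <- cumsum(df$label[ord])
  fp <- cumsum(!df$label[ord])
  n_pos <- sum(df$label); n_neg <- sum(!df$label)
  last <- !duplicated(df$score[ord], fromLast = TRUE)  # one point per threshold
  roc <- data.frame(threshold = c(Inf, df$score[ord][last]),
                    fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  pr <- data.frame(threshold = df$score[ord][last],
                   recall = tp[last] / n_pos,
                   precision = tp[last] / (tp[last] + fp[last]))
  pr_auc <- sum(diff(c(0, pr$recall)) * pr$precision)
  per_drug <- vapply(unique(df$drug_id), function(d) {
    s <- df[df$drug_id == d, ]
    if (length(unique(s$label)) < 2) return(NA_real_)
    roc_auc_rank(s$score, s$label)
  }, numeric(1))
  per_line <- vapply(unique(df$line_id), function(l) {
    s <- df[df$line_id == l, ]
    if (length(unique(s$label)) < 2) return(NA_real_)
    roc_auc_rank(s$score, s$label)
  }, numeric(1))
  structure(list(roc = roc, pr = pr,
                 roc_auc = roc_auc_rank(df$score, df$label),
                 pr_auc = pr_auc, per_drug_auc = per_drug,
                 per_line_auc = per_line, n_pos = n_pos, n_neg = n_neg),
            class = "drug_eval")
}

#' @method print drug_eval
#' @export
print.drug_eval <- function(x, ...) {
  cat("drug_eval:", x$n_pos, "positives /", x$n_neg, "negatives; ROC AUC",
      round(x$roc_auc, 3), "; PR AUC", round(x$pr_auc, 3), "\n")
  invisible(x)
}

#' Correlate predictions with observed drug response
#'
#' Spearman correlation between predicted median ES and observed
#' viability over matched (group, drug) pairs. Low viability goes with
#' negative ES for a good predictor, so a positive correlation is the
#' expected sign when correlating ES against viability directly.
#'
#' @param pred group x drug median-ES matrix.
#' @param observed group x drug observed viability/potency matrix.
#' @return List with `scc`, `p_value`, `n` (matched non-missing pairs).
#' @export
correlate_predictions <- function(pred, observed) {
  stopifnot(is.matrix(pred), is.matrix(observed))
  groups <- intersect(rownames(pred), rownames(observed))
  drugs <- intersect(colnames(pred), colnames(observed))
  x <- as.vector(pred[groups, drugs, drop = FALSE])
  y <- as.vector(observed[groups, drugs, drop = FALSE])
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 matched (group, drug) pairs")
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
  list(scc = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Binarized therapeutic landscape
#'
#' Builds the line x drug matrix `A` of fractions of cells predicted
#' sensitive (default rule: ES < 0 and p < 0.05), binarizes it at
#' `sens_threshold` (inclusive: `A >= 0.9 -> 1`), and hierarchically
#' clusters both rows and columns of the binary matrix with the Jaccard
#' ("binary") distance, cutting each dendrogram into `k` clusters.
#' Pairs of all-zero rows/columns have undefined Jaccard distance and
#' are treated as identical (distance 0).
#'
#' @inheritParams percent_sensitive
#' @param sens_threshold binarization cutoff on the sensitive fraction.
#' @param k_rows,k_cols cluster counts for lines and drugs (capped at
#'   the available number).
#' @param linkage agglomeration method for [stats::hclust()].
#' @return List of class `landscape`: `A`, `A_bin`, `row_clusters`,
#'   `col_clusters`, `row_hclust`, `col_hclust`.
#' @export
build_landscape <- function(records, grouping, sens_threshold = 0.9,
                            rule = "p", p_threshold = 0.05,
                            fdr_threshold = 0.1, k_rows = 4L, k_cols = 4L,
                            linkage = "complete") {
  A <- percent_sensitive(records, grouping, rule = rule,
                         fdr_threshold = fdr_threshold,
                         p_threshold = p_threshold)
  A_bin <- (A >= sens_threshold) * 1
  if (all(A_bin == 0))
    stop("binarized landscape is all zero; nothing to cluster ",
         "(lower sens_threshold or check predictions)")
  jacc <- function(m) {
    d <- as.matrix(dist(m, method = "binary"))
    d[is.na(d)] <- 0
    as.dist(d)
  }
  cluster_side <- function(m, k) {
    if (nrow(m) < 2)
      return(list(h = NULL, cl = setNames(rep(1L, nrow(m)), rownames(m))))
    h <- hclust(jacc(m), method = linkage)
    list(h = h, cl = cutree(h, k = min(k, nrow(m))))
  }
  rows <- cluster_side(A_bin, k_rows)
  cols <- cluster_side(t(A_bin), k_cols)
  structure(list(A = A, A_bin = A_bin,
                 row_clusters = rows$cl, col_clusters = cols$cl,
                 row_hclust = rows$h, col_hclust = cols$h,
                 sens_threshold = sens_threshold),
            class = "landscape")
}

#' @method print landscape
#' @export
print.landscape <- function(x, ...) {
  cat("landscape:", nrow(x$A), "lines x", ncol(x$A), "drugs;",
      sum(x$A_bin), "sensitive calls at threshold", x$sens_threshold, "\n")
  invisible(x)
}

# Mann-Whitney U test, two-sided. Exact enumeration of all
# choose(n1+n2, n1) labelings when the pooled size is <= exact_max_n
# (valid under ties); normal approximation with tie correction above.
mw_test <- function(x, y, exact_max_n = 8L) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max_n) {
    sets <- combn(n1 + n2, n1)
    U_all <- apply(sets, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(U - mu) / sqrt(sigma2))
  }
  list(U = U, p_value = min(1, p))
}

#' Differential drug sensitivity between subpopulations
#'
#' For every subpopulation and drug, a two-sided Mann-Whitney test
#' compares the ES of the subpopulation's cells against all other
#' cells; p-values are BH-corrected across drugs within each focal
#' subpopulation. A drug is called specific for a subpopulation when
#' its FDR is below `fdr_threshold` and the median ES in every other
#' subpopulation is greater than zero (the others are predicted
#' tolerant). Drugs whose ES is zero (or undefined) in all cells are
#' excluded; all-tied drugs get p = 1 and are never specific.
#'
#' @inheritParams median_es
#' @param labels named vector, cell id -> subpopulation (>= 2
#'   subpopulations, each with >= 2 cells).
#' @param fdr_threshold specificity cutoff, default 0.1.
#' @param exact_max_n pooled-size bound for exact enumeration in the
#'   Mann-Whitney test.
#' @return Data frame of class `diff_drug_result`: `group`, `drug_id`,
#'   `U`, `p_value`, `FDR`, `median_focal`, `min_median_others`,
#'   `specific`.
#' @export
diff_drug_analysis <- function(records, labels, fdr_threshold = 0.1,
                               exact_max_n = 8L) {
  stopifnot(is.data.frame(records))
  g <- resolve_grouping(records, labels)
  groups <- unique(g)
  if (length(groups) < 2) stop("need at least 2 subpopulations")
  sizes <- table(labels[unique(records$cell_id)])
  if (any(sizes < 2)) stop("every subpopulation needs >= 2 cells")
  med <- median_es(records, labels)
  rows <- list()
  for (gr in groups) {
    for (d in unique(records$drug_id)) {
      rec <- records[records$drug_id == d & !is.na(records$ES), ]
      if (nrow(rec) == 0) next
      es_g <- rec$ES[g[records$drug_id == d & !is.na(records$ES)] == gr]
      es_o <- rec$ES[g[records$drug_id == d & !is.na(records$ES)] != gr]
      if (length(es_g) < 2 || length(es_o) < 2) next
      if (all(c(es_g, es_o) == 0)) next
      mw <- mw_test(es_g, es_o, exact_max_n = exact_max_n)
      others <- med[setdiff(groups, gr), d]
      rows[[length(rows) + 1L]] <- data.frame(
        group = gr, drug_id = d, U = mw$U, p_value = mw$p_value,
        median_focal = med[gr, d],
        min_median_others = suppressWarnings(min(others, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no testable drug (all ES zero or undefined)")
  out <- do.call(rbind, rows)
  out$FDR <- stats::ave(out$p_value, out$group,
                        FUN = function(p) p.adjust(p, method = "BH"))
  out$specific <- out$FDR < fdr_threshold &
    is.finite(out$min_median_others) & out$min_median_others > 0
  class(out) <- c("diff_drug_result", "data.frame")
  out
}
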