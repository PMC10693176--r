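# Independent oracles, deliberately naive: each re-derives the quantity
# from its definition so the fast implementations have something honest
# to be checked against.

# Brute-force weighted KS running sum: walk the whole ranked list one
# gene at a time and take the signed maximum deviation (ties -> the
# positive extremum, as documented for gsea_es()).
oracle_es <- function(scores, hits, exponent = 1) {
  L <- length(scores)
  is_hit <- seq_len(L) %in% hits
  k <- sum(is_hit)
  w <- abs(scores)^exponent
  NR <- sum(w[is_hit])
  step <- numeric(L)
  step[is_hit] <- if (NR > 0) w[is_hit] / NR else 1 / k
  step[!is_hit] <- if (L > k) -1 / (L - k) else 0
  walk <- cumsum(step)
  sup <- max(0, walk)
  inf <- min(0, walk)
  # same tolerance-based tie rule as the implementation: an analytic
  # |sup| == |inf| tie goes to the positive extremum
  if (sup + inf >= -1e-9) sup else inf
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Exact two-sided Mann-Whitney p by enumerating every labeling of the
# pooled sample (valid under ties).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  sets <- combn(length(pooled), n1)
  U_all <- apply(sets, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Histogram entropy from the definition (10 equal-width bins over the
# gene's own range, natural log).
oracle_entropy <- function(x, n_bins = 10) {
  if (min(x) == max(x)) return(0)
  cuts <- cut(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
              include.lowest = TRUE)
  p <- table(cuts) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Elementwise Fuzzy Jaccard Distance between two sign vectors.
oracle_fjd <- function(sx, sy) {
  1 - sum(abs(sign(sx) + sign(sy))) / (2 * length(sx))
}

# ROC AUC by counting concordant prediction/gold pairs (ties count 1/2).
oracle_roc_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# --- small fixture builders ------------------------------------------------

make_gpds <- function(scores, genes = sprintf("g%03d", seq_along(scores)),
                      drug_id = "d1") {
  ord <- order(-scores, genes)
  structure(list(drug_id = drug_id, genes = genes[ord], scores = scores[ord],
                 n_lines_used = length(scores), source_tag = "test",
                 metric_tag = "AUC"),
            class = "gpds")
}

make_records <- function(cell_id, drug_id, ES, p_value = rep(0.01, length(ES)),
                         FDR = NULL, n_overlap = rep(10L, length(ES))) {
  df <- data.frame(cell_id = cell_id, drug_id = drug_id, ES = ES,
                   p_value = p_value, n_overlap = n_overlap,
                   stringsAsFactors = FALSE)
  if (!is.null(FDR)) df$FDR <- FDR
  class(df) <- c("enrichment_records", "data.frame")
  df
}

make_cell_counts <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  cell_counts(Matrix::Matrix(m, sparse = TRUE), ...)
}

# All sign vectors of length m over {-1, 0, +1}, one per row.
all_sign_vectors <- function(m, zero_free = FALSE) {
  vals <- if (zero_free) c(-1, 1) else c(-1, 0, 1)
  as.matrix(do.call(expand.grid, rep(list(vals), m)))
}
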