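grp <- function(cells, groups) setNames(groups, cells)

test_that("median_es aggregates per (group, drug) and excludes undefined", {
  rec <- make_records(cell_id = c("c1", "c2", "c3", "c4", "c1", "c2"),
                      drug_id = c(rep("dA", 4), "dB", "dB"),
                      ES = c(-0.2, -0.4, 0.1, 0.5, NA, NA))
  g <- grp(c("c1", "c2", "c3", "c4"), c("P", "P", "P", "Q"))
  m <- median_es(rec, g)
  expect_equal(m["P", "dA"], -0.2)       # median of {-0.2, -0.4, 0.1}
  expect_equal(m["Q", "dA"], 0.5)        # singleton group
  expect_true(is.na(m["P", "dB"]))       # all undefined -> NA, not 0
  expect_error(median_es(rec, g[1:2]), "missing")
})

test_that("percent_sensitive counts significant negative calls only", {
  # 10 cells: 3 pass the rule with ES < 0, 2 have ES < 0 but fail it
  rec <- make_records(cell_id = sprintf("c%02d", 1:10), drug_id = "dA",
                      ES = c(-0.5, -0.4, -0.3, -0.2, -0.1,
                             0.2, 0.3, 0.4, 0.5, 0.6),
                      p_value = c(0.01, 0.02, 0.03, 0.4, 0.9,
                                  0.01, 0.6, 0.7, 0.8, 0.9))
  g <- grp(sprintf("c%02d", 1:10), rep("P", 10))
  expect_equal(unname(percent_sensitive(rec, g, rule = "p")["P", "dA"]), 0.3)
  rec$FDR <- rep(1, 10)
  expect_equal(unname(percent_sensitive(rec, g, rule = "fdr")["P", "dA"]), 0)
  rec$FDR <- rep(0.01, 10); rec$ES <- rep(-0.3, 10)
  expect_equal(unname(percent_sensitive(rec, g, rule = "fdr")["P", "dA"]), 1)
})

test_that("build_gold_standard flags the low-AUC z-score tail", {
  set.seed(51)
  # 20 distinct AUCs at percentile 0.05 -> exactly the minimum flagged
  auc20 <- matrix(sample(seq(0.2, 0.9, length.out = 20)), 1, 20,
                  dimnames = list("dA", sprintf("l%02d", 1:20)))
  gs <- build_gold_standard(drug_viability(auc20))
  expect_equal(nrow(gs$sensitive_pairs), 1L)
  expect_equal(gs$sensitive_pairs$line_id,
               colnames(auc20)[which.min(auc20)])
  # 100 distinct values -> exactly 5 flagged (the 5 smallest)
  auc100 <- matrix(sample(seq_len(100) / 101), 1, 100,
                   dimnames = list("dA", sprintf("l%03d", 1:100)))
  gs100 <- build_gold_standard(drug_viability(auc100))
  expect_setequal(gs100$sensitive_pairs$line_id,
                  colnames(auc100)[order(auc100[1, ])[1:5]])
  # zero variance -> warning, nothing flagged
  flat <- matrix(0.5, 1, 10, dimnames = list("dA", sprintf("l%02d", 1:10)))
  expect_warning(gs_flat <- build_gold_standard(drug_viability(flat)),
                 "zero potency variance")
  expect_equal(nrow(gs_flat$sensitive_pairs), 0L)
})

test_that("gold-standard size is monotone in the percentile", {
  set.seed(52)
  auc <- matrix(runif(3 * 60), 3, 60,
                dimnames = list(sprintf("d%d", 1:3), sprintf("l%02d", 1:60)))
  viab <- drug_viability(auc)
  sizes <- vapply(c(0.02, 0.05, 0.1, 0.25, 0.5),
                  function(q) nrow(build_gold_standard(viab, q)$sensitive_pairs),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("evaluate ranks by -median ES and reproduces analytic AUCs", {
  gold <- structure(list(sensitive_pairs = data.frame(
    line_id = c("a", "b"), drug_id = "dA", stringsAsFactors = FALSE),
    percentile = 0.05, metric_tag = "AUC"), class = "gold_standard")
  # predicted order a, c, b, d (most sensitive first) with gold {a, b}
  pred <- matrix(c(-0.9, -0.5, -0.7, -0.1), 4, 1,
                 dimnames = list(c("a", "b", "c", "d"), "dA"))
  ev <- evaluate(pred, gold)
  expect_equal(ev$roc_auc, 0.75)
  # perfect and inverted orderings
  perfect <- matrix(c(-0.9, -0.8, 0.5, 0.6), 4, 1,
                    dimnames = list(c("a", "b", "c", "d"), "dA"))
  expect_equal(evaluate(perfect, gold)$roc_auc, 1)
  expect_equal(evaluate(-perfect, gold)$roc_auc, 0)
  # degenerate gold standard rejected
  all_pos <- structure(list(sensitive_pairs = data.frame(
    line_id = c("a", "b", "c", "d"), drug_id = "dA"),
    percentile = 0.05, metric_tag = "AUC"), class = "gold_standard")
  expect_error(evaluate(pred, all_pos), "degenerate")
})

test_that("evaluate ROC AUC equals the Mann-Whitney identity", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    es <- rnorm(n)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    lines <- sprintf("l%02d", seq_len(n))
    pred <- matrix(es, n, 1, dimnames = list(lines, "dA"))
    gold <- structure(list(sensitive_pairs = data.frame(
      line_id = lines[lab], drug_id = "dA", stringsAsFactors = FALSE),
      percentile = 0.05, metric_tag = "AUC"), class = "gold_standard")
    ev <- evaluate(pred, gold)
    expect_equal(ev$roc_auc, oracle_roc_auc(-es, lab))
    # PR curve sanity: precision/recall within [0, 1], recall reaches 1
    expect_true(all(ev$pr$precision >= 0 & ev$pr$precision <= 1))
    expect_equal(max(ev$pr$recall), 1)
  }
})

test_that("correlate_predictions matches the rank-correlation oracle", {
  pred <- matrix(1:5, 5, 1, dimnames = list(letters[1:5], "dA"))
  expect_equal(correlate_predictions(pred, pred)$scc, 1)
  expect_equal(correlate_predictions(pred, -pred)$scc, -1)
  obs <- matrix(c(2.3, 0.1, 5.5, 4.4, 3.0), 5, 1,
                dimnames = list(letters[1:5], "dA"))
  expect_equal(correlate_predictions(pred, obs)$scc,
               cor(1:5, obs[, 1], method = "spearman"))
  expect_error(correlate_predictions(pred[1:2, , drop = FALSE],
                                     obs[1:2, , drop = FALSE]), "fewer than 3")
})

test_that("build_landscape binarizes inclusively and recovers planted blocks", {
  # two clean line blocks responding to two disjoint drug blocks
  lines <- sprintf("L%02d", 1:6)
  drugs <- sprintf("D%02d", 1:4)
  cells <- sprintf("cell%02d", 1:60)
  g <- grp(cells, rep(lines, each = 10))
  block_of_line <- rep(c(1, 2), each = 3)
  rows <- expand.grid(cell_id = cells, drug_id = drugs,
                      stringsAsFactors = FALSE)
  line_of_cell <- g[rows$cell_id]
  drug_block <- ifelse(rows$drug_id %in% drugs[1:2], 1, 2)
  hit <- block_of_line[match(line_of_cell, lines)] == drug_block
  rec <- make_records(rows$cell_id, rows$drug_id,
                      ES = ifelse(hit, -0.5, 0.4),
                      p_value = ifelse(hit, 0.001, 0.8))
  ls <- build_landscape(rec, g, k_rows = 2, k_cols = 2)
  expect_true(all(ls$A %in% c(0, 1)))
  expect_equal(length(unique(ls$row_clusters[1:3])), 1)
  expect_equal(length(unique(ls$row_clusters[4:6])), 1)
  expect_false(ls$row_clusters[1] == ls$row_clusters[4])
  expect_false(ls$col_clusters[["D01"]] == ls$col_clusters[["D03"]])

  # boundary: fraction exactly 0.9 and above binarize to 1
  rec2 <- make_records(sprintf("c%02d", 1:20), "dA",
                       ES = c(rep(-0.5, 19), 0.3),
                       p_value = c(rep(0.01, 9), 0.5,
                                   rep(0.01, 8), 0.5, 0.01))
  g2 <- grp(sprintf("c%02d", 1:20), rep(c("L90", "L92"), each = 10))
  # L90: 9/10 pass -> exactly 0.9, binarized to 1 (inclusive bound);
  # L92: 8/10 pass -> 0.8 -> 0
  ls2 <- build_landscape(rec2, g2, k_rows = 2, k_cols = 1)
  expect_equal(unname(ls2$A["L90", "dA"]), 0.9)
  expect_equal(unname(ls2$A_bin["L90", "dA"]), 1)

  # all-zero binarized landscape is rejected
  rec3 <- make_records(sprintf("c%02d", 1:20), "dA", ES = rep(0.4, 20),
                       p_value = rep(0.9, 20))
  expect_error(build_landscape(rec3, g2), "all zero")
})

test_that("landscape clustering is invariant to input row order", {
  set.seed(54)
  cells <- sprintf("c%03d", 1:80)
  drugs <- sprintf("d%d", 1:6)
  g <- grp(cells, rep(sprintf("L%d", 1:8), each = 10))
  rows <- expand.grid(cell_id = cells, drug_id = drugs,
                      stringsAsFactors = FALSE)
  sens <- (as.integer(sub("L", "", g[rows$cell_id])) +
             as.integer(sub("d", "", rows$drug_id))) %% 2 == 0
  rec <- make_records(rows$cell_id, rows$drug_id,
                      ES = ifelse(sens, -0.6, 0.2),
                      p_value = ifelse(sens, 0.001, 0.7))
  ls_a <- build_landscape(rec, g, k_rows = 2, k_cols = 2)
  perm <- sample(nrow(rec))
  rec_p <- rec[perm, ]
  ls_b <- build_landscape(rec_p, g, k_rows = 2, k_cols = 2)
  expect_equal(ls_b$A[rownames(ls_a$A), colnames(ls_a$A)], ls_a$A)
  same_a <- outer(ls_a$row_clusters, ls_a$row_clusters, "==")
  same_b <- outer(ls_b$row_clusters[names(ls_a$row_clusters)],
                  ls_b$row_clusters[names(ls_a$row_clusters)], "==")
  expect_equal(same_b, same_a)  # identical partition up to label names
})

test_that("diff_drug_analysis reproduces the exact Mann-Whitney case", {
  cells <- sprintf("c%d", 1:6)
  labels <- grp(cells, rep(c("A", "B"), each = 3))
  rec <- make_records(cell_id = rep(cells, 2),
                      drug_id = rep(c("dX", "dY"), each = 6),
                      ES = c(-0.5, -0.4, -0.6, 0.1, 0.2, 0.3,
                             -0.5, -0.4, -0.6, 0.1, 0.2, 0.3))
  res <- diff_drug_analysis(rec, labels)
  a_dx <- res[res$group == "A" & res$drug_id == "dX", ]
  expect_equal(a_dx$U, 0)
  expect_equal(a_dx$p_value, 0.1)   # 2 / C(6,3) extreme labelings
  expect_equal(a_dx$median_focal, -0.5)
  expect_equal(a_dx$min_median_others, 0.2)
  # FDR = 0.1 is not < 0.1, so nothing is specific here
  expect_false(any(res$specific))
  # with more drugs at the same extreme configuration FDR stays 0.1
  expect_true(all(res$FDR == 0.1))
})

test_that("diff_drug_analysis p-values match enumeration for n <= 8", {
  set.seed(55)
  for (i in 1:15) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2), 1)  # ties likely
    got <- scdrugsea:::mw_test(x, y)
    expect_equal(got$p_value, oracle_mw_exact(x, y))
  }
  # identical distributions: never specific
  cells <- sprintf("c%d", 1:8)
  labels <- grp(cells, rep(c("A", "B"), each = 4))
  rec <- make_records(rep(cells, 1), "dX", ES = rep(c(-0.1, 0.2), 4))
  res <- diff_drug_analysis(rec, labels)
  expect_false(any(res$specific))
  # all-tied ES -> p = 1
  rec_t <- make_records(cells, "dX", ES = rep(0.3, 8))
  res_t <- diff_drug_analysis(rec_t, labels)
  expect_true(all(res_t$p_value == 1))
  # all-zero drug excluded
  rec_z <- rbind(rec_t, make_records(cells, "dZ", ES = rep(0, 8)))
  class(rec_z) <- c("enrichment_records", "data.frame")
  expect_false("dZ" %in% diff_drug_analysis(rec_z, labels)$drug_id)
})

test_that("large-sample Mann-Whitney approximation tracks wilcox.test", {
  set.seed(56)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  got <- scdrugsea:::mw_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
})
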