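#' Synthetic bulk pharmacogenomic cohort with planted biomarkers
#'
#' Emulates the structure of a bulk screen: per-drug potencies (AUC)
#' drawn uniformly on \[0, 1\] across cell lines, a log10-scale latent
#' expression matrix in which each drug's planted resistance biomarkers
#' follow `effect * AUC + noise` (sensitivity biomarkers the negated
#' slope) on top of a constant offset, background genes independent
#' noise around gene-specific baselines, and integer counts obtained by
#' exponentiating the latent matrix and multinomially sampling each
#' line's library. Biomarker gene sets are disjoint across drugs.
#'
#' @param n_lines,n_genes,n_drugs cohort dimensions.
#' @param n_biomarkers_per_drug planted genes per drug (half resistance,
#'   half sensitivity).
#' @param effect slope linking latent log10 expression to AUC.
#' @param noise_sd standard deviation of the latent Gaussian noise.
#' @param missing_frac fraction of potency entries set missing at
#'   random.
#' @param library_size_range per-line sequencing depth range.
#' @param seed integer; fixtures are bit-reproducible given (parameters,
#'   seed).
#' @return List with `counts` (genes x lines integer matrix),
#'   `viability` ([drug_viability]), and `truth` (planted biomarker
#'   table, parameters, seed).
#' @export
generate_pharmacogenomic_fixture <- function(n_lines = 200L,
                                             n_genes = 2000L,
                                             n_drugs = 20L,
                                             n_biomarkers_per_drug = 20L,
                                             effect = 1, noise_sd = 0.5,
                                             missing_frac = 0,
                                             library_size_range = c(1e6, 2e6),
                                             seed = 1L) {
  if (n_lines < 3) stop("need at least 3 cell lines")
  if (n_drugs * n_biomarkers_per_drug > n_genes)
    stop("not enough genes for disjoint biomarker sets")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  lines <- sprintf("line%03d", seq_len(n_lines))
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  auc <- matrix(runif(n_drugs * n_lines), n_drugs, n_lines,
                dimnames = list(drugs, lines))
  # disjoint planted sets; within each drug, first half resistance (+),
  # second half sensitivity (-)
  planted_idx <- matrix(sample.int(n_genes, n_drugs * n_biomarkers_per_drug),
                        nrow = n_drugs, byrow = TRUE)
  n_res <- ceiling(n_biomarkers_per_drug / 2)
  latent <- matrix(runif(n_genes, 0.5, 2.5), n_genes, n_lines) +
    matrix(rnorm(n_genes * n_lines, sd = noise_sd), n_genes, n_lines)
  truth_rows <- list()
  for (d in seq_len(n_drugs)) {
    idx <- planted_idx[d, ]
    slope <- rep(c(effect, -effect), c(n_res, n_biomarkers_per_drug - n_res))
    latent[idx, ] <- 1.5 + slope %o% auc[d, ] +
      matrix(rnorm(length(idx) * n_lines, sd = noise_sd),
             length(idx), n_lines)
    truth_rows[[d]] <- data.frame(
      drug_id = drugs[d], gene = genes[idx], effect = slope,
      class = rep(c("resistance", "sensitivity"),
                  c(n_res, n_biomarkers_per_drug - n_res)),
      stringsAsFactors = FALSE)
  }
  latent <- pmax(latent, 0)
  lib <- round(runif(n_lines, library_size_range[1], library_size_range[2]))
  counts <- vapply(seq_len(n_lines), function(l)
    rmultinom(1, size = lib[l], prob = 10^latent[, l])[, 1],
    integer(n_genes))
  dimnames(counts) <- list(genes, lines)
  if (missing_frac > 0)
    auc[matrix(runif(length(auc)) < missing_frac, n_drugs, n_lines)] <- NA
  list(counts = counts,
       viability = drug_viability(auc, metric_tag = "AUC"),
       truth = list(biomarkers = do.call(rbind, truth_rows), seed = seed,
                    params = list(n_lines = n_lines, n_genes = n_genes,
                                  n_drugs = n_drugs,
                                  n_biomarkers_per_drug = n_biomarkers_per_drug,
                                  effect = effect, noise_sd = noise_sd,
                                  missing_frac = missing_frac)))
}

#' Synthetic single-cell cohort with planted drug-response programs
#'
#' Emulates a population of cells split into subpopulations that are
#' sensitive or tolerant to given drugs. Each subpopulation's program
#' genes are taken from the extremes of the corresponding GPDS ranking
#' (tolerant: top / resistance biomarkers; sensitive: bottom /
#' sensitivity biomarkers). Program genes behave like markers: strongly
#' up-weighted (`signal_strength`) in their own subpopulation and
#' down-weighted (`off_program_factor`) elsewhere — necessary because
#' gf-icf assigns zero relevance to genes detected in every cell. UMI
#' counts are multinomially sampled at a per-cell library size drawn
#' from `library_size_range`; Bernoulli dropout zeroes each gene's
#' weight per cell before sampling, so every cell's total UMI equals
#' its drawn library size and QC passes by construction. A small block
#' of `MT-` genes carries `mito_frac` of the expected library.
#'
#' @param n_cells_per_pop cells per subpopulation.
#' @param populations named list; each element is a named character
#'   vector `drug_id -> "sensitive"|"tolerant"`.
#' @param gpds a `gpds_collection` providing the gene universe and
#'   rankings.
#' @param n_program_genes GPDS-extreme genes per (drug, phenotype).
#' @param signal_strength multiplicative up-weight of program genes in
#'   their own subpopulation.
#' @param off_program_factor multiplicative down-weight of program genes
#'   outside it.
#' @param library_size_range inclusive UMI depth range per cell.
#' @param dropout_rate per-(gene, cell) Bernoulli zeroing probability.
#' @param n_mito_genes,mito_frac size and expected UMI share of the
#'   mitochondrial block.
#' @param seed integer seed.
#' @return List with `counts` (a [cell_counts]) and `truth` (cell
#'   phenotype table, program genes, parameters, seed).
#' @export
generate_single_cell_fixture <- function(n_cells_per_pop = 100L,
                                         populations, gpds,
                                         n_program_genes = 50L,
                                         signal_strength = 5,
                                         off_program_factor = 0.05,
                                         library_size_range = c(5000, 20000),
                                         dropout_rate = 0.2,
                                         n_mito_genes = 10L,
                                         mito_frac = 0.03,
                                         seed = 1L) {
  stopifnot(inherits(gpds, "gpds_collection"), length(populations) > 0,
            !is.null(names(populations)))
  set.seed(seed)
  universe <- gpds$gene_universe
  program <- lapply(populations, function(prog) {
    bad <- setdiff(names(prog), names(gpds$gpds))
    if (length(bad))
      stop("program references drug(s) absent from gpds: ",
           paste(bad, collapse = ", "))
    unique(unlist(lapply(names(prog), function(d) {
      g <- gpds$gpds[[d]]
      if (prog[[d]] == "tolerant") head(g$genes, n_program_genes)
      else utils::tail(g$genes, n_program_genes)
    })))
  })
  all_program <- unique(unlist(program))
  base_w <- rlnorm(length(universe), 0, 1)
  names(base_w) <- universe
  mito_genes <- if (n_mito_genes > 0) sprintf("MT-%d", seq_len(n_mito_genes))
                else character(0)
  pops <- names(populations)
  cells <- list(); phen <- list()
  for (p in pops) {
    w <- base_w
    w[setdiff(all_program, program[[p]])] <-
      w[setdiff(all_program, program[[p]])] * off_program_factor
    w[program[[p]]] <- w[program[[p]]] * signal_strength
    mito_w <- if (n_mito_genes > 0)
      rep(mito_frac / (1 - mito_frac) * sum(w) / n_mito_genes, n_mito_genes)
    else numeric(0)
    wp <- c(w, stats::setNames(mito_w, mito_genes))
    lib <- round(runif(n_cells_per_pop, library_size_range[1],
                       library_size_range[2]))
    cnt <- vapply(seq_len(n_cells_per_pop), function(i) {
      wi <- wp * (runif(length(wp)) >= dropout_rate)
      if (all(wi == 0)) wi <- wp
      rmultinom(1, size = lib[i], prob = wi)[, 1]
    }, integer(length(wp)))
    colnames(cnt) <- sprintf("%s_cell%03d", p, seq_len(n_cells_per_pop))
    cells[[p]] <- cnt
    phen[[p]] <- do.call(rbind, lapply(names(populations[[p]]), function(d)
      data.frame(cell_id = colnames(cnt), population = p, drug_id = d,
                 phenotype = populations[[p]][[d]],
                 stringsAsFactors = FALSE)))
  }
  counts <- do.call(cbind, cells)
  rownames(counts) <- c(universe, mito_genes)
  cc <- cell_counts(Matrix::Matrix(counts, sparse = TRUE),
                    mito_flag = c(rep(FALSE, length(universe)),
                                  rep(TRUE, length(mito_genes))))
  list(counts = cc,
       truth = list(cell_phenotype = do.call(rbind, phen),
                    program_genes = program, seed = seed,
                    params = list(n_cells_per_pop = n_cells_per_pop,
                                  n_program_genes = n_program_genes,
                                  signal_strength = signal_strength,
                                  off_program_factor = off_program_factor,
                                  library_size_range = library_size_range,
                                  dropout_rate = dropout_rate,
                                  mito_frac = mito_frac)))
}

#' Monotone IC50-style transform of an AUC viability table
#'
#' Derives an IC50-flavoured potency table from AUC values through a
#' strictly increasing transform (rank order preserved), to exercise the
#' `metric_tag = "IC50"` configuration.
#'
#' @param viability an AUC [drug_viability].
#' @return A [drug_viability] with `metric_tag = "IC50"`.
#' @export
auc_to_ic50 <- function(viability) {
  stopifnot(inherits(viability, "drug_viability"))
  drug_viability(10^(3 * viability$potency - 1.5),
                 metric_tag = "IC50")
}
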