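# Seeded generator of tumor/normal multi-omic cohorts with known ground
# truth: a planted silenced splicing factor whose promoter gains
# methylation, target exons monotonically coupled to its expression, a
# latent proliferation variable driving a signature-gene block, and
# missing PSI entries.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline is built for: 9
#' tissues with 40 tumor and 25 normal samples each (cohorts of at least
#' 20 per group), 202 splicing factors of which one is planted as
#' epigenetically silenced, 314 target exons (about two thirds of them
#' microexons, and about two thirds starting from zero baseline inclusion
#' as known targets do outside neural tissue), a tumor/normal median
#' expression ratio of 3.67 for the planted factor, and a latent
#' proliferation variable anticorrelated with it.
#'
#' @param seed Integer seed; fully determines the generated cohort.
#' @param n_tissues Number of tissues (default 9).
#' @param n_tumor_per_tissue,n_normal_per_tissue Group sizes
#'   (defaults 40 / 25).
#' @param n_sfs Number of splicing factors (default 202).
#' @param n_background_genes Non-SF genes available as randomization
#'   background (default 600).
#' @param n_signature_genes Proliferation-signature genes (default 50).
#' @param n_exons Total exons in the PSI matrix (default 800).
#' @param n_targets Planted target exons (default 314).
#' @param fraction_microexon_targets Fraction of targets 3-27 nt long
#'   (default 0.66).
#' @param zero_baseline_fraction Fraction of targets with baseline PSI 0
#'   outside neural-like tissue (default 2/3).
#' @param planted_sf_index Index (1-based) of the planted SF (default 1).
#' @param expression_silencing_factor Divisor applied to the planted SF's
#'   tumor expression; >= 1 (default 3.67; 1 = null).
#' @param methylation_shift Additive tumor shift of the planted SF's
#'   promoter methylation on the logit scale, in \[0, 1\] (default 0.8;
#'   0 = null).
#' @param coupling_slope Slope of target PSI in `log1p` planted-SF
#'   expression (default 8; 0 = null).
#' @param psi_noise_sd Gaussian noise SD on the PSI scale (default 8).
#' @param mi_anticorrelation Loading of the latent proliferation variable
#'   on the planted SF's log expression, in \[-1, 0\] (default -0.4;
#'   0 = null).
#' @param missing_psi_rate Probability that a PSI cell is masked missing,
#'   in \[0, 1) (default 0.05).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_tissues = 9L,
                             n_tumor_per_tissue = 40L,
                             n_normal_per_tissue = 25L,
                             n_sfs = 202L,
                             n_background_genes = 600L,
                             n_signature_genes = 50L,
                             n_exons = 800L,
                             n_targets = 314L,
                             fraction_microexon_targets = 0.66,
                             zero_baseline_fraction = 2 / 3,
                             planted_sf_index = 1L,
                             expression_silencing_factor = 3.67,
                             methylation_shift = 0.8,
                             coupling_slope = 8,
                             psi_noise_sd = 8,
                             mi_anticorrelation = -0.4,
                             missing_psi_rate = 0.05) {
  cfg <- list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
              n_tumor_per_tissue = as.integer(n_tumor_per_tissue),
              n_normal_per_tissue = as.integer(n_normal_per_tissue),
              n_sfs = as.integer(n_sfs),
              n_background_genes = as.integer(n_background_genes),
              n_signature_genes = as.integer(n_signature_genes),
              n_exons = as.integer(n_exons), n_targets = as.integer(n_targets),
              fraction_microexon_targets = fraction_microexon_targets,
              zero_baseline_fraction = zero_baseline_fraction,
              planted_sf_index = as.integer(planted_sf_index),
              expression_silencing_factor = expression_silencing_factor,
              methylation_shift = methylation_shift,
              coupling_slope = coupling_slope,
              psi_noise_sd = psi_noise_sd,
              mi_anticorrelation = mi_anticorrelation,
              missing_psi_rate = missing_psi_rate)
  stopifnot(
    cfg$n_tissues >= 1, cfg$n_tumor_per_tissue >= 1,
    cfg$n_normal_per_tissue >= 1, cfg$n_sfs >= 1,
    cfg$n_exons >= cfg$n_targets, cfg$n_targets >= 1,
    cfg$fraction_microexon_targets >= 0, cfg$fraction_microexon_targets <= 1,
    cfg$zero_baseline_fraction >= 0, cfg$zero_baseline_fraction <= 1,
    cfg$planted_sf_index >= 1, cfg$planted_sf_index <= cfg$n_sfs,
    cfg$expression_silencing_factor >= 1,
    cfg$methylation_shift >= 0, cfg$methylation_shift <= 1,
    cfg$psi_noise_sd >= 0,
    cfg$mi_anticorrelation >= -1, cfg$mi_anticorrelation <= 0,
    cfg$missing_psi_rate >= 0, cfg$missing_psi_rate < 1
  )
  structure(cfg, class = "generator_config")
}

#' Null-mode generator configuration
#'
#' A [generator_config()] with every planted effect switched off (no
#' silencing, no methylation shift, no coupling, no proliferation
#' loading), for calibration experiments.
#'
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
null_config <- function(...) {
  overrides <- list(...)
  base <- list(expression_silencing_factor = 1, methylation_shift = 0,
               coupling_slope = 0, mi_anticorrelation = 0)
  do.call(generator_config, modifyList(base, overrides))
}

#' Generate a synthetic tumor/normal multi-omic cohort
#'
#' Draws, under a single seed, per-sample latent proliferation (higher
#' mean in tumors), splicing-factor expression (the planted factor divided
#' by the silencing factor in tumors and loaded negatively on
#' proliferation), promoter methylation beta values (the planted factor's
#' promoter shifted up in tumors and positively coupled to proliferation),
#' target-exon PSI as a clamped monotone (`log1p`) function of the planted
#' factor's expression plus Gaussian noise, independent non-target exons,
#' signature genes increasing in proliferation, and a missingness mask on
#' PSI. Identical configurations produce identical cohorts.
#'
#' @param config A [generator_config()].
#' @return A list of class `cohort_simulation`: `expression`,
#'   `methylation`, `psi` (each an [omics_matrix()]), `samples` (sample
#'   table), `target_map` (tibble `sf_id`, `exon_id`), `annotation` (exon
#'   annotation), `signature_genes` (character), and `truth` (planted SF
#'   id, target ids, per-tissue effect sizes, per-sample latent
#'   proliferation), plus the `config`.
#' @export
generate_cohorts <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  per_tissue <- cfg$n_tumor_per_tissue + cfg$n_normal_per_tissue
  samples <- tibble::tibble(
    tissue = rep(tissues, each = per_tissue),
    condition = rep(rep(c("tumor", "normal"),
                        c(cfg$n_tumor_per_tissue, cfg$n_normal_per_tissue)),
                    cfg$n_tissues)
  )
  samples$sample_id <- sprintf("%s_%s_%02d", samples$tissue,
                               substr(samples$condition, 1, 1),
                               stats::ave(seq_len(nrow(samples)),
                                          samples$tissue, samples$condition,
                                          FUN = seq_along))
  samples <- samples[c("sample_id", "tissue", "condition")]
  ns <- nrow(samples)
  is_tumor <- samples$condition == "tumor"
  tissue_idx <- match(samples$tissue, tissues)

  # latent proliferation, higher in tumors
  prolif <- rnorm(ns, mean = ifelse(is_tumor, 1, 0), sd = 1)

  sf_ids <- sprintf("SF%03d", seq_len(cfg$n_sfs))
  bg_ids <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  sig_ids <- sprintf("MIG%03d", seq_len(cfg$n_signature_genes))
  planted <- sf_ids[cfg$planted_sf_index]

  # expression: tissue-specific lognormal baselines, no tumor effect except
  # for the planted SF
  gene_ids <- c(sf_ids, bg_ids, sig_ids)
  ng <- length(gene_ids)
  base_gene <- matrix(exp(rnorm(ng * cfg$n_tissues, log(20), 0.5)),
                      nrow = ng)
  expr <- base_gene[, tissue_idx] * exp(matrix(rnorm(ng * ns, 0, 0.5),
                                               nrow = ng))
  rownames(expr) <- gene_ids

  planted_base <- runif(cfg$n_tissues, 2, 10)
  sf_expr <- planted_base[tissue_idx] *
    ifelse(is_tumor, 1 / cfg$expression_silencing_factor, 1) *
    exp(cfg$mi_anticorrelation * prolif + rnorm(ns, 0, 0.4))
  expr[planted, ] <- pmax(sf_expr, 0)

  sig_rows <- match(sig_ids, gene_ids)
  expr[sig_rows, ] <- base_gene[sig_rows, tissue_idx] *
    exp(0.5 * rep(prolif, each = length(sig_rows)) +
        rnorm(length(sig_rows) * ns, 0, 0.4))

  colnames(expr) <- samples$sample_id

  # promoter methylation for SFs and background genes
  meth_ids <- c(sf_ids, bg_ids)
  nm <- length(meth_ids)
  base_meth <- matrix(rnorm(nm * cfg$n_tissues, qlogis(0.3), 0.5), nrow = nm)
  meth_logit <- base_meth[, tissue_idx] + matrix(rnorm(nm * ns, 0, 0.3),
                                                 nrow = nm)
  meth_logit[match(planted, meth_ids), ] <-
    meth_logit[match(planted, meth_ids), ] +
    cfg$methylation_shift * is_tumor - cfg$mi_anticorrelation * prolif
  meth <- plogis(meth_logit)
  rownames(meth) <- meth_ids
  colnames(meth) <- samples$sample_id

  # exons: targets coupled to the planted SF, the rest independent
  target_ids <- sprintf("TEX%04d", seq_len(cfg$n_targets))
  nontarget_ids <- sprintf("NEX%04d", seq_len(cfg$n_exons - cfg$n_targets))
  exon_ids <- c(target_ids, nontarget_ids)
  zero_base <- runif(cfg$n_targets) < cfg$zero_baseline_fraction
  target_base <- ifelse(zero_base, 0, runif(cfg$n_targets, 20, 60))
  sf_term <- cfg$coupling_slope * log1p(expr[planted, ])
  psi_t <- outer(target_base, rep(1, ns)) +
    matrix(rep(sf_term, each = cfg$n_targets), nrow = cfg$n_targets) +
    matrix(rnorm(cfg$n_targets * ns, 0, cfg$psi_noise_sd),
           nrow = cfg$n_targets)
  n_non <- length(nontarget_ids)
  psi_n <- outer(runif(n_non, 0, 100), rep(1, ns)) +
    matrix(rnorm(n_non * ns, 0, cfg$psi_noise_sd), nrow = n_non, ncol = ns)
  psi <- pmin(pmax(rbind(psi_t, psi_n), 0), 100)
  rownames(psi) <- exon_ids
  colnames(psi) <- samples$sample_id
  if (cfg$missing_psi_rate > 0) {
    psi[runif(length(psi)) < cfg$missing_psi_rate] <- NA_real_
  }

  # annotation: target lengths mostly microexonic, non-targets mostly not
  n_micro_t <- round(cfg$fraction_microexon_targets * cfg$n_targets)
  target_len <- sample(c(sample(seq(3, 27, 3), n_micro_t, replace = TRUE),
                         sample(28:300, cfg$n_targets - n_micro_t,
                                replace = TRUE)))
  n_micro_n <- round(0.1 * n_non)
  nontarget_len <- sample(c(sample(seq(3, 27, 3), n_micro_n, replace = TRUE),
                            sample(28:300, n_non - n_micro_n,
                                   replace = TRUE)))
  annotation <- tibble::tibble(
    exon_id = exon_ids,
    gene_id = sprintf("HG%04d", seq_along(exon_ids)),
    length_nt = as.integer(c(target_len, nontarget_len))
  )

  # per-tissue effect sizes realized in the emitted matrices
  effects <- dplyr::bind_rows(lapply(seq_along(tissues), function(t) {
    sel <- tissue_idx == t
    med_t <- median(expr[planted, sel & is_tumor])
    med_n <- median(expr[planted, sel & !is_tumor])
    tibble::tibble(
      tissue = tissues[t],
      expression_ratio = med_t / med_n,
      methylation_delta = median(meth[planted, sel & is_tumor]) -
        median(meth[planted, sel & !is_tumor]),
      expected_dpsi = cfg$coupling_slope * (log1p(med_t) - log1p(med_n))
    )
  }))

  structure(list(
    expression = omics_matrix(expr, "expression"),
    methylation = omics_matrix(meth, "methylation"),
    psi = omics_matrix(psi, "psi"),
    samples = samples,
    target_map = tibble::tibble(sf_id = planted, exon_id = target_ids),
    annotation = annotation,
    signature_genes = sig_ids,
    truth = list(
      planted_sf_id = planted,
      target_exons = target_ids,
      zero_baseline_targets = target_ids[zero_base],
      effects = effects,
      proliferation = tibble::tibble(sample_id = samples$sample_id,
                                     proliferation = prolif)
    ),
    config = cfg
  ), class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "Synthetic cohort (seed %d): %d tissues x (%d tumor + %d normal), ",
    "%d SFs (planted: %s), %d exons (%d targets)\n"),
    cfg$seed, cfg$n_tissues, cfg$n_tumor_per_tissue, cfg$n_normal_per_tissue,
    cfg$n_sfs, x$truth$planted_sf_id, cfg$n_exons, cfg$n_targets))
  invisible(x)
}

#' Evaluate recovery of the planted truth by pipeline outputs
#'
#' Compares screen, exon-call, coupling and MI outputs computed from a
#' generated cohort against its ground truth. All arguments except the
#' simulation are optional; metrics for missing inputs are `NA`.
#'
#' @param sim A [generate_cohorts()] result.
#' @param expression_screen,methylation_screen Outputs of [run_screen()]
#'   on the simulated expression / methylation matrices.
#' @param exon_calls Output of [differential_psi()] on the simulated PSI.
#' @param randomization A [randomization_test()] result for the planted SF.
#' @param mi Output of [mi_score()] on the simulated expression.
#' @param q_threshold Threshold for consistency scoring (default 0.05).
#' @return A one-row tibble: `planted_sf_id`,
#'   `expression_rank` (1 = most negative consistency score),
#'   `methylation_rank` (1 = most positive), `target_sensitivity` (true
#'   targets significant in >= 1 tissue), `target_specificity`
#'   (non-targets never significant), `randomization_p`,
#'   `mi_sf_spearman` (MI score vs planted SF expression across tumors),
#'   `mi_latent_spearman` (MI score vs latent proliferation).
#' @export
evaluate_recovery <- function(sim, expression_screen = NULL,
                              methylation_screen = NULL, exon_calls = NULL,
                              randomization = NULL, mi = NULL,
                              q_threshold = 0.05) {
  stopifnot(inherits(sim, "cohort_simulation"))
  planted <- sim$truth$planted_sf_id
  expr_rank <- meth_rank <- NA_integer_
  if (!is.null(expression_screen)) {
    cs <- consistency_scores(expression_screen, q_threshold)
    if (!planted %in% cs$sf_id) abort("planted SF missing from screen output")
    expr_rank <- cs$rank[cs$sf_id == planted]
  }
  if (!is.null(methylation_screen)) {
    cs <- consistency_scores(methylation_screen, q_threshold)
    if (!planted %in% cs$sf_id) abort("planted SF missing from screen output")
    # most positive score first
    ord <- order(-cs$score, -xtfrm(cs$mean_fold_magnitude), cs$sf_id)
    meth_rank <- match(planted, cs$sf_id[ord])
  }
  sens <- spec <- NA_real_
  if (!is.null(exon_calls)) {
    truth_targets <- sim$truth$target_exons
    called <- unique(exon_calls$exon_id[exon_calls$significant])
    tested <- unique(exon_calls$exon_id)
    sens <- frac_or_na(length(intersect(called, truth_targets)),
                       length(intersect(tested, truth_targets)))
    non_targets <- setdiff(tested, truth_targets)
    spec <- frac_or_na(length(setdiff(non_targets, called)),
                       length(non_targets))
  }
  rand_p <- if (!is.null(randomization)) randomization$p_one_tailed else NA_real_
  mi_sf <- mi_latent <- NA_real_
  if (!is.null(mi)) {
    tumor_ids <- sim$samples$sample_id[sim$samples$condition == "tumor"]
    sc <- setNames(mi$mi_score, mi$sample_id)[tumor_ids]
    sf_expr <- omics_values(sim$expression)[planted, tumor_ids]
    mi_sf <- spearman_rho(sc, sf_expr)
    lat <- setNames(sim$truth$proliferation$proliferation,
                    sim$truth$proliferation$sample_id)[tumor_ids]
    mi_latent <- spearman_rho(sc, lat)
  }
  tibble::tibble(
    planted_sf_id = planted,
    expression_rank = expr_rank,
    methylation_rank = meth_rank,
    target_sensitivity = sens,
    target_specificity = spec,
    randomization_p = rand_p,
    mi_sf_spearman = mi_sf,
    mi_latent_spearman = mi_latent
  )
}

#' Write all cohort inputs of a simulation as TSV files
#'
#' Emits the expression, methylation and PSI matrices, the sample table,
#' target map, exon annotation, signature gene list and truth tables into
#' a directory, each with a comment header recording the seed. Output is
#' byte-identical for identical configurations.
#'
#' @param sim A [generate_cohorts()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("mexscreen synthetic cohort; seed=%d", sim$config$seed)
  write_omics_matrix(sim$expression, file.path(dir, "expression.tsv"), hdr)
  write_omics_matrix(sim$methylation, file.path(dir, "methylation.tsv"), hdr)
  write_omics_matrix(sim$psi, file.path(dir, "psi.tsv"), hdr)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$target_map, file.path(dir, "targets.tsv"))
  readr::write_tsv(sim$annotation, file.path(dir, "exons.tsv"))
  writeLines(sim$signature_genes, file.path(dir, "mi_genes.txt"))
  readr::write_tsv(sim$truth$effects, file.path(dir, "truth_effects.tsv"))
  readr::write_tsv(sim$truth$proliferation,
                   file.path(dir, "truth_proliferation.tsv"))
  invisible(dir)
}
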