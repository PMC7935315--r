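# End-to-end convenience wrapper used by the worked examples, the recovery
# experiments and the acceptance script.

#' Run the full screen-and-inclusion analysis on a cohort
#'
#' Convenience wrapper chaining the pipeline stages on matched expression,
#' methylation and PSI matrices: per-tissue differential screens of both
#' assays with consistency scoring, coverage-filtered differential exon
#' inclusion, direction and enrichment summaries for a target set, MI
#' signature scoring, and (optionally) the randomization test of the focal
#' splicing factor's target coupling.
#'
#' @param expression,methylation,psi [omics_matrix()] objects over the
#'   same samples (`methylation` may be `NULL`).
#' @param samples Sample table.
#' @param targets Character vector of target exon ids.
#' @param focal_sf Id of the focal splicing factor. When given, the
#'   randomization test is run on its expression profile over tumor
#'   samples.
#' @param signature_genes Optional MI signature gene ids.
#' @param annotation Optional exon annotation (adds microexon
#'   classification).
#' @param min_group_size,min_n,dpsi_threshold,q_threshold Thresholds
#'   passed to [run_screen()] and [differential_psi()].
#' @param screen_q q-value threshold for consistency direction counting
#'   (default 0.05).
#' @param B,rand_seed Randomization-test size and seed.
#' @return A list: `expression_screen`, `methylation_screen`,
#'   `expression_consistency`, `methylation_consistency`, `exon_calls`,
#'   `direction_summary`, `target_enrichment`, `direction_bias`,
#'   `mi_scores`, `randomization`.
#' @export
run_cohort_analysis <- function(expression, methylation = NULL, psi, samples,
                                targets, focal_sf = NULL,
                                signature_genes = NULL, annotation = NULL,
                                min_group_size = 20, min_n = 20,
                                dpsi_threshold = 5, q_threshold = 0.01,
                                screen_q = 0.05, B = 500, rand_seed = 1L) {
  expr_screen <- run_screen(expression, samples,
                            min_group_size = min_group_size,
                            sig_threshold = screen_q)
  meth_screen <- if (!is.null(methylation)) {
    run_screen(methylation, samples, min_group_size = min_group_size,
               sig_threshold = screen_q)
  }
  calls <- differential_psi(psi, samples, min_n = min_n,
                            dpsi_threshold = dpsi_threshold,
                            q_threshold = q_threshold,
                            annotation = annotation, targets = targets)
  mi <- if (!is.null(signature_genes)) mi_score(expression, signature_genes)
  rand <- NULL
  if (!is.null(focal_sf)) {
    tumor_ids <- samples$sample_id[samples$condition == "tumor"]
    expr_vals <- omics_values(expression)
    tumor_ids <- intersect(tumor_ids, colnames(expr_vals))
    psi_tumor <- psi[, c("feature_id", tumor_ids)]
    psi_tumor <- omics_matrix(psi_tumor, "psi")
    rand <- randomization_test(
      psi = psi_tumor, targets = targets,
      focal_profile = expr_vals[focal_sf, tumor_ids],
      background = expression, focal_id = focal_sf,
      B = B, tail = "greater", background_kind = "random",
      seed = rand_seed)
  }
  list(
    expression_screen = expr_screen,
    methylation_screen = meth_screen,
    expression_consistency = consistency_scores(expr_screen, screen_q),
    methylation_consistency = if (!is.null(meth_screen))
      consistency_scores(meth_screen, screen_q),
    exon_calls = calls,
    direction_summary = direction_summary(calls, targets),
    target_enrichment = target_enrichment(calls, targets),
    direction_bias = direction_bias_test(calls, targets),
    mi_scores = mi,
    randomization = rand
  )
}
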