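# Coverage-filtered tumor-vs-normal differential exon inclusion, microexon
# classification, direction summaries and target-set enrichment.

#' Classify microexons by length
#'
#' A microexon is a cassette exon between 3 and 27 nucleotides long,
#' inclusive on both boundaries.
#'
#' @param length_nt Integer vector of exon lengths in nucleotides
#'   (must be >= 1).
#' @return Logical vector.
#' @examples
#' classify_microexon(c(3, 27, 28))  # TRUE TRUE FALSE
#' @export
classify_microexon <- function(length_nt) {
  if (anyNA(length_nt) || any(length_nt < 1)) {
    abort("length_nt must be a positive integer")
  }
  length_nt >= 3 & length_nt <= 27
}

#' Coverage filter for PSI matrices
#'
#' Keeps exons quantified (non-missing PSI) in at least `min_n` tumor
#' samples and at least `min_n` normal samples of the given tissue. The
#' filter is monotone: raising `min_n` never enlarges the surviving set.
#'
#' @param psi An [omics_matrix()] of kind `"psi"`.
#' @param samples Sample table.
#' @param tissue Tissue label.
#' @param min_n Minimum quantified samples per group (default 20).
#' @return Character vector of surviving exon ids.
#' @export
coverage_filter <- function(psi, samples, tissue, min_n = 20) {
  if (!identical(omics_kind(psi), "psi")) abort("psi matrix required")
  vals <- omics_values(psi)
  s <- samples[samples$tissue == tissue & samples$sample_id %in% colnames(vals), ]
  if (!nrow(s)) abort(sprintf("tissue '%s' absent from samples", tissue))
  nt <- rowSums(!is.na(vals[, s$sample_id[s$condition == "tumor"], drop = FALSE]))
  nn <- rowSums(!is.na(vals[, s$sample_id[s$condition == "normal"], drop = FALSE]))
  rownames(vals)[nt >= min_n & nn >= min_n]
}

#' Differential exon inclusion between tumor and normal
#'
#' For each tissue, exons passing the coverage filter are tested with the
#' Wilcoxon-Mann-Whitney test on their non-missing PSI values;
#' Benjamini-Hochberg correction is applied within each tissue (the family
#' is all exons passing coverage there). dPSI is the difference of group
#' medians (tumor - normal). An exon is called significant when
#' `q < q_threshold` and `|dPSI| >= dpsi_threshold` (set
#' `strict_dpsi = TRUE` for a strict inequality).
#'
#' @inheritParams coverage_filter
#' @param tissue Tissue label(s); default all tissues in `samples`.
#' @param dpsi_threshold Minimum absolute dPSI for a call (default 5).
#' @param q_threshold q-value threshold (default 0.01).
#' @param strict_dpsi Use `|dPSI| > threshold` instead of `>=`
#'   (default `FALSE`).
#' @param annotation Optional exon annotation; adds an `is_microexon`
#'   column.
#' @param targets Optional character vector of target exon ids; adds an
#'   `is_target` column.
#' @return A tibble with one row per surviving exon and tissue: `exon_id`,
#'   `tissue`, `n_tumor`, `n_normal`, `psi_tumor`, `psi_normal`, `dpsi`,
#'   `p_value`, `q_value`, `significant`, `direction`, and optionally
#'   `is_microexon` / `is_target`.
#' @export
differential_psi <- function(psi, samples, tissue = NULL, min_n = 20,
                             dpsi_threshold = 5, q_threshold = 0.01,
                             strict_dpsi = FALSE, annotation = NULL,
                             targets = NULL) {
  if (!identical(omics_kind(psi), "psi")) abort("psi matrix required")
  vals <- omics_values(psi)
  tissues <- tissue %||% unique(samples$tissue)
  unknown <- setdiff(tissues, samples$tissue)
  if (length(unknown)) {
    abort(sprintf("tissue '%s' absent from samples", unknown[1]))
  }
  res <- purrr::map(tissues, function(tis) {
    keep <- coverage_filter(psi, samples, tis, min_n)
    if (!length(keep)) return(NULL)
    s <- samples[samples$tissue == tis & samples$sample_id %in% colnames(vals), ]
    tv <- vals[keep, s$sample_id[s$condition == "tumor"], drop = FALSE]
    nv <- vals[keep, s$sample_id[s$condition == "normal"], drop = FALSE]
    n <- length(keep)
    p <- mt <- mn <- numeric(n)
    ct <- cn <- integer(n)
    for (i in seq_len(n)) {
      xi <- tv[i, ]; yi <- nv[i, ]
      xi <- xi[!is.na(xi)]; yi <- yi[!is.na(yi)]
      ct[i] <- length(xi); cn[i] <- length(yi)
      mt[i] <- median(xi); mn[i] <- median(yi)
      p[i] <- mw_p(xi, yi)$p_value
    }
    tibble::tibble(exon_id = keep, tissue = tis, n_tumor = ct, n_normal = cn,
                   psi_tumor = mt, psi_normal = mn, dpsi = mt - mn,
                   p_value = p, q_value = bh_adjust(p))
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) return(out)
  pass_dpsi <- if (strict_dpsi) abs(out$dpsi) > dpsi_threshold
               else abs(out$dpsi) >= dpsi_threshold
  out$significant <- out$q_value < q_threshold & pass_dpsi
  out$direction <- dplyr::case_when(
    out$significant & out$dpsi > 0 ~ "up",
    out$significant & out$dpsi < 0 ~ "down",
    TRUE ~ "none"
  )
  if (!is.null(annotation)) {
    len <- annotation$length_nt[match(out$exon_id, annotation$exon_id)]
    out$is_microexon <- classify_microexon(len)
  }
  if (!is.null(targets)) out$is_target <- out$exon_id %in% targets
  out
}

frac_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Direction summaries of significant exon calls
#'
#' Per tissue, and pooled over all tissues, summarizes the significant
#' calls: the fraction of significant target exons decreasing in tumors,
#' the same split for microexons and non-microexons, and the fraction of
#' decreasing (respectively increasing) target exons that are microexons.
#' Empty denominators are reported as `NA`, never as 0.
#'
#' @param calls Output of [differential_psi()].
#' @param targets Character vector of target exon ids (default: the
#'   `is_target` column of `calls`).
#' @return A tibble with one row per tissue plus a `"pooled"` row.
#' @export
direction_summary <- function(calls, targets = NULL) {
  if (!is.null(targets)) calls$is_target <- calls$exon_id %in% targets
  if (is.null(calls$is_target)) abort("targets not given and no is_target column")
  sig <- calls[calls$significant, , drop = FALSE]
  one <- function(df, label) {
    tg <- df[df$is_target, , drop = FALSE]
    has_len <- !is.null(df$is_microexon)
    tibble::tibble(
      tissue = label,
      n_significant = nrow(df),
      n_target_significant = nrow(tg),
      frac_down = frac_or_na(sum(df$direction == "down"), nrow(df)),
      frac_target_down = frac_or_na(sum(tg$direction == "down"), nrow(tg)),
      frac_micro_down = if (has_len)
        frac_or_na(sum(df$direction == "down" & df$is_microexon),
                   sum(df$is_microexon)) else NA_real_,
      frac_nonmicro_down = if (has_len)
        frac_or_na(sum(df$direction == "down" & !df$is_microexon),
                   sum(!df$is_microexon)) else NA_real_,
      frac_down_targets_micro = if (has_len)
        frac_or_na(sum(tg$direction == "down" & tg$is_microexon),
                   sum(tg$direction == "down")) else NA_real_,
      frac_up_targets_micro = if (has_len)
        frac_or_na(sum(tg$direction == "up" & tg$is_microexon),
                   sum(tg$direction == "up")) else NA_real_
    )
  }
  per_tissue <- purrr::map(split(sig, sig$tissue), ~ one(.x, .x$tissue[1]))
  dplyr::bind_rows(c(per_tissue, list(one(sig, "pooled"))))
}

#' Target-set enrichment among significant exons
#'
#' Per tissue, a one-sided (greater) Fisher exact test on the 2x2 table
#' (significant vs not) x (target vs not) over all exons passing coverage
#' in that tissue.
#'
#' @inheritParams direction_summary
#' @return A tibble: `tissue`, `n_universe`, `n_target`, `n_significant`,
#'   `overlap` (significant targets), `p_value`.
#' @export
target_enrichment <- function(calls, targets = NULL) {
  if (!is.null(targets)) calls$is_target <- calls$exon_id %in% targets
  if (is.null(calls$is_target)) abort("targets not given and no is_target column")
  if (!nrow(calls)) abort("empty exon universe")
  calls |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_universe = dplyr::n(),
      n_target = sum(.data$is_target),
      n_significant = sum(.data$significant),
      overlap = sum(.data$significant & .data$is_target),
      p_value = fisher_exact_p(matrix(c(
        sum(.data$significant & .data$is_target),
        sum(.data$significant & !.data$is_target),
        sum(!.data$significant & .data$is_target),
        sum(!.data$significant & !.data$is_target)), nrow = 2),
        alternative = "greater"),
      .groups = "drop"
    )
}

#' Excess of decreasing target exons among significant calls
#'
#' Per tissue, restricted to significant calls, a one-sided Fisher exact
#' test of whether target exons are more often decreased than the
#' remaining significantly changing exons (the reference background). A
#' tissue with an empty margin yields `NA`.
#'
#' @inheritParams direction_summary
#' @return A tibble: `tissue`, `target_down`, `target_up`,
#'   `nontarget_down`, `nontarget_up`, `p_value`.
#' @export
direction_bias_test <- function(calls, targets = NULL) {
  if (!is.null(targets)) calls$is_target <- calls$exon_id %in% targets
  if (is.null(calls$is_target)) abort("targets not given and no is_target column")
  sig <- calls[calls$significant, , drop = FALSE]
  sig |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      target_down = sum(.data$is_target & .data$direction == "down"),
      target_up = sum(.data$is_target & .data$direction == "up"),
      nontarget_down = sum(!.data$is_target & .data$direction == "down"),
      nontarget_up = sum(!.data$is_target & .data$direction == "up"),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_value = purrr::pmap_dbl(
      list(.data$target_down, .data$target_up,
           .data$nontarget_down, .data$nontarget_up),
      function(td, tu, nd, nu) {
        if ((td + tu) < 1 || (nd + nu) < 1) return(NA_real_)
        fisher_exact_p(matrix(c(td, nd, tu, nu), nrow = 2),
                       alternative = "greater")
      }))
}
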