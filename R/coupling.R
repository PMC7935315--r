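# Coupling statistics: mitotic-index signature scoring, splicing-factor to
# target-exon correlation, randomization-test backgrounds, per-exon MI
# correlation and sign-agreement testing.

#' Mitotic-index signature scores
#'
#' Scores each sample as the mean, over signature genes, of the
#' within-cohort z-score of `log2(x + 1)` expression. The cohort is the
#' full set of columns of `expr`; cohort means of the scores are therefore
#' approximately zero. Samples with fewer than `min_fraction` of the
#' signature genes quantified get an `NA` score. Signature genes that are
#' constant across the cohort carry no ranking information and are dropped
#' from the score.
#'
#' @param expr An expression [omics_matrix()].
#' @param signature_genes Character vector of signature gene ids; at least
#'   2 must be present in `expr`.
#' @param min_fraction Minimum fraction of signature genes quantified per
#'   sample (default 0.5).
#' @return A tibble: `sample_id`, `mi_score`.
#' @export
mi_score <- function(expr, signature_genes, min_fraction = 0.5) {
  vals <- omics_values(expr)
  present <- intersect(signature_genes, rownames(vals))
  if (length(present) < 2) {
    abort("fewer than 2 signature genes present in the expression matrix")
  }
  lg <- log2(vals[present, , drop = FALSE] + 1)
  mu <- rowMeans(lg, na.rm = TRUE)
  s <- apply(lg, 1, sd, na.rm = TRUE)
  keep <- !is.na(s) & s > 0
  z <- (lg[keep, , drop = FALSE] - mu[keep]) / s[keep]
  n_quant <- colSums(!is.na(z))
  score <- colMeans(z, na.rm = TRUE)
  score[n_quant < min_fraction * length(present)] <- NA_real_
  tibble::tibble(sample_id = colnames(vals), mi_score = unname(score))
}

as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    setNames(profile[[2]], profile[[1]])
  } else if (!is.null(names(profile))) {
    profile
  } else {
    abort("profile must be a named numeric vector or a two-column data frame")
  }
}

# The randomization test evaluates B * |targets| Spearman pairs, so the
# per-target quantities that do not depend on the profile (the non-missing
# sample set and the ranks of PSI within it) are computed once, and each
# profile only contributes one rank per target. Results are identical to
# spearman_rho pair by pair.
prep_target_ranks <- function(psi_vals, targets) {
  targets <- intersect(targets, rownames(psi_vals))
  prep <- lapply(targets, function(e) {
    y <- psi_vals[e, ]
    ok <- which(!is.na(y))
    n <- length(ok)
    if (n < 3) return(NULL)
    ry <- rank(y[ok])
    s <- n * (n + 1) / 2
    cy <- sum(ry * ry) - s * s / n
    if (cy == 0) return(NULL)  # constant PSI: correlation undefined
    list(ok = ok, ry = ry, n = n, s = s, cy = cy)
  })
  names(prep) <- targets
  prep
}

coupling_vs_prep <- function(prof, prep) {
  prof_has_na <- anyNA(prof)
  vapply(prep, function(t) {
    if (is.null(t)) return(NA_real_)
    x <- prof[t$ok]
    if (prof_has_na && anyNA(x)) {
      keep <- !is.na(x)
      n <- sum(keep)
      if (n < 3) return(NA_real_)
      rx <- rank(x[keep]); ry <- rank(t$ry[keep])
      s <- n * (n + 1) / 2
      cx <- sum(rx * rx) - s * s / n
      cy <- sum(ry * ry) - s * s / n
      if (cx == 0 || cy == 0) return(NA_real_)
      return((sum(rx * ry) - s * s / n) / sqrt(cx * cy))
    }
    rx <- rank(x)
    cx <- sum(rx * rx) - t$s * t$s / t$n
    if (cx == 0) return(NA_real_)
    (sum(rx * t$ry) - t$s * t$s / t$n) / sqrt(cx * t$cy)
  }, numeric(1))
}

target_couplings <- function(profile, psi_vals, targets) {
  prof <- profile[colnames(psi_vals)]
  coupling_vs_prep(prof, prep_target_ranks(psi_vals, targets))
}

#' Median coupling of a per-sample profile with target exon PSI
#'
#' Computes the Spearman correlation (pairwise-complete) between the
#' profile (e.g. the expression or promoter methylation of a splicing
#' factor) and the PSI of each target exon, and reports the median over
#' targets with a defined correlation.
#'
#' @param profile Named numeric vector (names = sample ids) or two-column
#'   data frame (`sample_id`, value).
#' @param psi An [omics_matrix()] of kind `"psi"`. Samples to use (e.g.
#'   tumors of one tissue) are selected by subsetting its columns before
#'   the call.
#' @param targets Character vector of target exon ids.
#' @return A one-row tibble: `median_rho`, `n_targets` (requested),
#'   `n_used` (with a defined correlation).
#' @export
sf_target_coupling <- function(profile, psi, targets) {
  vals <- omics_values(psi)
  rho <- target_couplings(as_profile(profile), vals, targets)
  used <- rho[!is.na(rho)]
  if (!length(used)) abort("no target exon with a defined correlation")
  tibble::tibble(median_rho = median(used),
                 n_targets = length(targets), n_used = length(used))
}

#' Randomization test for median target coupling
#'
#' Tests whether the observed median Spearman correlation between a focal
#' profile and its target exons' PSI is more extreme than the same
#' statistic computed for randomly drawn background genes. For each of `B`
#' background genes sampled from `background_pool`, the median correlation
#' of that gene's profile (a row of `background`) with the same target set
#' is computed; the one-tailed p-value uses the add-one rule
#' `p = (1 + #\{background >= observed\}) / (B + 1)` for `tail = "greater"`
#' (mirrored for `"less"`), so p is never exactly zero. Sampling is
#' without replacement by default and deterministic under `seed`. The
#' focal gene must be excluded from the pool (use `focal_id`).
#'
#' @inheritParams sf_target_coupling
#' @param focal_profile Named numeric vector or two-column data frame: the
#'   profile whose coupling is being tested.
#' @param background An [omics_matrix()] (expression or methylation)
#'   providing background gene profiles over the same samples.
#' @param background_pool Character vector of candidate background gene
#'   ids (default: all rows of `background`).
#' @param focal_id Optional id of the focal gene, removed from the pool.
#' @param B Number of background genes to draw (default 500).
#' @param tail `"greater"` (default) or `"less"`.
#' @param background_kind Label recorded in the result: `"random"`,
#'   `"splicing_go"`, `"microexon_regulators"` or `"custom"`.
#' @param seed Optional integer seed; the RNG state is restored on exit.
#' @param replace Sample the pool with replacement (default `FALSE`; a
#'   pool smaller than `B` without replacement is an error).
#' @return An object of class `randomization_test` with elements
#'   `observed_median_rho`, `background_medians`, `n_background`,
#'   `p_one_tailed`, `tail`, `background_kind`, `background_ids`.
#'   [tidy()], [glance()] and [autoplot()] methods are provided.
#' @export
randomization_test <- function(psi, targets, focal_profile, background,
                               background_pool = NULL, focal_id = NULL,
                               B = 500, tail = c("greater", "less"),
                               background_kind = c("random", "splicing_go",
                                                   "microexon_regulators",
                                                   "custom"),
                               seed = NULL, replace = FALSE) {
  tail <- match.arg(tail)
  background_kind <- match.arg(background_kind)
  if (B < 1) abort("B must be >= 1")
  psi_vals <- omics_values(psi)
  bg_vals <- omics_values(background)
  shared <- intersect(colnames(psi_vals), colnames(bg_vals))
  if (length(shared) < 3) abort("too few shared samples between psi and background")
  psi_vals <- psi_vals[, shared, drop = FALSE]
  pool <- background_pool %||% rownames(bg_vals)
  pool <- setdiff(intersect(pool, rownames(bg_vals)), focal_id)
  if (!length(pool)) abort("empty background pool")
  if (!replace && length(pool) < B) {
    abort(sprintf("pool (%d) smaller than B (%d) without replacement",
                  length(pool), B))
  }
  obs <- sf_target_coupling(as_profile(focal_profile)[shared],
                            omics_matrix(psi_vals, "psi"), targets)$median_rho
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  drawn <- sample(pool, B, replace = replace)
  prep <- prep_target_ranks(psi_vals, targets)
  bg_med <- vapply(drawn, function(g) {
    rho <- coupling_vs_prep(bg_vals[g, shared], prep)
    rho <- rho[!is.na(rho)]
    if (!length(rho)) NA_real_ else median(rho)
  }, numeric(1))
  ok <- !is.na(bg_med)
  hits <- if (tail == "greater") sum(bg_med[ok] >= obs) else sum(bg_med[ok] <= obs)
  structure(list(
    observed_median_rho = obs,
    background_medians = unname(bg_med),
    n_background = sum(ok),
    p_one_tailed = (1 + hits) / (sum(ok) + 1),
    tail = tail,
    background_kind = background_kind,
    background_ids = drawn
  ), class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf(
    "Randomization test (%s background, B = %d, tail = %s)\n",
    x$background_kind, x$n_background, x$tail))
  cat(sprintf("  observed median rho: %.4f\n", x$observed_median_rho))
  cat(sprintf("  one-tailed p: %.4g\n", x$p_one_tailed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.randomization_test <- function(x, ...) {
  tibble::tibble(observed_median_rho = x$observed_median_rho,
                 p_value = x$p_one_tailed, tail = x$tail,
                 background_kind = x$background_kind,
                 n_background = x$n_background)
}

#' @exportS3Method generics::glance
glance.randomization_test <- function(x, ...) {
  tibble::tibble(p_value = x$p_one_tailed,
                 observed_median_rho = x$observed_median_rho,
                 background_median = median(x$background_medians, na.rm = TRUE),
                 n_background = x$n_background)
}

#' Per-exon correlation with the mitotic-index signature
#'
#' Spearman correlation between each exon's PSI and the MI score, across
#' tumor samples of each tissue (pairwise-complete, at least 3 pairs).
#' Exons failing the pair requirement, or with constant PSI, are reported
#' with `NA` rather than dropped.
#'
#' @param psi An [omics_matrix()] of kind `"psi"`.
#' @param mi Output of [mi_score()].
#' @param samples Sample table.
#' @param tissue Tissue label(s); default all tissues in `samples`.
#' @param p_threshold Significance flag threshold on the correlation
#'   p-value (default 0.05).
#' @return A tibble: `exon_id`, `tissue`, `n`, `rho`, `p_value`,
#'   `significant`.
#' @export
per_exon_mi_correlation <- function(psi, mi, samples, tissue = NULL,
                                    p_threshold = 0.05) {
  vals <- omics_values(psi)
  scores <- setNames(mi$mi_score, mi$sample_id)
  tissues <- tissue %||% unique(samples$tissue)
  res <- purrr::map(tissues, function(tis) {
    sid <- samples$sample_id[samples$tissue == tis &
                             samples$condition == "tumor"]
    sid <- intersect(sid, intersect(colnames(vals), names(scores)))
    m <- scores[sid]
    rows <- purrr::map(rownames(vals), function(e) {
      st <- spearman_test(vals[e, sid], m)
      tibble::tibble(exon_id = e, tissue = tis, n = st$n, rho = st$rho,
                     p_value = st$p_value)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(res)
  out$significant <- !is.na(out$p_value) & out$p_value < p_threshold
  out
}

#' Sign agreement between exon calls and MI correlations
#'
#' Evaluates (exon, tissue) pairs that carry both a significant
#' differential-inclusion call and a defined MI correlation, and tests with
#' a two-sided exact binomial test (p0 = 0.5) whether the sign of the MI
#' correlation matches the sign of dPSI more often than chance. With the
#' default `success = "concordant"`, a success is an exon whose PSI falls
#' where proliferation is high *and* falls in tumors (negative rho with
#' negative dPSI), or rises in both.
#'
#' @param calls Output of [differential_psi()].
#' @param rhos Output of [per_exon_mi_correlation()].
#' @param success `"concordant"` (default: same sign of rho and dPSI) or
#'   `"discordant"`.
#' @return An object of class `agreement_test`: `n`, `k`, `proportion`,
#'   `p_two_sided`. [tidy()] and [glance()] methods are provided.
#' @export
sign_agreement_test <- function(calls, rhos,
                                success = c("concordant", "discordant")) {
  success <- match.arg(success)
  df <- dplyr::inner_join(
    calls[calls$significant, c("exon_id", "tissue", "dpsi")],
    rhos[!is.na(rhos$rho), c("exon_id", "tissue", "rho")],
    by = c("exon_id", "tissue"))
  df <- df[df$rho != 0 & df$dpsi != 0, , drop = FALSE]
  if (!nrow(df)) abort("no (exon, tissue) pair with both a significant call and a defined correlation")
  same <- sign(df$rho) == sign(df$dpsi)
  k <- if (success == "concordant") sum(same) else sum(!same)
  n <- nrow(df)
  structure(list(n = n, k = k, proportion = k / n,
                 p_two_sided = binomial_test_p(k, n, 0.5, "two.sided"),
                 success = success),
            class = "agreement_test")
}

new_agreement <- function(n, k, success = "concordant") {
  structure(list(n = n, k = k,
                 proportion = if (n > 0) k / n else NA_real_,
                 p_two_sided = if (n > 0) binomial_test_p(k, n, 0.5, "two.sided")
                               else NA_real_,
                 success = success),
            class = "agreement_test")
}

#' @export
print.agreement_test <- function(x, ...) {
  cat(sprintf("Sign agreement: %d / %d (%.1f%%), two-sided binomial p = %.4g\n",
              x$k, x$n, 100 * x$proportion, x$p_two_sided))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.agreement_test <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, proportion = x$proportion,
                 p_value = x$p_two_sided, success = x$success)
}

#' @exportS3Method generics::glance
glance.agreement_test <- function(x, ...) tidy(x)
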