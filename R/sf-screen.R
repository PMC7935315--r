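# Pan-tissue splicing-factor screen: per-tissue tumor-vs-normal differential
# testing of expression / promoter methylation, cross-tissue consistency
# scoring and median fold-change summaries.

split_tissue_groups <- function(samples, cols) {
  # list of per-tissue lists with tumor / normal column indices into `cols`
  samples <- samples[samples$sample_id %in% cols, , drop = FALSE]
  idx <- match(samples$sample_id, cols)
  lapply(split(seq_len(nrow(samples)), samples$tissue), function(i) {
    list(tumor = idx[i][samples$condition[i] == "tumor"],
         normal = idx[i][samples$condition[i] == "normal"])
  })
}

#' Run a per-tissue differential screen over features
#'
#' For every feature and every tissue with at least `min_group_size` tumor
#' and `min_group_size` normal samples, compares tumor against normal with
#' the Wilcoxon-Mann-Whitney test and adjusts p-values with
#' Benjamini-Hochberg within each tissue (one family per tissue and assay).
#' Tissues with too few samples are skipped with a warning. A feature that
#' is identical in both groups (e.g. all-zero expression) yields p = 1 and
#' direction `"none"` rather than being dropped, keeping the score
#' denominator comparable across features.
#'
#' @param x An [omics_matrix()] (expression or methylation).
#' @param samples Sample table with `sample_id`, `tissue`, `condition`.
#' @param features Features to test (default: all rows of `x`). Features
#'   absent from `x` are an error.
#' @param min_group_size Minimum tumor and normal group size per tissue
#'   (default 20).
#' @param sig_threshold q-value threshold used to assign the `direction`
#'   label (default 0.05).
#' @param exact Passed to [mw_test()].
#' @return A tibble with one row per feature and tissue: `feature_id`,
#'   `tissue`, `assay`, `n_tumor`, `n_normal`, `median_tumor`,
#'   `median_normal`, `delta` (tumor - normal), `p_value`, `q_value`,
#'   `direction` (`"up"`, `"down"` or `"none"`).
#' @export
run_screen <- function(x, samples, features = NULL, min_group_size = 20,
                       sig_threshold = 0.05, exact = NULL) {
  assay <- omics_kind(x)
  vals <- omics_values(x)
  features <- features %||% rownames(vals)
  missing_feat <- setdiff(features, rownames(vals))
  if (length(missing_feat)) {
    abort(paste0("features absent from matrix: ",
                 paste(head(missing_feat, 5), collapse = ", ")))
  }
  vals <- vals[features, , drop = FALSE]
  groups <- split_tissue_groups(samples, colnames(vals))
  res <- purrr::imap(groups, function(g, tissue) {
    nt <- length(g$tumor); nn <- length(g$normal)
    if (nt < min_group_size || nn < min_group_size) {
      warn(sprintf("skipping tissue '%s': %d tumor / %d normal < %d",
                   tissue, nt, nn, min_group_size))
      return(NULL)
    }
    tv <- vals[, g$tumor, drop = FALSE]
    nv <- vals[, g$normal, drop = FALSE]
    p <- numeric(length(features))
    for (i in seq_along(features)) {
      xi <- tv[i, ]; yi <- nv[i, ]
      xi <- xi[!is.na(xi)]; yi <- yi[!is.na(yi)]
      p[i] <- mw_p(xi, yi, exact = exact)$p_value
    }
    tibble::tibble(
      feature_id = features,
      tissue = tissue,
      assay = assay,
      n_tumor = nt,
      n_normal = nn,
      median_tumor = apply(tv, 1, median, na.rm = TRUE),
      median_normal = apply(nv, 1, median, na.rm = TRUE),
      p_value = p,
      q_value = bh_adjust(p)
    )
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) abort("no tissue passed the minimum group size")
  out |>
    dplyr::mutate(
      delta = .data$median_tumor - .data$median_normal,
      direction = dplyr::case_when(
        .data$q_value < sig_threshold & .data$delta > 0 ~ "up",
        .data$q_value < sig_threshold & .data$delta < 0 ~ "down",
        TRUE ~ "none"
      )
    ) |>
    dplyr::relocate("delta", .after = "median_normal")
}

#' Median fold change of one feature in one tissue
#'
#' Ratio of the tumor median to the normal median. Zero medians yield
#' explicit sentinels rather than infinities: both zero gives status
#' `"undefined-both-zero"`, a zero normal median alone gives
#' `"undefined-zero-denominator"`, a zero tumor median alone gives ratio 0
#' with status `"zero-numerator"`. Non-`"ok"` rows are excluded from mean
#' fold magnitudes downstream.
#'
#' @param x An [omics_matrix()].
#' @param samples Sample table.
#' @param feature Feature id.
#' @param tissue Tissue label.
#' @return A one-row tibble: `feature_id`, `tissue`, `median_tumor`,
#'   `median_normal`, `ratio`, `magnitude` (`max(ratio, 1/ratio)` when
#'   defined), `status`.
#' @export
median_fold_change <- function(x, samples, feature, tissue) {
  vals <- omics_values(x)
  if (!feature %in% rownames(vals)) abort("feature absent from matrix")
  s <- samples[samples$tissue == tissue & samples$sample_id %in% colnames(vals), ]
  mt <- median(vals[feature, s$sample_id[s$condition == "tumor"]], na.rm = TRUE)
  mn <- median(vals[feature, s$sample_id[s$condition == "normal"]], na.rm = TRUE)
  fc <- classify_fold_change(mt, mn)
  tibble::tibble(feature_id = feature, tissue = tissue,
                 median_tumor = mt, median_normal = mn,
                 ratio = fc$ratio, magnitude = fc$magnitude,
                 status = fc$status)
}

classify_fold_change <- function(mt, mn) {
  if (mt == 0 && mn == 0) {
    list(ratio = NA_real_, magnitude = NA_real_, status = "undefined-both-zero")
  } else if (mn == 0) {
    list(ratio = NA_real_, magnitude = NA_real_,
         status = "undefined-zero-denominator")
  } else if (mt == 0) {
    list(ratio = 0, magnitude = NA_real_, status = "zero-numerator")
  } else {
    r <- mt / mn
    list(ratio = r, magnitude = max(r, 1 / r), status = "ok")
  }
}

#' Cross-tissue consistency scores
#'
#' Summarizes a differential screen per feature: the number of tissues with
#' a significant increase (`n_up`) and decrease (`n_down`) at
#' `q_threshold`, the consistency score `n_up - n_down`, flags for
#' significance in the same direction in every tested tissue, and the mean
#' fold magnitude (mean over tissues of `max(r, 1/r)` for the
#' tumor/normal median ratio `r`, tissues with undefined ratios excluded).
#' Features are ranked ascending by score (most consistently silenced
#' first); ties go to the larger mean fold magnitude, then lexical id.
#'
#' @param records Output of [run_screen()].
#' @param q_threshold Significance threshold for direction counting
#'   (default 0.05).
#' @return A tibble with one row per feature: `sf_id`, `assay`, `n_up`,
#'   `n_down`, `score`, `n_tissues_tested`, `consistent_all_down`,
#'   `consistent_all_up`, `mean_fold_magnitude`, `rank`.
#' @export
consistency_scores <- function(records, q_threshold = 0.05) {
  fc <- purrr::map2(records$median_tumor, records$median_normal,
                    classify_fold_change)
  records$.magnitude <- vapply(fc, `[[`, numeric(1), "magnitude")
  out <- records |>
    dplyr::group_by(sf_id = .data$feature_id, assay = .data$assay) |>
    dplyr::summarise(
      n_up = sum(.data$q_value < q_threshold & .data$delta > 0),
      n_down = sum(.data$q_value < q_threshold & .data$delta < 0),
      n_tissues_tested = dplyr::n(),
      mean_fold_magnitude =
        if (all(is.na(.data$.magnitude))) NA_real_
        else mean(.data$.magnitude, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      score = .data$n_up - .data$n_down,
      consistent_all_down = .data$n_down == .data$n_tissues_tested,
      consistent_all_up = .data$n_up == .data$n_tissues_tested
    )
  out <- out[order(out$score, -xtfrm(out$mean_fold_magnitude), out$sf_id), ]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "sf_id", "assay", "n_up", "n_down", "score",
                  "n_tissues_tested", "consistent_all_down",
                  "consistent_all_up", "mean_fold_magnitude", "rank")
}
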