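# Overexpression-response analysis: replicated dPSI target definition,
# shared inclusion sets across cell lines, fold-change expression calls and
# cross-dataset direction agreement.

as_change_table <- function(x, what = "change table") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) abort(sprintf("%s needs id and change columns", what))
    setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else if (!is.null(names(x))) {
    x
  } else {
    abort(sprintf("%s must be a named numeric vector or two-column data frame",
                  what))
  }
}

#' Define target exons from two perturbation replicates
#'
#' An exon is a target when its inclusion change (dPSI between
#' overexpression and control) reaches `threshold` in *both* replicates;
#' the boundary is inclusive (a change of exactly 25 counts at the default
#' threshold of 25). Higher thresholds always yield subsets.
#'
#' @param dpsi_rep1,dpsi_rep2 Change tables: named numeric vectors or
#'   two-column data frames (`exon_id`, dPSI).
#' @param threshold Minimum dPSI in each replicate (default 25).
#' @return Character vector of target exon ids.
#' @examples
#' define_targets(c(a = 30, b = 30), c(a = 26, b = 24))  # "a"
#' @export
define_targets <- function(dpsi_rep1, dpsi_rep2, threshold = 25) {
  r1 <- as_change_table(dpsi_rep1, "dpsi_rep1")
  r2 <- as_change_table(dpsi_rep2, "dpsi_rep2")
  shared <- intersect(names(r1), names(r2))
  if (!length(shared)) abort("replicates share no exons")
  shared[r1[shared] >= threshold & r2[shared] >= threshold]
}

#' Shared inclusion sets across cell lines
#'
#' From per-line change tables, derives the set of exons passing
#' `threshold` in each line and summarizes every observed combination of
#' lines with exclusive (UpSet-style) intersection counts, plus the
#' all-lines intersection and the union. Exclusive counts sum to the union
#' size by construction.
#'
#' @param per_line Named list (>= 2 entries) of change tables, one per
#'   cell line.
#' @param threshold Minimum change per line (default 25).
#' @return A list of class `inclusion_sets`: `sets` (per-line id sets),
#'   `intersections` (tibble `combination`, `n_lines`, `size`, exclusive
#'   counts, largest combinations first), `shared` (ids passing in every
#'   line) and `union`.
#' @export
shared_inclusion_sets <- function(per_line, threshold = 25) {
  if (length(per_line) < 2) abort("need at least 2 lines")
  if (is.null(names(per_line))) abort("per_line must be a named list")
  sets <- lapply(per_line, function(ct) {
    ct <- as_change_table(ct)
    names(ct)[ct >= threshold]
  })
  all_ids <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1,
                                                 dimnames = list(NULL, names(sets)))
  combo <- apply(membership, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  tab <- table(combo)
  inter <- tibble::tibble(
    combination = names(tab),
    n_lines = lengths(strsplit(names(tab), "&", fixed = TRUE)),
    size = as.integer(tab)
  )
  inter <- inter[order(-inter$n_lines, -inter$size), ]
  structure(list(
    sets = sets,
    intersections = inter,
    shared = Reduce(intersect, sets),
    union = all_ids
  ), class = "inclusion_sets")
}

#' @export
print.inclusion_sets <- function(x, ...) {
  cat(sprintf("Inclusion sets over %d lines: union %d, shared by all %d\n",
              length(x$sets), length(x$union), length(x$shared)))
  print(x$intersections, ...)
  invisible(x)
}

#' Fold-change expression calls
#'
#' Calls features up- or down-regulated from linear-scale expression in a
#' case and a control condition. A pseudocount guards against zero
#' denominators: `ratio = (case + pseudocount) / (control + pseudocount)`;
#' a feature is `"up"` when `ratio >= threshold` and `"down"` when
#' `ratio <= 1/threshold`.
#'
#' @param expr_case,expr_control Named numeric vectors or two-column data
#'   frames of non-negative linear-scale expression (e.g. cRPKM).
#' @param threshold Fold-change threshold, > 1 (default 2).
#' @param pseudocount Non-negative pseudocount (default 1).
#' @return A tibble over the shared features: `feature_id`, `case`,
#'   `control`, `ratio`, `call` (`"up"`, `"down"`, `"none"`).
#' @export
fold_change_calls <- function(expr_case, expr_control, threshold = 2,
                              pseudocount = 1) {
  if (threshold <= 1) abort("threshold must be > 1")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  case <- as_change_table(expr_case, "expr_case")
  control <- as_change_table(expr_control, "expr_control")
  if (any(case < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE)) {
    abort("expression must be non-negative")
  }
  shared <- intersect(names(case), names(control))
  ratio <- (case[shared] + pseudocount) / (control[shared] + pseudocount)
  tibble::tibble(
    feature_id = shared,
    case = unname(case[shared]),
    control = unname(control[shared]),
    ratio = unname(ratio),
    call = dplyr::case_when(ratio >= threshold ~ "up",
                            ratio <= 1 / threshold ~ "down",
                            TRUE ~ "none")
  )
}

#' Direction agreement between two perturbation datasets
#'
#' Features passing the magnitude cutoff in *both* datasets enter the
#' test; the number with the same sign of change in both is compared to a
#' fair coin with a two-sided exact binomial test. For `kind = "psi"`,
#' changes are dPSI and the cutoff applies as `|dPSI| >= cutoff`; for
#' `kind = "expression"`, changes are log2 fold changes and the cutoff is
#' on the linear fold scale (`|log2fc| >= log2(cutoff)`). The test is
#' symmetric in its two datasets. With no feature passing both cutoffs the
#' result is undefined (`NA`), not p = 1.
#'
#' @param changes_a,changes_b Change tables (named numeric vectors or
#'   two-column data frames).
#' @param threshold_a,threshold_b Magnitude cutoffs for each dataset
#'   (defaults: 5 for PSI, 2 for expression).
#' @param kind `"psi"` or `"expression"`.
#' @return An `agreement_test` object (`n`, `k`, `proportion`,
#'   `p_two_sided`), as from [sign_agreement_test()].
#' @export
cross_dataset_agreement <- function(changes_a, changes_b,
                                    threshold_a = NULL, threshold_b = NULL,
                                    kind = c("psi", "expression")) {
  kind <- match.arg(kind)
  default_thr <- if (kind == "psi") 5 else 2
  threshold_a <- threshold_a %||% default_thr
  threshold_b <- threshold_b %||% default_thr
  a <- as_change_table(changes_a, "changes_a")
  b <- as_change_table(changes_b, "changes_b")
  cut_a <- if (kind == "psi") threshold_a else log2(threshold_a)
  cut_b <- if (kind == "psi") threshold_b else log2(threshold_b)
  shared <- intersect(names(a), names(b))
  pass <- shared[!is.na(a[shared]) & !is.na(b[shared]) &
                 abs(a[shared]) >= cut_a & abs(b[shared]) >= cut_b]
  if (!length(pass)) {
    warn("no feature passes both cutoffs; agreement undefined")
    return(new_agreement(0L, 0L))
  }
  k <- sum(sign(a[pass]) == sign(b[pass]))
  new_agreement(length(pass), k)
}
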