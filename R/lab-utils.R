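# Closed-form wet-lab calculations: ddCt relative quantification,
# xenograft tumor volume, reference normalization for growth and
# competition assays.

#' Relative expression fold change by the ddCt method
#'
#' With Ct values already averaged over technical replicates,
#' `dCt = target_ct - reference_ct` per condition,
#' `ddCt = dCt_treated - dCt_control`, and the fold change is
#' `2^-ddCt`. Shifting both conditions' target Ct by the same constant
#' leaves the result unchanged.
#'
#' @param target_treated,reference_treated Target and reference-gene Ct of
#'   the treated condition (finite, > 0).
#' @param target_control,reference_control Same for the control condition.
#' @return The fold change `2^-ddCt` (vectorized).
#' @examples
#' ddct_fold_change(20, 15, 24, 15)  # ddCt = -4 -> 16
#' @export
ddct_fold_change <- function(target_treated, reference_treated,
                             target_control, reference_control) {
  ct <- c(target_treated, reference_treated, target_control,
          reference_control)
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    abort("Ct values must be finite and > 0")
  }
  ddct <- (target_treated - reference_treated) -
    (target_control - reference_control)
  2^(-ddct)
}

#' Xenograft tumor volume from caliper measurements
#'
#' `volume = (length x width^2) / 2`, in cubic millimetres. The volume
#' scales cubically under uniform scaling of both dimensions. Width larger
#' than length suggests swapped calipers and triggers a warning, not an
#' error.
#'
#' @param length_mm,width_mm Caliper measurements in mm (> 0).
#' @return Volume in cubic millimetres (vectorized).
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (anyNA(c(length_mm, width_mm)) || any(length_mm <= 0) ||
      any(width_mm <= 0)) {
    abort("dimensions must be positive")
  }
  if (any(width_mm > length_mm)) {
    warn("width exceeds length; measurements may be swapped")
  }
  length_mm * width_mm^2 / 2
}

#' Normalize a measurement series to a reference value
#'
#' Element-wise division by a positive reference, as used to express
#' growth-assay fluorescence relative to uninduced cells or competition
#' ratios relative to the first day.
#'
#' @param series Numeric vector.
#' @param reference_value Positive scalar.
#' @return `series / reference_value`.
#' @examples
#' normalize_to_reference(c(2, 4, 6), 2)
#' @export
normalize_to_reference <- function(series, reference_value) {
  if (length(reference_value) != 1 || is.na(reference_value) ||
      reference_value <= 0) {
    abort("reference_value must be a single positive number")
  }
  series / reference_value
}
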