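#' Normalized intensity (NI) of a gated sample
#'
#' NI is 1000 times the median over surviving cells of the per-cell
#' reporter/reference ratio. The even-count median is the mean of the two
#' central order statistics.
#'
#' @param gated A `gated_events` object from [apply_standard_gating()],
#'   or a plain event table with `reporter`/`reference` columns.
#' @param sample_id Optional identifier carried into the summary.
#' @return A `sample_summary`: list with `sample_id`, `NI`, `n_cells`.
#' @export
normalized_intensity <- function(gated, sample_id = NA_character_) {
  events <- if (inherits(gated, "gated_events")) gated$events else gated
  check_columns(events, c("reporter", "reference"))
  if (nrow(events) == 0) {
    abort_oc("insufficient_data_error", "no surviving events to summarize")
  }
  if (any(events$reference <= 0)) {
    abort_oc("division_domain_error",
             "non-positive reference intensity in survivor set")
  }
  ratio <- events$reporter / events$reference
  structure(list(sample_id = sample_id,
                 NI = 1000 * stats::median(ratio),
                 n_cells = nrow(events)),
            class = "sample_summary")
}

ni_value <- function(x) if (inherits(x, "sample_summary")) x$NI else as.numeric(x)

#' Relative intensity (RI): trigger-plus over trigger-minus NI
#'
#' @param ni_plus,ni_minus `sample_summary` objects or bare NI values for
#'   the trigger-plus and trigger-minus samples of one switch.
#' @return The ratio `NI(trigger+)/NI(trigger-)`.
#' @export
relative_intensity <- function(ni_plus, ni_minus) {
  num <- ni_value(ni_plus); den <- ni_value(ni_minus)
  if (!is.finite(den) || den <= 0) {
    abort_oc("division_domain_error", "trigger-minus NI must be > 0")
  }
  num / den
}

#' Relative reporter expression: RI normalized by the No-gRNA control
#'
#' The No-gRNA sample itself maps to exactly 1; percent repression of an
#' OFF switch is `1 - relative reporter expression`.
#'
#' @param ri RI of the sample of interest.
#' @param ri_no_grna RI of the No-gRNA control under the same trigger.
#' @return Dimensionless ratio.
#' @export
relative_reporter_expression <- function(ri, ri_no_grna) {
  if (!is.finite(ri_no_grna) || ri_no_grna <= 0) {
    abort_oc("division_domain_error", "No-gRNA RI must be > 0")
  }
  ri / ri_no_grna
}

#' Switch-type oriented fold change
#'
#' RI for ON switches, its reciprocal for OFF switches, so values >= 1
#' always mean switching in the designed direction.
#'
#' @param ri Relative intensity.
#' @param switch_type `"OFF"` or `"ON"`.
#' @return Fold change >= 0.
#' @export
fold_change <- function(ri, switch_type) {
  if (!is.finite(ri) || ri <= 0) {
    abort_oc("domain_error", "RI must be > 0 for fold change")
  }
  switch(toupper(switch_type),
         ON = ri,
         OFF = 1 / ri,
         abort_oc("invalid_parameter_error", "switch_type must be OFF or ON"))
}

#' Fold activation relative to a baseline sample
#'
#' @param ri_sample RI of the condition of interest.
#' @param ri_baseline RI of the all-negative baseline.
#' @return `ri_sample / ri_baseline`.
#' @export
fold_activation <- function(ri_sample, ri_baseline) {
  if (!is.finite(ri_baseline) || ri_baseline <= 0) {
    abort_oc("division_domain_error", "baseline RI must be > 0")
  }
  ri_sample / ri_baseline
}

#' Imaging defined value (DV)
#'
#' Median per-record reporter/reference ratio over the reference-positive
#' area of an image (inputs are assumed background-subtracted).
#'
#' @param pixel_pairs Data frame with `reporter` and `reference` columns.
#' @return The median ratio.
#' @export
imaging_defined_value <- function(pixel_pairs) {
  check_columns(pixel_pairs, c("reporter", "reference"))
  if (nrow(pixel_pairs) == 0) {
    abort_oc("insufficient_data_error", "empty reference-positive area")
  }
  if (any(pixel_pairs$reference <= 0)) {
    abort_oc("division_domain_error", "non-positive reference intensity")
  }
  stats::median(pixel_pairs$reporter / pixel_pairs$reference)
}

#' Imaging relative value (RV): DV of trigger-plus over trigger-minus
#'
#' @param dv_plus,dv_minus Defined values of the two conditions.
#' @return The ratio.
#' @export
imaging_relative_value <- function(dv_plus, dv_minus) {
  if (!is.finite(dv_minus) || dv_minus <= 0) {
    abort_oc("division_domain_error", "trigger-minus DV must be > 0")
  }
  dv_plus / dv_minus
}

#' Imaging normalized fold change (NFC): RV over the No-gRNA RV
#'
#' @param rv,rv_no_grna Relative values of the sample and the No-gRNA
#'   control.
#' @return Dimensionless ratio; the No-gRNA sample maps to exactly 1.
#' @export
imaging_normalized_fold_change <- function(rv, rv_no_grna) {
  if (!is.finite(rv_no_grna) || rv_no_grna <= 0) {
    abort_oc("division_domain_error", "No-gRNA RV must be > 0")
  }
  rv / rv_no_grna
}

#' Normalized fluorescence intensity (NFI)
#'
#' DV of a condition divided by the DV of the stated control condition
#' (for multi-state logic panels, the all-zero input state).
#'
#' @param dv_condition,dv_control Defined values.
#' @return Ratio; the control condition maps to exactly 1.
#' @export
normalized_fluorescence_intensity <- function(dv_condition, dv_control) {
  if (!is.finite(dv_control) || dv_control <= 0) {
    abort_oc("division_domain_error", "control DV must be > 0")
  }
  dv_condition / dv_control
}

#' Replicate mean and sample standard deviation
#'
#' @param values Numeric vector of per-replicate values.
#' @return List with `mean` and `sd` (sd is `NA` for a single value,
#'   computed with the n-1 denominator otherwise).
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) {
    abort_oc("insufficient_data_error", "no replicate values")
  }
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}
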