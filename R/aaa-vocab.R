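#' Controlled vocabularies for individual case safety reports
#'
#' Enumerations used throughout the pipeline. A spontaneous report carries a
#' causality assessment (as recorded by the reporter, not re-derived here),
#' a route of administration, and zero or more regulatory seriousness
#' criteria; a report is "serious" when at least one criterion applies.
#'
#' @name srs-vocab
#' @keywords internal
NULL

srs_genders <- c("male", "female", "unknown")

srs_causality_levels <- c(
  "certain", "probable", "possible", "unlikely", "unassessable", "unknown"
)

srs_routes <- c("parenteral", "oral", "other")

srs_yes_no_unknown <- c("yes", "no", "unknown")

srs_seriousness_criteria <- c(
  "death",
  "life_threatening",
  "carcinogenesis_teratogenesis_birth_defect",
  "disability",
  "hospitalization_or_prolongation",
  "other_important_medical_event"
)

#' @rdname srs-vocab
#' @format NULL
#' @export
srs_age_groups <- c("1-3", "4-6", "7-11", "12-14", "15-17")

#' @rdname srs-vocab
#' @format NULL
#' @export
srs_onset_bins <- c("on_the_day", "d1_3", "d4_7", "d8_14", "d15_30", "over_month")

# Round half away from zero, the convention used for all printed percentages
# (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a p-value for display
#'
#' Three decimals; values below 0.0005 render as `"<0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.4234, 0.0082, 1e-5))
format_p <- function(p) {
  ifelse(p < 5e-4, "<0.001", sprintf("%.3f", round_half_up(p, 3)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
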