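# Drug-event disproportionality statistics over a spontaneous-report
# corpus: reporting odds ratio (ROR), proportional reporting ratio (PRR),
# and the MHRA comprehensive criterion (minimum case count plus a
# Yates-corrected chi-square threshold).
#
# Each report contributes one (primary drug, primary ADR) pair. For a
# drug-event combination (DEC) the 2x2 table is
#   a  reports with the suspect drug and the suspect ADR
#   b  reports with the suspect ADR under other drugs
#   c  reports with the suspect drug and other ADRs
#   d  all remaining reports

#' Signal-mining configuration
#'
#' Defaults are the conventional published thresholds: a DEC is flagged by
#' ROR when `a >= 3` and the lower 95% CI limit exceeds 1; by PRR when
#' `a >= 3`, `PRR >= 2` and the lower CI limit exceeds 1; by the MHRA
#' criterion when `a >= 3` and the Yates-corrected chi-square is at least 4.
#'
#' @param min_a Minimum case count `a` for any flag.
#' @param ror_ci_threshold Lower-CI threshold for the ROR flag.
#' @param prr_threshold Point-estimate threshold for the PRR flag.
#' @param prr_ci_threshold Lower-CI threshold for the PRR flag.
#' @param chi2_threshold Threshold for the MHRA chi-square.
#' @param z Normal quantile for the CIs (1.96 = 95%).
#' @param zero_cell_policy `"undefined"` (default: any zero cell leaves the
#'   ratio and its CI undefined) or `"haldane_half"` (add 0.5 to every
#'   cell before computing ratios and CIs).
#' @param combine_rule How `flag_combined` aggregates the three methods:
#'   `"all"`, `"any"`, or `"majority"`.
#' @return A list with class `mining_config`.
#' @export
mining_config <- function(min_a = 3, ror_ci_threshold = 1, prr_threshold = 2,
                          prr_ci_threshold = 1, chi2_threshold = 4, z = 1.96,
                          zero_cell_policy = c("undefined", "haldane_half"),
                          combine_rule = c("all", "any", "majority")) {
  stopifnot(min_a >= 0, ror_ci_threshold > 0, prr_threshold > 0,
            chi2_threshold > 0, z > 0)
  structure(
    list(min_a = min_a, ror_ci_threshold = ror_ci_threshold,
         prr_threshold = prr_threshold, prr_ci_threshold = prr_ci_threshold,
         chi2_threshold = chi2_threshold, z = z,
         zero_cell_policy = match.arg(zero_cell_policy),
         combine_rule = match.arg(combine_rule)),
    class = "mining_config"
  )
}

#' @rdname mining_config
#' @param path Path to a YAML file whose keys match the arguments above.
#' @export
mining_config_from_yaml <- function(path) {
  do.call(mining_config, yaml::read_yaml(path))
}

#' Build drug-event 2x2 contingency tables
#'
#' One table per distinct observed (primary drug, primary ADR) pair. Every
#' table satisfies `a + b + c + d = n` (the corpus size) and the `a` cells
#' over all pairs sum to `n`.
#'
#' @param coded Coded-report tibble (columns `primary_drug`, `primary_adr`).
#' @return A tibble with columns `drug`, `event`, `a`, `b`, `c`, `d`.
#' @export
build_dec_tables <- function(coded) {
  if (nrow(coded) == 0) {
    return(tibble::tibble(drug = character(), event = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer()))
  }
  n <- nrow(coded)
  pairs <- dplyr::count(coded, drug = .data$primary_drug,
                        event = .data$primary_adr, name = "a")
  drug_tot <- dplyr::count(coded, drug = .data$primary_drug, name = "n_drug")
  event_tot <- dplyr::count(coded, event = .data$primary_adr, name = "n_event")
  pairs |>
    dplyr::left_join(drug_tot, by = "drug") |>
    dplyr::left_join(event_tot, by = "event") |>
    dplyr::mutate(
      b = .data$n_event - .data$a,
      c = .data$n_drug - .data$a,
      d = n - .data$a - .data$b - .data$c
    ) |>
    dplyr::select("drug", "event", "a", "b", "c", "d")
}

adjust_cells <- function(a, b, c, d, policy) {
  if (policy == "haldane_half") {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    list(a = a + 0.5 * zero, b = b + 0.5 * zero, c = c + 0.5 * zero,
         d = d + 0.5 * zero, defined = rep(TRUE, length(a)))
  } else {
    list(a = a, b = b, c = c, d = d,
         defined = a > 0 & b > 0 & c > 0 & d > 0)
  }
}

log_scale_ci <- function(est, a, b, c, d, z) {
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(low = exp(log(est) - z * se), high = exp(log(est) + z * se))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a/c) / (b/d) = ad / bc`, with the CI taken on the log scale:
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Under the default
#' zero-cell policy any zero cell leaves the estimate undefined (`NA`);
#' no continuity correction is applied unless `haldane_half` is requested.
#'
#' @param a,b,c,d Integer vectors of cell counts (recycled together).
#' @param config A [mining_config()].
#' @return A tibble with columns `ror`, `ror_low`, `ror_high`.
#' @export
#' @examples
#' ror_with_ci(10, 20, 30, 240)
ror_with_ci <- function(a, b, c, d, config = mining_config()) {
  stopifnot(all(c(a, b, c, d) >= 0))
  cells <- adjust_cells(a, b, c, d, config$zero_cell_policy)
  est <- with(cells, a * d / (b * c))
  est[!cells$defined] <- NA_real_
  ci <- log_scale_ci(est, cells$a, cells$b, cells$c, cells$d, config$z)
  tibble::tibble(
    ror = est,
    ror_low = ifelse(cells$defined, ci$low, NA_real_),
    ror_high = ifelse(cells$defined, ci$high, NA_real_)
  )
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, with the CI on the log scale using the
#' same `sqrt(1/a + 1/b + 1/c + 1/d)` standard error as the ROR, and the
#' same zero-cell handling.
#'
#' @inheritParams ror_with_ci
#' @return A tibble with columns `prr`, `prr_low`, `prr_high`.
#' @export
#' @examples
#' prr_with_ci(10, 20, 30, 240)
prr_with_ci <- function(a, b, c, d, config = mining_config()) {
  stopifnot(all(c(a, b, c, d) >= 0))
  cells <- adjust_cells(a, b, c, d, config$zero_cell_policy)
  est <- with(cells, (a / (a + b)) / (c / (c + d)))
  est[!cells$defined] <- NA_real_
  ci <- log_scale_ci(est, cells$a, cells$b, cells$c, cells$d, config$z)
  tibble::tibble(
    prr = est,
    prr_low = ifelse(cells$defined, ci$low, NA_real_),
    prr_high = ifelse(cells$defined, ci$high, NA_real_)
  )
}

#' MHRA Yates-corrected chi-square statistic
#'
#' The continuity-corrected chi-square on the DEC 2x2 table,
#' `n * (max(0, |ad - bc| - n/2))^2 / [(a+b)(c+d)(a+c)(b+d)]`, with the
#' continuity term clamped at zero so perfectly independent tables score 0.
#' A table with a zero marginal carries no association information; its
#' statistic is defined as 0 with a warning.
#'
#' @param a,b,c,d Integer vectors of cell counts.
#' @return Numeric vector of chi-square values.
#' @export
#' @examples
#' mhra_chi2(22, 23, 114, 272)
mhra_chi2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  bad <- denom == 0
  if (any(bad)) {
    warning(sum(bad), " table(s) with a zero marginal; chi-square set to 0",
            call. = FALSE)
  }
  num <- n * pmax(0, abs(a * d - b * c) - n / 2)^2
  out <- ifelse(bad, 0, num / ifelse(bad, 1, denom))
  out
}

#' Evaluate disproportionality signals for all DEC tables
#'
#' Computes ROR, PRR (with CIs) and the MHRA chi-square for every table and
#' applies the flag rules of the [mining_config()]. All flags are `FALSE`
#' whenever `a < min_a`. Results are sorted by chi-square, descending.
#'
#' @param tables Tibble from [build_dec_tables()].
#' @param config A [mining_config()].
#' @return The input tibble augmented with `ror`, `ror_low`, `ror_high`,
#'   `prr`, `prr_low`, `prr_high`, `chi2`, `flag_ror`, `flag_prr`,
#'   `flag_mhra`, `flag_combined`; the configuration is attached as the
#'   `"mining_config"` attribute.
#' @export
evaluate_signals <- function(tables, config = mining_config()) {
  if (nrow(tables) == 0) {
    out <- dplyr::mutate(tables, ror = numeric(0), ror_low = numeric(0),
                         ror_high = numeric(0), prr = numeric(0),
                         prr_low = numeric(0), prr_high = numeric(0),
                         chi2 = numeric(0), flag_ror = logical(0),
                         flag_prr = logical(0), flag_mhra = logical(0),
                         flag_combined = logical(0))
    attr(out, "mining_config") <- config
    return(out)
  }
  ror <- ror_with_ci(tables$a, tables$b, tables$c, tables$d, config)
  prr <- prr_with_ci(tables$a, tables$b, tables$c, tables$d, config)
  chi2 <- suppressWarnings(mhra_chi2(tables$a, tables$b, tables$c, tables$d))

  gate <- tables$a >= config$min_a
  flag_ror <- gate & !is.na(ror$ror_low) & ror$ror_low > config$ror_ci_threshold
  flag_prr <- gate & !is.na(prr$prr) & prr$prr >= config$prr_threshold &
    !is.na(prr$prr_low) & prr$prr_low > config$prr_ci_threshold
  flag_mhra <- gate & chi2 >= config$chi2_threshold
  n_methods <- flag_ror + flag_prr + flag_mhra
  flag_combined <- switch(
    config$combine_rule,
    all = n_methods == 3,
    any = n_methods >= 1,
    majority = n_methods >= 2
  )

  out <- dplyr::bind_cols(tables, ror, prr, tibble::tibble(
    chi2 = chi2, flag_ror = flag_ror, flag_prr = flag_prr,
    flag_mhra = flag_mhra, flag_combined = flag_combined
  ))
  out <- dplyr::arrange(out, dplyr::desc(.data$chi2))
  attr(out, "mining_config") <- config
  out
}

#' Render the flagged-signal table
#'
#' Rows are the DECs passing `flag_combined` (or, with `min_flags`, at
#' least that many individual methods); estimates round to two decimals and
#' rows keep the chi-square-descending order.
#'
#' @param results Tibble from [evaluate_signals()].
#' @param min_flags Optional integer 1--3; when given, overrides the
#'   combined-flag filter.
#' @return A tibble with columns `drug`, `event`, `n_reports`, `ror`,
#'   `ror_ci_low`, `prr`, `prr_ci_low`, `chi2`.
#' @export
signal_report <- function(results, min_flags = NULL) {
  keep <- if (is.null(min_flags)) {
    results$flag_combined
  } else {
    (results$flag_ror + results$flag_prr + results$flag_mhra) >= min_flags
  }
  out <- results[keep, , drop = FALSE]
  tibble::tibble(
    drug = out$drug, event = out$event, n_reports = out$a,
    ror = round_half_up(out$ror, 2), ror_ci_low = round_half_up(out$ror_low, 2),
    prr = round_half_up(out$prr, 2), prr_ci_low = round_half_up(out$prr_low, 2),
    chi2 = round_half_up(out$chi2, 2)
  )
}
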