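# Severity-stratified descriptive tables and the associated 2-group tests.

# Characteristic -> (column, ordered levels, display labels). Boolean
# characteristics list TRUE first, matching the usual exposed-first layout.
strat_characteristics <- list(
  gender = list(col = "gender", levels = c("male", "female")),
  age_group = list(col = "age_group", levels = srs_age_groups),
  disease_types = list(col = "multi_disease", levels = c(FALSE, TRUE),
                       labels = c("single", "multiple")),
  past_adr_history = list(col = "past_adr_history", levels = c("yes", "no")),
  onset_bin = list(col = "onset_bin", levels = srs_onset_bins),
  polypharmacy_ge2 = list(col = "polypharmacy_ge2", levels = c(TRUE, FALSE),
                          labels = c("polypharmacy", "non_polypharmacy")),
  polypharmacy_ge5 = list(col = "polypharmacy_ge5", levels = c(TRUE, FALSE),
                          labels = c("polypharmacy", "non_polypharmacy")),
  route = list(col = "route", levels = srs_routes),
  off_label = list(col = "off_label", levels = c(TRUE, FALSE),
                   labels = c("yes", "no"))
)

#' Characteristics available for severity stratification
#' @return Character vector of characteristic names.
#' @export
stratified_characteristics <- function() names(strat_characteristics)

#' Test-selection rule configuration
#'
#' The Cochran rule: Fisher's exact test when any expected cell of a 2x2 is
#' below `expected_min`, or when more than `max_small_frac` of the expected
#' cells of an r x c table are; Pearson chi-square otherwise.
#'
#' @param expected_min Expected-count threshold (default 5).
#' @param max_small_frac Tolerated fraction of small expected cells in
#'   r x c tables (default 0.2).
#' @return A list with class `test_rule_config`.
#' @export
test_rule_config <- function(expected_min = 5, max_small_frac = 0.2) {
  structure(list(expected_min = expected_min, max_small_frac = max_small_frac),
            class = "test_rule_config")
}

#' Choose between Pearson chi-square and Fisher's exact test
#'
#' @param counts Matrix of non-negative integer counts.
#' @param config A [test_rule_config()].
#' @param override `NULL`, `"pearson_chi2"`, or `"fisher_exact"`; a non-NULL
#'   override wins regardless of expected counts.
#' @return `"pearson_chi2"` or `"fisher_exact"`.
#' @export
choose_test <- function(counts, config = test_rule_config(), override = NULL) {
  if (!is.null(override)) {
    return(match.arg(override, c("pearson_chi2", "fisher_exact")))
  }
  counts <- as.matrix(counts)
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0) || n == 0) return("fisher_exact")
  expected <- outer(rs, cs) / n
  small <- expected < config$expected_min
  is_2x2 <- all(dim(counts) == c(2, 2))
  if ((is_2x2 && any(small)) || (!is_2x2 && mean(small) > config$max_small_frac)) {
    "fisher_exact"
  } else {
    "pearson_chi2"
  }
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' @param counts r x c matrix of non-negative counts; all marginals must be
#'   positive.
#' @return A list (`statistic`, `df`, `p_value`, `method`).
#' @export
#' @examples
#' pearson_chi2(matrix(c(22, 114, 23, 272), nrow = 2))
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in contingency table; use fisher_exact()",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), method = "pearson_chi2")
}

#' Fisher's exact test
#'
#' For 2x2 tables the two-sided p is the exact hypergeometric tail (sum of
#' tables, at the observed margins, whose probability does not exceed the
#' observed table's). For r x c tables the exact Freeman-Halton test is
#' attempted first; if its network evaluation exceeds the workspace budget,
#' a seeded Monte Carlo p with its standard error is reported instead.
#'
#' @param counts Matrix of non-negative integer counts.
#' @param workspace Workspace budget for the exact r x c network algorithm.
#' @param mc_B Number of Monte Carlo resamples for the fallback.
#' @param mc_seed RNG seed for the Monte Carlo fallback.
#' @param monte_carlo Force the seeded Monte Carlo variant instead of the
#'   exact computation.
#' @return A list (`statistic = NA`, `df = NA`, `p_value`, `method`, and
#'   `mc_se` when Monte Carlo was used).
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), nrow = 2))
fisher_exact <- function(counts, workspace = 2e6, mc_B = 1e5,
                         mc_seed = 20211220, monte_carlo = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  exact <- if (monte_carlo) NULL else tryCatch(
    stats::fisher.test(counts, workspace = workspace),
    error = function(e) NULL
  )
  if (!is.null(exact)) {
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = unname(exact$p.value), method = "fisher_exact"))
  }
  mc <- withr::with_seed(
    mc_seed,
    stats::fisher.test(counts, simulate.p.value = TRUE, B = mc_B)
  )
  p <- unname(mc$p.value)
  list(statistic = NA_real_, df = NA_integer_, p_value = p,
       method = "fisher_exact_mc", mc_se = sqrt(p * (1 - p) / mc_B))
}

#' Build a severity-stratified characteristic table
#'
#' Cross-tabulates one characteristic against report severity
#' (serious/normal), computes row percentages (half-up, one decimal), and
#' runs the appropriate independence test. Reports with an unknown or
#' missing category are excluded from that characteristic's table only; the
#' number excluded is recorded. Levels unobserved in the data are dropped
#' before testing.
#'
#' @param coded Coded-report tibble from [code_reports()].
#' @param characteristic One of [stratified_characteristics()].
#' @param test Optional override, see [choose_test()].
#' @param rule_config A [test_rule_config()].
#' @return An object of class `strat_table`.
#' @export
build_stratified_table <- function(coded, characteristic, test = NULL,
                                   rule_config = test_rule_config()) {
  spec <- strat_characteristics[[characteristic]]
  if (is.null(spec)) {
    stop("unknown characteristic: ", characteristic, call. = FALSE)
  }
  values <- coded[[spec$col]]
  severity <- coded$severity
  known <- if (is.logical(values)) !is.na(values) else {
    !is.na(values) & values %in% as.character(spec$levels)
  }
  n_excluded <- sum(!known)
  values <- values[known]; severity <- severity[known]

  labels <- spec$labels %||% as.character(spec$levels)
  counts <- vapply(seq_along(spec$levels), function(i) {
    sel <- values == spec$levels[[i]]
    c(sum(sel & severity == "serious"), sum(sel & severity == "normal"))
  }, numeric(2))
  counts <- t(counts)
  dimnames(counts) <- list(labels, c("serious", "normal"))

  observed <- rowSums(counts) > 0
  counts_t <- counts[observed, , drop = FALSE]

  result <- if (nrow(counts_t) >= 2 && all(colSums(counts_t) > 0)) {
    used <- choose_test(counts_t, rule_config, override = test)
    if (used == "pearson_chi2") pearson_chi2(counts_t) else fisher_exact(counts_t)
  } else {
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
         method = "none")
  }

  row_tot <- rowSums(counts)
  row_percent <- counts / ifelse(row_tot == 0, NA_real_, row_tot) * 100
  row_percent <- round_half_up(row_percent, 1)

  structure(
    list(characteristic = characteristic, row_labels = rownames(counts),
         counts = counts, row_percent = row_percent,
         test_used = result$method, statistic = result$statistic,
         df = result$df, p_value = result$p_value,
         n_excluded_unknown = n_excluded),
    class = "strat_table"
  )
}

#' @export
print.strat_table <- function(x, ...) {
  cat(sprintf("%s  (serious vs normal)\n", x$characteristic))
  for (i in seq_along(x$row_labels)) {
    cat(sprintf("  %-18s %4d (%5.1f)  %4d (%5.1f)\n", x$row_labels[i],
                x$counts[i, 1], x$row_percent[i, 1],
                x$counts[i, 2], x$row_percent[i, 2]))
  }
  if (!is.na(x$p_value)) {
    cat(sprintf("  %s p = %s\n", x$test_used, format_p(x$p_value)))
  }
  invisible(x)
}

#' @export
as.data.frame.strat_table <- function(x, ...) {
  data.frame(
    characteristic = x$characteristic, category = x$row_labels,
    serious = x$counts[, 1], serious_pct = x$row_percent[, 1],
    normal = x$counts[, 2], normal_pct = x$row_percent[, 2],
    test = x$test_used, statistic = x$statistic,
    df = if (is.null(x$df)) NA_integer_ else x$df,
    p_value = x$p_value, p_display = format_p(x$p_value),
    row.names = NULL
  )
}

#' Build all severity-stratified tables
#'
#' @param coded Coded-report tibble.
#' @param overrides Named character vector mapping characteristic names to a
#'   forced test choice.
#' @return Named list of `strat_table` objects.
#' @export
build_all_tables <- function(coded, overrides = NULL) {
  out <- lapply(stratified_characteristics(), function(ch) {
    build_stratified_table(coded, ch, test = unname(overrides[ch]))
  })
  setNames(out, stratified_characteristics())
}

#' Headline summary proportions of a coded corpus
#'
#' All values are percentages: two decimals, except the within-one-week
#' onset share which follows the one-decimal convention of the stratified
#' tables. Rounding is half-up.
#'
#' @param coded Coded-report tibble.
#' @param background_total Optional count of all reports in the source
#'   database against which the corpus share is expressed.
#' @return A list of named percentages, including per-drug and per-ADR
#'   shares of the corpus.
#' @export
summary_proportions <- function(coded, background_total = NULL) {
  n <- nrow(coded)
  pct <- function(k, digits = 2) {
    if (n == 0) return(round_half_up(0, digits))
    round_half_up(100 * k / n, digits)
  }
  within_week <- sum(coded$onset_bin %in% c("on_the_day", "d1_3", "d4_7"),
                     na.rm = TRUE)
  out <- list(
    n = n,
    serious_pct = pct(sum(coded$severity == "serious")),
    past_history_pct = pct(sum(coded$past_adr_history == "yes")),
    off_label_pct = pct(sum(coded$off_label)),
    parenteral_pct = pct(sum(coded$route == "parenteral")),
    onset_within_week_pct = pct(within_week, digits = 1),
    drug_share_pct = if (n > 0) {
      round_half_up(100 * sort(table(coded$primary_drug), decreasing = TRUE) / n, 2)
    } else numeric(0),
    adr_share_pct = if (n > 0) {
      round_half_up(100 * sort(table(coded$primary_adr), decreasing = TRUE) / n, 2)
    } else numeric(0)
  )
  if (!is.null(background_total)) {
    out$corpus_share_pct <- round_half_up(100 * n / background_total, 2)
  }
  out
}

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention of `quantile(type = 7)`
#' (R's default); the convention is fixed so printed summaries are
#' reproducible.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  stopifnot(is.numeric(values), length(values) > 0)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}
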