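# Synthetic spontaneous-report generator.
#
# The generator emulates a pediatric antineoplastic-drug extract of a
# provincial spontaneous reporting system: its default vocabularies and
# marginal probabilities follow the published marginal mix of such a corpus
# (drug and ADR shares, age-group/onset/route/polypharmacy distributions,
# a ~31.5% serious share), and drug-event associations of known strength
# can be injected by multiplying a pair's joint probability. It exists so
# the ingest, descriptive and signal-mining stages can be validated with a
# known ground truth; it does not model reporting dynamics.

#' Default drug vocabulary with marginal probabilities
#'
#' Ten antineoplastic agents with marginals proportional to the drug mix of
#' a pediatric oncology SRS extract (cytarabine most frequent).
#'
#' @return A tibble with columns `name`, `prob` (summing to 1).
#' @export
default_drug_vocab <- function() {
  counts <- c(
    cytarabine = 113, asparaginase = 55, methotrexate = 49,
    pegaspargase = 37, cyclophosphamide = 30, etoposide = 22,
    vincristine = 17, cisplatin = 12, daunorubicin = 11, doxorubicin = 9
  )
  tibble::tibble(name = names(counts), prob = unname(counts) / sum(counts))
}

#' Default ADR vocabulary with marginal probabilities and SOC
#'
#' Twenty ADR terms (myelosuppression, rash, vomiting, ... ) with marginals
#' proportional to a pediatric oncology ADR mix, each carrying its
#' system organ class from [default_soc_map()].
#'
#' @return A tibble with columns `term`, `prob` (summing to 1), `soc`.
#' @export
default_event_vocab <- function() {
  counts <- c(
    myelosuppression = 67, rash = 60, vomiting = 51, fever = 37,
    nausea = 26, `gastrointestinal reaction` = 20,
    `fibrinogen decreased` = 12, `leukocyte count decreased` = 10,
    dyspnea = 9, `hepatic failure` = 9, diarrhea = 8, alopecia = 6,
    `mucositis oral` = 6, itch = 5, anemia = 5, thrombocytopenia = 5,
    cyanosis = 4, chills = 4, phlebitis = 4, `drug eruption` = 3
  )
  soc <- default_soc_map()
  tibble::tibble(
    term = names(counts), prob = unname(counts) / sum(counts),
    soc = soc$soc[match(names(counts), soc$term)]
  )
}

#' Default logistic severity model
#'
#' Log-odds of a serious report given its covariates. The coefficients
#' reflect the direction and rough size of the severity associations seen
#' in pediatric oncology SRS data (past ADR history, polypharmacy, and
#' late onset each raise the odds); the intercept is calibrated so the
#' marginal serious share under the default demographics is about 31.5%.
#'
#' @return A named list: `intercept`, `past_adr_history`,
#'   `polypharmacy_ge2`, `polypharmacy_ge5`, `onset_ge8`.
#' @export
default_severity_model <- function() {
  list(intercept = -1.69, past_adr_history = 0.85, polypharmacy_ge2 = 0.80,
       polypharmacy_ge5 = 0.75, onset_ge8 = 1.40)
}

#' Default demographic and report-structure distributions
#'
#' Marginals follow the published mix of a pediatric antineoplastic SRS
#' extract: age groups peaking at 1-3 years, ~62% male, ~10% past ADR
#' history, ~6% multi-disease, ~94% parenteral, ~7% off-label, onset
#' concentrated within one week, and a medication-count distribution
#' giving ~49% polypharmacy (>=2) and ~7% at the conservative >=5
#' threshold.
#'
#' @return A named list of probability vectors.
#' @export
default_demographics <- function() {
  list(
    age_group_probs = c(`1-3` = 130, `4-6` = 103, `7-11` = 101,
                        `12-14` = 61, `15-17` = 36) / 431,
    gender_probs = c(male = 267, female = 164) / 431,
    past_history_prob = 45 / 431,
    multi_disease_prob = 25 / 431,
    off_label_prob = 32 / 431,
    route_probs = c(parenteral = 406, oral = 10, other = 15) / 431,
    onset_bin_probs = setNames(c(128, 140, 76, 66, 14, 7) / 431,
                               srs_onset_bins),
    drug_count_probs = setNames(
      c(218 / 431, rep((181 / 431) / 3, 3), rep((32 / 431) / 4, 4)),
      as.character(1:8)
    ),
    year_range = c(2016L, 2020L),
    causality_probs = c(certain = 0.1, probable = 0.3, possible = 0.6),
    criteria_probs = c(
      death = 0.01, life_threatening = 0.09,
      carcinogenesis_teratogenesis_birth_defect = 0.01, disability = 0.04,
      hospitalization_or_prolongation = 0.60,
      other_important_medical_event = 0.25
    )
  )
}

#' Simulation configuration for synthetic report corpora
#'
#' @param n_reports Number of reports to generate (> 0).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration and this seed.
#' @param drug_vocab Tibble (`name`, `prob`); probabilities must be in
#'   `[0, 1]` and sum to at most 1 (they are renormalized).
#' @param event_vocab Tibble (`term`, `prob`, `soc`).
#' @param injected_signals `NULL` or a tibble (`drug`, `event`,
#'   `multiplier`) with multipliers strictly greater than 1; each listed
#'   pair's joint probability is multiplied and the event distribution
#'   renormalized within the drug.
#' @param severity_model Named list as in [default_severity_model()]; set
#'   the coefficients to 0 for an intercept-only model.
#' @param demographics Named list as in [default_demographics()].
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_reports = 431, seed = 20211220,
                       drug_vocab = default_drug_vocab(),
                       event_vocab = default_event_vocab(),
                       injected_signals = NULL,
                       severity_model = default_severity_model(),
                       demographics = default_demographics()) {
  cfg <- structure(
    list(n_reports = as.integer(n_reports), seed = as.integer(seed),
         drug_vocab = drug_vocab, event_vocab = event_vocab,
         injected_signals = injected_signals,
         severity_model = severity_model, demographics = demographics),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_reports) || cfg$n_reports <= 0) {
    stop("n_reports must be a positive integer", call. = FALSE)
  }
  for (v in list(cfg$drug_vocab$prob, cfg$event_vocab$prob)) {
    if (any(v < 0 | v > 1) || sum(v) > 1 + 1e-8) {
      stop("vocabulary probabilities must lie in [0, 1] and sum to <= 1",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$injected_signals) && nrow(cfg$injected_signals) > 0) {
    inj <- cfg$injected_signals
    if (any(inj$multiplier <= 1)) {
      stop("injected-signal multipliers must be > 1", call. = FALSE)
    }
    if (!all(inj$drug %in% cfg$drug_vocab$name)) {
      stop("injected signal names an unknown drug", call. = FALSE)
    }
    if (!all(inj$event %in% cfg$event_vocab$term)) {
      stop("injected signal names an unknown event", call. = FALSE)
    }
  }
  dg <- cfg$demographics
  probs <- c(dg$age_group_probs, dg$gender_probs, dg$past_history_prob,
             dg$multi_disease_prob, dg$off_label_prob, dg$route_probs,
             dg$onset_bin_probs, dg$drug_count_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("demographic probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @param path Path to a YAML file; scalar fields map directly, vocabularies
#'   as lists of records.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_reports)) args$n_reports <- y$n_reports
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$drug_vocab)) {
    args$drug_vocab <- dplyr::bind_rows(lapply(y$drug_vocab, tibble::as_tibble))
  }
  if (!is.null(y$event_vocab)) {
    args$event_vocab <- dplyr::bind_rows(lapply(y$event_vocab, tibble::as_tibble))
  }
  if (!is.null(y$injected_signals)) {
    args$injected_signals <- dplyr::bind_rows(
      lapply(y$injected_signals, tibble::as_tibble))
  }
  if (!is.null(y$severity_model)) {
    args$severity_model <- modifyList(default_severity_model(), y$severity_model)
  }
  if (!is.null(y$demographics)) {
    dg <- default_demographics()
    for (nm in names(y$demographics)) {
      v <- y$demographics[[nm]]
      dg[[nm]] <- if (is.list(v)) unlist(v) else v
    }
    args$demographics <- dg
  }
  do.call(sim_config, args)
}

# Per-drug conditional event distribution: the event marginal re-weighted
# by the multiplier for injected pairs, renormalized within the drug.
conditional_event_matrix <- function(cfg) {
  nd <- nrow(cfg$drug_vocab); ne <- nrow(cfg$event_vocab)
  w <- matrix(rep(cfg$event_vocab$prob, each = nd), nrow = nd,
              dimnames = list(cfg$drug_vocab$name, cfg$event_vocab$term))
  if (!is.null(cfg$injected_signals)) {
    for (i in seq_len(nrow(cfg$injected_signals))) {
      inj <- cfg$injected_signals[i, ]
      w[inj$drug, inj$event] <- w[inj$drug, inj$event] * inj$multiplier
    }
  }
  w / rowSums(w)
}

#' Implied drug-event cell probabilities and reporting odds ratios
#'
#' The generator's analytical ground truth: for each injected pair, the
#' true 2x2 cell probabilities under the configured sampling scheme and
#' the reporting odds ratio they imply.
#'
#' @param config A [sim_config()] with at least one injected signal.
#' @return A tibble with columns `drug`, `event`, `multiplier`, `p_a`,
#'   `p_b`, `p_c`, `p_d`, `true_ror`.
#' @export
true_dec_stats <- function(config) {
  stopifnot(!is.null(config$injected_signals),
            nrow(config$injected_signals) > 0)
  q <- conditional_event_matrix(config)
  p_drug <- config$drug_vocab$prob / sum(config$drug_vocab$prob)
  joint <- q * p_drug                       # rows scaled by drug marginal
  p_event <- colSums(joint)
  purrr::pmap_dfr(config$injected_signals, function(drug, event, multiplier) {
    pa <- unname(joint[drug, event])
    pb <- unname(p_event[event]) - pa
    pc <- sum(joint[drug, ]) - pa
    pd <- 1 - pa - pb - pc
    tibble::tibble(drug = drug, event = event, multiplier = multiplier,
                   p_a = pa, p_b = pb, p_c = pc, p_d = pd,
                   true_ror = pa * pd / (pb * pc))
  })
}

#' Generate a synthetic report corpus
#'
#' Draws `n_reports` individual case safety reports: drug from its
#' marginal, event from the drug-conditional distribution (injected pairs
#' up-weighted), demographics and report structure from the configured
#' distributions, and severity from the logistic model on past history,
#' polypharmacy and late onset. Fields are sampled in a fixed order from a
#' single seed, so the same configuration and seed reproduce the corpus
#' exactly, and every generated report passes the default inclusion
#' filters by construction (use [corrupt_corpus()] to plant defects).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with elements `reports` (report tibble in the
#'   [parse_reports()] schema) and `truth` (injected pairs, per-report
#'   latent severity probability, seed used).
#' @export
generate_corpus <- function(config, seed = NULL) {
  validate_sim_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  n <- config$n_reports
  dg <- config$demographics

  withr::with_seed(seed, {
    drug_idx <- sample.int(nrow(config$drug_vocab), n, replace = TRUE,
                           prob = config$drug_vocab$prob)
    q <- conditional_event_matrix(config)
    event_idx <- integer(n)
    for (di in sort(unique(drug_idx))) {      # fixed drug order: deterministic
      sel <- which(drug_idx == di)
      event_idx[sel] <- sample.int(ncol(q), length(sel), replace = TRUE,
                                   prob = q[di, ])
    }

    age_bounds <- list(`1-3` = c(1, 3), `4-6` = c(4, 6), `7-11` = c(7, 11),
                       `12-14` = c(12, 14), `15-17` = c(15, 17))
    ag <- sample(names(dg$age_group_probs), n, replace = TRUE,
                 prob = dg$age_group_probs)
    age <- vapply(ag, function(g) {
      b <- age_bounds[[g]]
      sample(b[1]:b[2], 1)
    }, numeric(1))

    gender <- sample(names(dg$gender_probs), n, replace = TRUE,
                     prob = dg$gender_probs)
    past <- ifelse(runif(n) < dg$past_history_prob, "yes", "no")
    multi <- runif(n) < dg$multi_disease_prob
    disease_count <- ifelse(multi, sample(2:3, n, replace = TRUE), 1L)

    bin_days <- list(on_the_day = 0L, d1_3 = 1:3, d4_7 = 4:7, d8_14 = 8:14,
                     d15_30 = 15:30, over_month = 31:60)
    ob <- sample(srs_onset_bins, n, replace = TRUE, prob = dg$onset_bin_probs)
    lag <- vapply(ob, function(b) {
      days <- bin_days[[b]]
      if (length(days) == 1) days else sample(days, 1)
    }, integer(1))

    n_drugs <- as.integer(sample(names(dg$drug_count_probs), n, replace = TRUE,
                                 prob = dg$drug_count_probs))
    route <- sample(names(dg$route_probs), n, replace = TRUE,
                    prob = dg$route_probs)
    off_label <- runif(n) < dg$off_label_prob

    sm <- config$severity_model
    eta <- sm$intercept +
      sm$past_adr_history * (past == "yes") +
      sm$polypharmacy_ge2 * (n_drugs >= 2) +
      sm$polypharmacy_ge5 * (n_drugs >= 5) +
      sm$onset_ge8 * (lag >= 8)
    p_serious <- plogis(eta)
    serious <- runif(n) < p_serious
    criteria <- lapply(serious, function(s) {
      if (!s) character(0)
      else sample(names(dg$criteria_probs), 1, prob = dg$criteria_probs)
    })

    year <- sample(dg$year_range[1]:dg$year_range[2], n, replace = TRUE)
    causality <- sample(names(dg$causality_probs), n, replace = TRUE,
                        prob = dg$causality_probs)
  })

  drug <- config$drug_vocab$name[drug_idx]
  atc <- sprintf("L01X%02d", drug_idx)
  event <- config$event_vocab$term[event_idx]

  reports <- tibble::tibble(
    report_id = sprintf("R%06d", seq_len(n)),
    report_year = as.integer(year),
    age_years = as.integer(age),
    gender = gender,
    causality = causality,
    suspected_drugs = as.list(drug),
    atc_codes = as.list(atc),
    concomitant_drug_count = n_drugs,
    adr_terms = as.list(event),
    adr_serious = as.list(serious),
    seriousness_criteria = criteria,
    disease_count = as.integer(disease_count),
    past_adr_history = past,
    onset_lag_days = as.integer(lag),
    route = route,
    off_label = off_label,
    parse_failure = rep(FALSE, n)
  )
  truth <- list(
    injected = config$injected_signals %||%
      tibble::tibble(drug = character(), event = character(),
                     multiplier = numeric()),
    severity_prob = p_serious,
    seed = seed
  )
  list(reports = reports, truth = truth)
}

#' Corruption rates for planting filterable defects
#'
#' @param duplicate,bad_year,bad_causality,overage,negative_lag,blank_drug
#'   Rates in `[0, 1]`; each planted count is `round(rate * n)`.
#' @return A named list with class `corruption_rates`.
#' @export
corruption_rates <- function(duplicate = 0, bad_year = 0, bad_causality = 0,
                             overage = 0, negative_lag = 0, blank_drug = 0) {
  rates <- list(duplicate = duplicate, bad_year = bad_year,
                bad_causality = bad_causality, overage = overage,
                negative_lag = negative_lag, blank_drug = blank_drug)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop("corruption rates must lie in [0, 1]", call. = FALSE)
  }
  structure(rates, class = "corruption_rates")
}

# Which filter-audit rule catches each planted defect type.
corruption_rule_map <- c(
  duplicate = "duplicate", bad_year = "year_window",
  bad_causality = "causality", overage = "age_window",
  negative_lag = "negative_onset", blank_drug = "missing_critical"
)

#' Plant known defects into a clean corpus
#'
#' Modifies disjoint sets of reports so that each planted defect is removed
#' by exactly one filter rule, and appends duplicate copies (same
#' `report_id`) for the duplicate rate. The returned ledger of planted
#' counts is exactly recoverable from the [apply_inclusion_filters()]
#' audit.
#'
#' @param reports Clean report tibble.
#' @param rates A [corruption_rates()].
#' @param seed Integer seed for victim selection.
#' @return A list with elements `reports` (corrupted corpus) and `ledger`
#'   (named integer vector of planted counts).
#' @export
corrupt_corpus <- function(reports, rates = corruption_rates(), seed = 1) {
  n <- nrow(reports)
  counts <- vapply(rates, function(r) as.integer(round(r * n)), integer(1))
  modify_types <- c("bad_year", "bad_causality", "overage", "negative_lag",
                    "blank_drug")
  if (sum(counts[modify_types]) + counts[["duplicate"]] > n) {
    stop("corruption rates too high for corpus size", call. = FALSE)
  }
  out <- reports
  withr::with_seed(seed, {
    pool <- sample.int(n)                   # victims drawn without overlap
    take <- function(k) {
      if (k == 0) return(integer(0))
      idx <- head(pool, k)
      pool <<- pool[-seq_len(length(idx))]
      idx
    }
    idx_year <- take(counts[["bad_year"]])
    idx_caus <- take(counts[["bad_causality"]])
    idx_age <- take(counts[["overage"]])
    idx_lag <- take(counts[["negative_lag"]])
    idx_drug <- take(counts[["blank_drug"]])
    idx_dup <- take(counts[["duplicate"]])
  })
  out$report_year[idx_year] <- 2013L
  out$causality[idx_caus] <- "unlikely"
  out$age_years[idx_age] <- 130L
  out$onset_lag_days[idx_lag] <- -3L
  out$suspected_drugs[idx_drug] <- list(character(0))
  if (length(idx_dup) > 0) {
    out <- dplyr::bind_rows(out, reports[idx_dup, , drop = FALSE])
  }
  list(reports = out, ledger = counts)
}

#' Signal-recovery simulation experiment
#'
#' Per replicate: generate a corpus, run it through filtering and coding,
#' mine signals, and score recovery of the injected pairs. Reported per
#' replicate: sensitivity (share of injected pairs with the combined
#' flag), false-flag count (combined flags on non-injected pairs), and the
#' mean estimated ROR over injected pairs; the analytical true ROR is
#' attached for comparison.
#'
#' @param config A [sim_config()] with at least one injected signal.
#' @param n_replicates Number of simulated corpora.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @param mining A [mining_config()].
#' @return A tibble with one row per replicate (`replicate`, `sensitivity`,
#'   `false_flags`, `mean_ror`); true RORs are in the `"true_dec"`
#'   attribute and mean +/- sd summaries in the `"summary"` attribute.
#' @export
recovery_experiment <- function(config, n_replicates = 100, seed = 1,
                                mining = mining_config()) {
  stopifnot(!is.null(config$injected_signals),
            nrow(config$injected_signals) > 0)
  inj <- config$injected_signals
  rows <- lapply(seq_len(n_replicates), function(i) {
    gen <- generate_corpus(config, seed = seed + i - 1L)
    kept <- apply_inclusion_filters(gen$reports)$reports
    coded <- code_reports(kept)
    res <- evaluate_signals(build_dec_tables(coded), mining)
    is_inj <- paste(res$drug, res$event) %in% paste(inj$drug, inj$event)
    hit <- res$flag_combined[is_inj]
    tibble::tibble(
      replicate = i,
      sensitivity = sum(hit) / nrow(inj),
      false_flags = sum(res$flag_combined & !is_inj),
      mean_ror = mean(res$ror[is_inj], na.rm = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "true_dec") <- true_dec_stats(config)
  attr(out, "summary") <- list(
    sensitivity = c(mean = mean(out$sensitivity), sd = stats::sd(out$sensitivity)),
    false_flags = c(mean = mean(out$false_flags), sd = stats::sd(out$false_flags)),
    seed = seed
  )
  out
}

#' Confidence-interval coverage experiment for the ROR
#'
#' Simulates corpora in which every report falls into one cell of a single
#' drug-event 2x2 table with fixed cell probabilities (a multinomial draw,
#' which is the distribution the one-pair-per-report sampling scheme
#' induces), computes the 95% ROR interval for each corpus, and reports
#' how often it covers the true odds ratio.
#'
#' @param n_corpora Number of simulated corpora.
#' @param n_reports Reports per corpus.
#' @param cell_probs Probabilities of cells (a, b, c, d); choose them so
#'   expected counts are at least 5.
#' @param seed Integer seed.
#' @param config A [mining_config()] (supplies `z`).
#' @return A list: `coverage` (proportion in `[0, 1]`), `true_or`,
#'   `n_corpora`, `n_reports`.
#' @export
ror_coverage_experiment <- function(n_corpora = 2000, n_reports = 500,
                                    cell_probs = c(0.04, 0.06, 0.10, 0.80),
                                    seed = 1, config = mining_config()) {
  stopifnot(length(cell_probs) == 4, abs(sum(cell_probs) - 1) < 1e-8,
            all(n_reports * cell_probs >= 5))
  true_or <- cell_probs[1] * cell_probs[4] / (cell_probs[2] * cell_probs[3])
  draws <- withr::with_seed(
    seed, rmultinom(n_corpora, size = n_reports, prob = cell_probs)
  )
  ci <- ror_with_ci(draws[1, ], draws[2, ], draws[3, ], draws[4, ], config)
  covered <- !is.na(ci$ror_low) & ci$ror_low <= true_or & true_or <= ci$ror_high
  list(coverage = mean(covered), true_or = true_or,
       n_corpora = n_corpora, n_reports = n_reports)
}
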