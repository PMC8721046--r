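# Ingestion and coding of individual case safety reports (ICSRs).
#
# A report corpus is a tibble with one row per report. Multi-valued fields
# (suspected drugs, ATC codes, ADR terms and their per-term serious flags,
# seriousness criteria) are list-columns in memory and "|"-delimited cells
# on disk.

report_multi_columns <- c(
  "suspected_drugs", "atc_codes", "adr_terms", "adr_serious",
  "seriousness_criteria"
)

report_required_columns <- c(
  "report_id", "report_year", "age_years", "gender", "causality",
  "suspected_drugs", "atc_codes", "concomitant_drug_count", "adr_terms",
  "adr_serious", "seriousness_criteria", "disease_count",
  "past_adr_history", "onset_lag_days", "route", "off_label"
)

#' CSV dialect for report tables
#'
#' @param delim Field delimiter of the CSV file.
#' @param multi_delim Delimiter used inside multi-valued cells.
#' @return A list with class `srs_dialect`.
#' @export
report_dialect <- function(delim = ",", multi_delim = "|") {
  structure(list(delim = delim, multi_delim = multi_delim),
            class = "srs_dialect")
}

split_multi <- function(x, delim) {
  out <- strsplit(ifelse(is.na(x), "", x), delim, fixed = TRUE)
  lapply(out, function(v) {
    v <- stringr::str_squish(v)
    v[nzchar(v)]
  })
}

join_multi <- function(x, delim) {
  vapply(x, function(v) paste(as.character(v), collapse = delim), character(1))
}

parse_int_field <- function(x) {
  suppressWarnings(as.integer(stringr::str_squish(x)))
}

normalize_enum <- function(x, levels, field, fallback = "unknown") {
  v <- tolower(stringr::str_squish(ifelse(is.na(x), "", x)))
  bad <- !(v %in% levels)
  if (any(bad)) {
    warning(sprintf(
      "%d value(s) of '%s' outside {%s}; mapped to '%s'",
      sum(bad), field, paste(levels, collapse = ", "), fallback
    ), call. = FALSE)
    v[bad] <- fallback
  }
  v
}

parse_logical_field <- function(x) {
  v <- tolower(stringr::str_squish(ifelse(is.na(x), "", x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  out
}

#' Parse a raw report CSV into a report tibble
#'
#' Reads a UTF-8 CSV with one row per spontaneous report. Multi-valued cells
#' are split on the dialect's internal delimiter. Values of enumerated fields
#' outside their vocabulary are mapped to `"unknown"` (or `"other"` for
#' route, which has no unknown level) with a warning. Numeric fields that do
#' not parse leave `NA` and set the `parse_failure` flag so the filter stage
#' can exclude the record; they never crash the parser.
#'
#' @param path Path to the CSV file.
#' @param dialect A [report_dialect()].
#' @return A tibble with the report schema and a logical `parse_failure`
#'   column.
#' @export
parse_reports <- function(path, dialect = report_dialect()) {
  if (!file.exists(path)) stop("report file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = dialect$delim, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(report_required_columns, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_reports())

  md <- dialect$multi_delim
  year <- parse_int_field(raw$report_year)
  age <- parse_int_field(raw$age_years)
  lag <- parse_int_field(raw$onset_lag_days)
  n_con <- parse_int_field(raw$concomitant_drug_count)
  n_dis <- parse_int_field(raw$disease_count)

  adr_terms <- split_multi(raw$adr_terms, md)
  adr_serious_raw <- split_multi(raw$adr_serious, md)
  adr_serious <- purrr::map2(adr_serious_raw, adr_terms, function(s, t) {
    flags <- !is.na(parse_logical_field(s)) & parse_logical_field(s)
    length(flags) <- length(t)        # pad with NA, then default FALSE
    flags[is.na(flags)] <- FALSE
    flags
  })

  criteria <- split_multi(raw$seriousness_criteria, md)
  criteria <- lapply(criteria, function(v) {
    v <- tolower(v)
    intersect(v, srs_seriousness_criteria)
  })

  tibble::tibble(
    report_id = as.character(raw$report_id),
    report_year = year,
    age_years = age,
    gender = normalize_enum(raw$gender, srs_genders, "gender"),
    causality = normalize_enum(raw$causality, srs_causality_levels, "causality"),
    suspected_drugs = split_multi(raw$suspected_drugs, md),
    atc_codes = split_multi(raw$atc_codes, md),
    concomitant_drug_count = n_con,
    adr_terms = adr_terms,
    adr_serious = adr_serious,
    seriousness_criteria = criteria,
    disease_count = n_dis,
    past_adr_history = normalize_enum(raw$past_adr_history,
                                      srs_yes_no_unknown, "past_adr_history"),
    onset_lag_days = lag,
    route = normalize_enum(raw$route, srs_routes, "route", fallback = "other"),
    off_label = {
      ol <- parse_logical_field(raw$off_label)
      ol[is.na(ol)] <- FALSE
      ol
    },
    parse_failure = is.na(year) | is.na(age) | is.na(lag) |
      is.na(n_con) | is.na(n_dis)
  )
}

empty_reports <- function() {
  tibble::tibble(
    report_id = character(), report_year = integer(), age_years = integer(),
    gender = character(), causality = character(),
    suspected_drugs = list(), atc_codes = list(),
    concomitant_drug_count = integer(), adr_terms = list(),
    adr_serious = list(), seriousness_criteria = list(),
    disease_count = integer(), past_adr_history = character(),
    onset_lag_days = integer(), route = character(), off_label = logical(),
    parse_failure = logical()
  )
}

#' Write a report tibble to CSV
#'
#' Inverse of [parse_reports()]: list-columns are joined with the dialect's
#' internal delimiter; per-term serious flags serialize as 0/1.
#'
#' @param reports Report tibble.
#' @param path Output path.
#' @param dialect A [report_dialect()].
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, dialect = report_dialect()) {
  md <- dialect$multi_delim
  flat <- reports
  flat$suspected_drugs <- join_multi(reports$suspected_drugs, md)
  flat$atc_codes <- join_multi(reports$atc_codes, md)
  flat$adr_terms <- join_multi(reports$adr_terms, md)
  flat$adr_serious <- join_multi(lapply(reports$adr_serious, as.integer), md)
  flat$seriousness_criteria <- join_multi(reports$seriousness_criteria, md)
  flat$parse_failure <- NULL
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' Inclusion/exclusion filter configuration
#'
#' Defaults encode a pediatric antineoplastic-drug extract: reports from
#' 2016--2020, causality assessed as certain/probable/possible, at least one
#' suspected drug in ATC class L01 (antineoplastic agents), age 0--17 years,
#' non-negative onset lag, critical fields present, no duplicates.
#'
#' @param year_min,year_max Reporting-year window (inclusive).
#' @param causality_whitelist Causality categories retained.
#' @param age_min,age_max Age window in years (inclusive).
#' @param atc_prefix ATC code prefix a suspected drug must carry.
#' @param max_plausible_age Ages above this are treated as data errors.
#' @param dedup_key Character vector of fields defining a duplicate
#'   (default: `report_id`).
#' @return A list with class `filter_config`.
#' @export
filter_config <- function(year_min = 2016, year_max = 2020,
                          causality_whitelist = c("certain", "probable", "possible"),
                          age_min = 0, age_max = 17,
                          atc_prefix = "L01",
                          max_plausible_age = 120,
                          dedup_key = "report_id") {
  stopifnot(year_min <= year_max, age_min <= age_max)
  structure(
    list(year_min = as.integer(year_min), year_max = as.integer(year_max),
         causality_whitelist = causality_whitelist,
         age_min = as.integer(age_min), age_max = as.integer(age_max),
         atc_prefix = atc_prefix,
         max_plausible_age = as.integer(max_plausible_age),
         dedup_key = dedup_key),
    class = "filter_config"
  )
}

#' @rdname filter_config
#' @param path Path to a YAML file whose keys match the arguments above.
#' @export
filter_config_from_yaml <- function(path) {
  do.call(filter_config, yaml::read_yaml(path))
}

# Filter rules, applied in order; each rejected record is attributed to the
# first rule that rejects it, so the audit is deterministic.
filter_rule_names <- c(
  "missing_critical", "unparseable", "year_window", "causality",
  "atc_class", "age_window", "implausible_age", "negative_onset", "duplicate"
)

#' Apply inclusion/exclusion filters with an audit trail
#'
#' Filtering never errors: every rejected report is counted under the first
#' rule (in the fixed order missing-critical fields, unparseable numerics,
#' reporting-year window, causality whitelist, ATC class, age window,
#' implausible age, negative onset lag, duplicate) that rejects it, and the
#' audit satisfies `n_in = n_out + sum(removed)`. The operation is
#' idempotent.
#'
#' @param reports Report tibble from [parse_reports()] or
#'   [generate_corpus()].
#' @param config A [filter_config()].
#' @return A list with elements `reports` (survivors, input order preserved)
#'   and `audit` (class `filter_audit`: `n_in`, `n_out`, named `removed`
#'   counts).
#' @export
apply_inclusion_filters <- function(reports, config = filter_config()) {
  n_in <- nrow(reports)
  pf <- if ("parse_failure" %in% names(reports)) reports$parse_failure
        else rep(FALSE, n_in)

  has_drug <- vapply(reports$suspected_drugs, function(v) length(v) > 0, logical(1))
  has_adr <- vapply(reports$adr_terms, function(v) length(v) > 0, logical(1))
  has_atc <- vapply(reports$atc_codes, function(v) {
    any(startsWith(v, config$atc_prefix))
  }, logical(1))

  fail <- list(
    missing_critical = !has_drug | !has_adr | is.na(reports$report_id) |
      !nzchar(reports$report_id),
    unparseable = pf | is.na(reports$report_year) | is.na(reports$age_years) |
      is.na(reports$onset_lag_days),
    year_window = reports$report_year < config$year_min |
      reports$report_year > config$year_max,
    causality = !(reports$causality %in% config$causality_whitelist),
    atc_class = !has_atc,
    age_window = reports$age_years < config$age_min |
      reports$age_years > config$age_max,
    implausible_age = reports$age_years > config$max_plausible_age,
    negative_onset = reports$onset_lag_days < 0
  )

  rejected_by <- rep(NA_character_, n_in)
  for (rule in names(fail)) {
    hit <- is.na(rejected_by) & !is.na(fail[[rule]]) & fail[[rule]]
    rejected_by[hit] <- rule
  }

  # duplicates among otherwise-surviving reports, first occurrence kept
  keep <- is.na(rejected_by)
  if (any(keep)) {
    key <- dedup_key_string(reports[keep, , drop = FALSE], config$dedup_key)
    dup <- duplicated(key)
    rejected_by[which(keep)[dup]] <- "duplicate"
  }

  removed <- vapply(filter_rule_names, function(r) sum(rejected_by == r, na.rm = TRUE),
                    integer(1))
  out <- reports[is.na(rejected_by), , drop = FALSE]
  audit <- structure(
    list(n_in = n_in, n_out = nrow(out), removed = removed),
    class = "filter_audit"
  )
  list(reports = out, audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filter audit:", x$n_in, "in,", x$n_out, "out\n")
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  %-17s %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

dedup_key_string <- function(reports, key_fields) {
  missing <- setdiff(key_fields, names(reports))
  if (length(missing) > 0) {
    stop("unknown dedup key field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(key_fields, function(f) {
    col <- reports[[f]]
    if (is.list(col)) join_multi(col, "|") else as.character(col)
  })
  do.call(paste, c(cols, sep = "\r"))
}

#' Drop duplicate reports
#'
#' Keeps the first occurrence (in input order) of each distinct key; later
#' records with an identical key are dropped regardless of their other
#' fields.
#'
#' @param reports Report tibble.
#' @param key_fields Fields whose combination defines a duplicate.
#' @return The de-duplicated report tibble.
#' @export
deduplicate <- function(reports, key_fields = "report_id") {
  if (length(key_fields) == 0) stop("key_fields must be non-empty", call. = FALSE)
  key <- dedup_key_string(reports, key_fields)
  reports[!duplicated(key), , drop = FALSE]
}

#' Select the primary adverse reaction of a report
#'
#' A report may list several reactions but contributes a single
#' (drug, event) pair to the analysis. The default policy ranks any
#' serious-flagged term above non-serious terms and breaks ties by listing
#' order.
#'
#' @param terms Character vector of ADR terms (non-empty).
#' @param serious_flags Logical vector aligned to `terms`.
#' @param policy `"serious_first"` (default) or `"first_listed"`.
#' @return A list with elements `term` and `serious`.
#' @export
select_primary_adr <- function(terms, serious_flags,
                               policy = c("serious_first", "first_listed")) {
  policy <- match.arg(policy)
  if (length(terms) == 0) {
    stop("report has no ADR terms; such records should have been filtered",
         call. = FALSE)
  }
  serious_flags <- as.logical(serious_flags)
  idx <- if (policy == "serious_first" && any(serious_flags)) {
    which(serious_flags)[1]
  } else {
    1L
  }
  list(term = terms[idx], serious = serious_flags[idx])
}

#' Normalize drug names to generic names
#'
#' Lookup is case- and whitespace-insensitive. Unmapped names fall through
#' as their lower-cased, trimmed form with one summary warning; dropping
#' records is the filter stage's job, not the coder's.
#'
#' @param raw_names Character vector of raw drug names.
#' @param dictionary A two-column data frame (`raw`, `generic`), a named
#'   character vector (names = raw), or `NULL` for the identity mapping.
#' @return Character vector of generic names.
#' @export
normalize_drug_name <- function(raw_names, dictionary = NULL) {
  key <- tolower(stringr::str_squish(raw_names))
  if (is.null(dictionary)) return(key)
  if (is.data.frame(dictionary)) {
    map <- setNames(as.character(dictionary$generic),
                    tolower(stringr::str_squish(dictionary$raw)))
  } else {
    map <- setNames(as.character(dictionary),
                    tolower(stringr::str_squish(names(dictionary))))
  }
  out <- unname(map[key])
  miss <- is.na(out)
  if (any(miss)) {
    warning(sprintf("%d drug name(s) not in dictionary, kept as-is: %s",
                    sum(miss),
                    paste(unique(key[miss]), collapse = ", ")),
            call. = FALSE)
    out[miss] <- key[miss]
  }
  out
}

#' Map an ADR term to its system organ class
#'
#' A simplified surrogate for the MedDRA system-organ-class level: the map
#' is user-supplied; unmapped terms go to `"Unclassified"` with a warning.
#'
#' @param terms Character vector of ADR terms.
#' @param soc_map A two-column data frame (`term`, `soc`) or a named
#'   character vector (names = term).
#' @return Character vector of SOC names.
#' @export
map_event_to_soc <- function(terms, soc_map = default_soc_map()) {
  key <- tolower(stringr::str_squish(terms))
  if (is.data.frame(soc_map)) {
    map <- setNames(as.character(soc_map$soc),
                    tolower(stringr::str_squish(soc_map$term)))
  } else {
    map <- setNames(as.character(soc_map),
                    tolower(stringr::str_squish(names(soc_map))))
  }
  out <- unname(map[key])
  miss <- is.na(out)
  if (any(miss)) {
    warning(sprintf("%d ADR term(s) without SOC mapping set to 'Unclassified': %s",
                    sum(miss), paste(unique(key[miss]), collapse = ", ")),
            call. = FALSE)
    out[miss] <- "Unclassified"
  }
  out
}

#' Classify report severity from regulatory seriousness criteria
#'
#' A report is serious if and only if at least one of the six regulatory
#' criteria (death; life-threatening; carcinogenesis, teratogenesis or
#' birth defect; disability; hospitalization or its prolongation; other
#' important medical event) applies. Adding a criterion can therefore never
#' turn a serious report normal.
#'
#' @param criteria A character vector of criteria, or a list of such
#'   vectors (one element per report).
#' @return `"serious"` or `"normal"`, vectorized over a list input.
#' @export
classify_severity <- function(criteria) {
  if (!is.list(criteria)) criteria <- list(criteria)
  vapply(criteria, function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    if (length(v) > 0) "serious" else "normal"
  }, character(1))
}

#' Derive analysis bins from raw report fields
#'
#' Age groups 1--3, 4--6, 7--11, 12--14, 15--17 (inclusive); onset bins
#' same-day, 1--3, 4--7, 8--14, 15--30, over a month; polypharmacy flags at
#' the two-medication and five-medication thresholds; multi-disease at two
#' or more diagnoses. Age 0 falls inside the inclusion window but has no
#' age bin: such reports keep `NA` (with a warning) and stay in the corpus
#' for totals.
#'
#' @param age_years Integer vector, ages in years.
#' @param onset_lag_days Integer vector, days from administration to ADR
#'   (0 = same day).
#' @param concomitant_drug_count Integer vector, total medications on the
#'   report.
#' @param disease_count Integer vector, diagnoses before the ADR.
#' @return A tibble with columns `age_group`, `onset_bin`,
#'   `polypharmacy_ge2`, `polypharmacy_ge5`, `multi_disease`.
#' @export
derive_bins <- function(age_years, onset_lag_days, concomitant_drug_count,
                        disease_count) {
  stopifnot(all(onset_lag_days >= 0, na.rm = TRUE))
  age_group <- cut(age_years, breaks = c(0.5, 3.5, 6.5, 11.5, 14.5, 17.5),
                   labels = srs_age_groups)
  unbinned <- !is.na(age_years) & age_years < 1
  if (any(unbinned)) {
    warning(sum(unbinned),
            " report(s) with age < 1 year have no age bin (kept for totals)",
            call. = FALSE)
  }
  onset_bin <- cut(onset_lag_days,
                   breaks = c(-0.5, 0.5, 3.5, 7.5, 14.5, 30.5, Inf),
                   labels = srs_onset_bins)
  tibble::tibble(
    age_group = as.character(age_group),
    onset_bin = as.character(onset_bin),
    polypharmacy_ge2 = concomitant_drug_count >= 2,
    polypharmacy_ge5 = concomitant_drug_count >= 5,
    multi_disease = disease_count >= 2
  )
}

#' Code filtered reports into the analysis table
#'
#' Applies primary-ADR selection, drug-name normalization, SOC mapping,
#' severity classification, and bin derivation, yielding one analysis row
#' per report.
#'
#' @param reports Filtered report tibble.
#' @param drug_dictionary Passed to [normalize_drug_name()].
#' @param soc_map Passed to [map_event_to_soc()].
#' @param policy Primary-ADR policy, see [select_primary_adr()].
#' @return A coded-report tibble (one scalar row per report).
#' @export
code_reports <- function(reports, drug_dictionary = NULL,
                         soc_map = default_soc_map(),
                         policy = "serious_first") {
  if (nrow(reports) == 0) return(empty_coded())
  primary <- purrr::map2(reports$adr_terms, reports$adr_serious,
                         select_primary_adr, policy = policy)
  primary_drug_raw <- vapply(reports$suspected_drugs, `[[`, character(1), 1)
  bins <- derive_bins(reports$age_years, reports$onset_lag_days,
                      reports$concomitant_drug_count, reports$disease_count)
  tibble::tibble(
    report_id = reports$report_id,
    report_year = reports$report_year,
    age_years = reports$age_years,
    gender = reports$gender,
    causality = reports$causality,
    primary_drug = normalize_drug_name(primary_drug_raw, drug_dictionary),
    primary_adr = tolower(stringr::str_squish(
      vapply(primary, `[[`, character(1), "term"))),
    primary_adr_serious = vapply(primary, `[[`, logical(1), "serious"),
    soc = map_event_to_soc(vapply(primary, `[[`, character(1), "term"), soc_map),
    severity = classify_severity(reports$seriousness_criteria),
    age_group = bins$age_group,
    onset_bin = bins$onset_bin,
    polypharmacy_ge2 = bins$polypharmacy_ge2,
    polypharmacy_ge5 = bins$polypharmacy_ge5,
    multi_disease = bins$multi_disease,
    past_adr_history = reports$past_adr_history,
    route = reports$route,
    off_label = reports$off_label,
    disease_count = reports$disease_count,
    concomitant_drug_count = reports$concomitant_drug_count,
    onset_lag_days = reports$onset_lag_days
  )
}

empty_coded <- function() {
  tibble::tibble(
    report_id = character(), report_year = integer(), age_years = integer(),
    gender = character(), causality = character(), primary_drug = character(),
    primary_adr = character(), primary_adr_serious = logical(),
    soc = character(), severity = character(), age_group = character(),
    onset_bin = character(), polypharmacy_ge2 = logical(),
    polypharmacy_ge5 = logical(), multi_disease = logical(),
    past_adr_history = character(), route = character(),
    off_label = logical(), disease_count = integer(),
    concomitant_drug_count = integer(), onset_lag_days = integer()
  )
}

#' Read/write coded-report tables
#'
#' Coded reports are flat CSVs; these helpers fix the column types on the
#' way back in.
#'
#' @param coded Coded-report tibble.
#' @param path CSV path.
#' @return `write_coded_reports()` returns `path` invisibly;
#'   `read_coded_reports()` returns the coded tibble.
#' @export
write_coded_reports <- function(coded, path) {
  readr::write_csv(coded, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_coded_reports
#' @export
read_coded_reports <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      report_id = "c", report_year = "i", age_years = "i", gender = "c",
      causality = "c", primary_drug = "c", primary_adr = "c",
      primary_adr_serious = "l", soc = "c", severity = "c", age_group = "c",
      onset_bin = "c", polypharmacy_ge2 = "l", polypharmacy_ge5 = "l",
      multi_disease = "l", past_adr_history = "c", route = "c",
      off_label = "l", disease_count = "i", concomitant_drug_count = "i",
      onset_lag_days = "i"
    ),
    progress = FALSE, show_col_types = FALSE
  )
}

#' Default ADR term to system-organ-class map
#'
#' A small simplified surrogate covering the vocabulary of the shipped
#' synthetic generator; real analyses should supply their own map.
#'
#' @return A tibble with columns `term` and `soc`.
#' @export
default_soc_map <- function() {
  tibble::tribble(
    ~term, ~soc,
    "myelosuppression", "Blood and lymphatic system disorders",
    "fibrinogen decreased", "Blood and lymphatic system disorders",
    "leukocyte count decreased", "Blood and lymphatic system disorders",
    "anemia", "Blood and lymphatic system disorders",
    "thrombocytopenia", "Blood and lymphatic system disorders",
    "vomiting", "Gastrointestinal disorders",
    "nausea", "Gastrointestinal disorders",
    "gastrointestinal reaction", "Gastrointestinal disorders",
    "diarrhea", "Gastrointestinal disorders",
    "mucositis oral", "Gastrointestinal disorders",
    "rash", "Skin and subcutaneous tissue disorders",
    "itch", "Skin and subcutaneous tissue disorders",
    "alopecia", "Skin and subcutaneous tissue disorders",
    "drug eruption", "Skin and subcutaneous tissue disorders",
    "fever", "General disorders and administration site conditions",
    "chills", "General disorders and administration site conditions",
    "phlebitis", "General disorders and administration site conditions",
    "dyspnea", "Respiratory, thoracic and mediastinal disorders",
    "cyanosis", "Respiratory, thoracic and mediastinal disorders",
    "hepatic failure", "Hepatobiliary disorders"
  )
}
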