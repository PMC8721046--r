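# Shared fixtures: the published stratified-table counts, a brute-force
# Fisher oracle, raw-CSV builders, and random-table generators.

# Severity-stratified counts (columns serious, normal) as published for a
# pediatric antineoplastic SRS corpus of 431 reports.
published_counts <- list(
  gender = matrix(c(88, 48, 179, 116), nrow = 2,
                  dimnames = list(c("male", "female"), c("serious", "normal"))),
  age_group = matrix(c(31, 30, 38, 26, 11, 99, 73, 63, 35, 25), nrow = 5,
                     dimnames = list(srsmine::srs_age_groups,
                                     c("serious", "normal"))),
  disease_types = matrix(c(127, 9, 279, 16), nrow = 2,
                         dimnames = list(c("single", "multiple"),
                                         c("serious", "normal"))),
  past_adr_history = matrix(c(22, 114, 23, 272), nrow = 2,
                            dimnames = list(c("yes", "no"),
                                            c("serious", "normal"))),
  onset_bin = matrix(c(30, 31, 25, 42, 6, 2, 98, 109, 51, 24, 8, 5), nrow = 6,
                     dimnames = list(srsmine::srs_onset_bins,
                                     c("serious", "normal"))),
  polypharmacy_ge2 = matrix(c(86, 50, 127, 168), nrow = 2,
                            dimnames = list(c("polypharmacy", "non_polypharmacy"),
                                            c("serious", "normal"))),
  polypharmacy_ge5 = matrix(c(19, 117, 13, 282), nrow = 2,
                            dimnames = list(c("polypharmacy", "non_polypharmacy"),
                                            c("serious", "normal"))),
  route = matrix(c(130, 3, 3, 276, 7, 12), nrow = 3,
                 dimnames = list(c("parenteral", "oral", "other"),
                                 c("serious", "normal"))),
  off_label = matrix(c(8, 128, 24, 271), nrow = 2,
                     dimnames = list(c("yes", "no"), c("serious", "normal")))
)

# Brute-force two-sided Fisher p for a 2x2 table: enumerate every table
# with the observed margins and sum the probabilities of those no more
# probable than the observed table (with the customary relative-error
# guard for ties).
fisher_enum_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One well-formed raw report row as a named character vector.
raw_row <- function(report_id = "R1", report_year = "2018", age_years = "6",
                    gender = "male", causality = "probable",
                    suspected_drugs = "cytarabine", atc_codes = "L01BC01",
                    concomitant_drug_count = "1", adr_terms = "rash",
                    adr_serious = "0", seriousness_criteria = "",
                    disease_count = "1", past_adr_history = "no",
                    onset_lag_days = "2", route = "parenteral",
                    off_label = "FALSE") {
  c(report_id = report_id, report_year = report_year, age_years = age_years,
    gender = gender, causality = causality, suspected_drugs = suspected_drugs,
    atc_codes = atc_codes, concomitant_drug_count = concomitant_drug_count,
    adr_terms = adr_terms, adr_serious = adr_serious,
    seriousness_criteria = seriousness_criteria, disease_count = disease_count,
    past_adr_history = past_adr_history, onset_lag_days = onset_lag_days,
    route = route, off_label = off_label)
}

write_raw_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Random strictly-positive 2x2 tables for property checks.
random_tables <- function(n, seed, max_cell = 200) {
  withr::with_seed(seed, tibble::tibble(
    a = sample.int(max_cell, n, replace = TRUE),
    b = sample.int(max_cell, n, replace = TRUE),
    c = sample.int(max_cell, n, replace = TRUE),
    d = sample.int(max_cell, n, replace = TRUE)
  ))
}

# A coded tibble whose per-column marginals match the published corpus
# (columns are independent; only marginal totals matter for proportions).
coded_from_published_marginals <- function() {
  n <- 431
  fill <- function(counts, labels) {
    rep(labels, times = counts)[seq_len(n)]
  }
  tibble::tibble(
    report_id = sprintf("R%03d", seq_len(n)),
    severity = fill(c(136, 295), c("serious", "normal")),
    past_adr_history = fill(c(45, 386), c("yes", "no")),
    route = fill(c(406, 10, 15), c("parenteral", "oral", "other")),
    off_label = fill(c(32, 399), c(TRUE, FALSE)),
    onset_bin = fill(c(128, 140, 76, 66, 14, 7), srsmine::srs_onset_bins),
    primary_drug = fill(c(113, 55, 49, 37, 30, 22, 17, 12, 11, 9, 76),
                        c("cytarabine", "asparaginase", "methotrexate",
                          "pegaspargase", "cyclophosphamide", "etoposide",
                          "vincristine", "cisplatin", "daunorubicin",
                          "doxorubicin", "other")),
    primary_adr = fill(c(67, 60, 51, 37, 26, 190),
                       c("myelosuppression", "rash", "vomiting", "fever",
                         "nausea", "other"))
  )
}

# Zero-row coded tibble with the full column set.
empty_coded_fixture <- function() {
  srsmine::code_reports(
    srsmine::generate_corpus(srsmine::sim_config(n_reports = 1, seed = 1))$reports
  )[0, ]
}
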