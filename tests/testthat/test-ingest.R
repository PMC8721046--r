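test_that("parser round-trips well-formed rows and handles the empty file", {
  rows <- list(
    raw_row(report_id = "A", adr_terms = "rash|myelosuppression",
            adr_serious = "0|1", suspected_drugs = "cytarabine|methotrexate",
            atc_codes = "L01BC01|L01BA01"),
    raw_row(report_id = "B", causality = "certain",
            seriousness_criteria = "hospitalization_or_prolongation"),
    raw_row(report_id = "C", gender = "female", route = "oral")
  )
  path <- write_raw_csv(rows)
  reports <- parse_reports(path)
  expect_equal(nrow(reports), 3)
  expect_equal(reports$report_id, c("A", "B", "C"))
  expect_equal(reports$suspected_drugs[[1]], c("cytarabine", "methotrexate"))
  expect_equal(reports$adr_terms[[1]], c("rash", "myelosuppression"))
  expect_equal(reports$adr_serious[[1]], c(FALSE, TRUE))
  expect_equal(reports$seriousness_criteria[[2]],
               "hospitalization_or_prolongation")
  expect_false(any(reports$parse_failure))

  # round trip through the writer preserves content
  out <- withr::local_tempfile(fileext = ".csv")
  write_reports(reports, out)
  again <- parse_reports(out)
  expect_equal(again$suspected_drugs, reports$suspected_drugs)
  expect_equal(again$adr_serious, reports$adr_serious)
  expect_equal(again$onset_lag_days, reports$onset_lag_days)

  empty <- write_raw_csv(list(raw_row()[0]))
  writeLines(paste(names(raw_row()), collapse = ","), empty)
  expect_equal(nrow(parse_reports(empty)), 0)
})

test_that("parser flags unparseable numerics and normalizes unknown enums", {
  path <- write_raw_csv(list(raw_row(report_id = "A", age_years = "abc"),
                             raw_row(report_id = "B", gender = "boy")))
  reports <- suppressWarnings(parse_reports(path))
  expect_true(reports$parse_failure[1])
  expect_false(reports$parse_failure[2])
  expect_equal(reports$gender[2], "unknown")
  expect_warning(parse_reports(path), "gender")

  filtered <- apply_inclusion_filters(reports)
  expect_equal(filtered$audit$removed[["unparseable"]], 1)
  expect_equal(filtered$audit$n_out, 1)
})

test_that("parser errors on a missing required column", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(rbind(raw_row()))
  df$suspected_drugs <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(parse_reports(path), "suspected_drugs")
  expect_error(parse_reports(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("inclusion filters keep the valid records and audit every removal", {
  rows <- list(
    raw_row(report_id = "bad_year", report_year = "2015"),
    raw_row(report_id = "bad_causality", causality = "unlikely"),
    raw_row(report_id = "bad_atc", atc_codes = "J01CA04"),
    raw_row(report_id = "too_old", age_years = "25"),
    raw_row(report_id = "neg_lag", onset_lag_days = "-1"),
    raw_row(report_id = "dup"),
    raw_row(report_id = "dup"),
    raw_row(report_id = "ok1"),
    raw_row(report_id = "ok2"),
    raw_row(report_id = "ok3")
  )
  reports <- parse_reports(write_raw_csv(rows))
  res <- apply_inclusion_filters(reports)
  expect_equal(res$audit$n_in, 10)
  expect_equal(res$audit$n_out, 4)
  expect_equal(sum(res$audit$removed), 6)
  expect_equal(res$audit$removed[["year_window"]], 1)
  expect_equal(res$audit$removed[["causality"]], 1)
  expect_equal(res$audit$removed[["atc_class"]], 1)
  expect_equal(res$audit$removed[["age_window"]], 1)
  expect_equal(res$audit$removed[["negative_onset"]], 1)
  expect_equal(res$audit$removed[["duplicate"]], 1)
  expect_setequal(res$reports$report_id, c("dup", "ok1", "ok2", "ok3"))

  # conservation and idempotence
  expect_equal(res$audit$n_in - res$audit$n_out, sum(res$audit$removed))
  twice <- apply_inclusion_filters(res$reports)
  expect_equal(twice$reports, res$reports)
  expect_equal(sum(twice$audit$removed), 0)
})

test_that("all-valid input passes the filters unchanged with a zero audit", {
  reports <- parse_reports(write_raw_csv(list(
    raw_row(report_id = "A"), raw_row(report_id = "B")
  )))
  res <- apply_inclusion_filters(reports)
  expect_equal(res$reports, reports)
  expect_true(all(res$audit$removed == 0))
})

test_that("deduplication keeps the first occurrence per key", {
  reports <- parse_reports(write_raw_csv(list(
    raw_row(report_id = "A", gender = "male"),
    raw_row(report_id = "A", gender = "female"),
    raw_row(report_id = "B")
  )))
  kept <- deduplicate(reports, "report_id")
  expect_equal(nrow(kept), 2)
  expect_equal(kept$gender[kept$report_id == "A"], "male")   # order-stable

  # a pair differing only in report_id: kept under the id key, collapsed
  # under a content key
  pair <- parse_reports(write_raw_csv(list(
    raw_row(report_id = "X"), raw_row(report_id = "Y")
  )))
  expect_equal(nrow(deduplicate(pair, "report_id")), 2)
  content_key <- setdiff(names(pair), c("report_id", "parse_failure"))
  expect_equal(nrow(deduplicate(pair, content_key)), 1)

  expect_equal(nrow(deduplicate(reports[3, ], "report_id")), 1)
  expect_error(deduplicate(reports, "no_such_field"), "no_such_field")
  expect_error(deduplicate(reports, character(0)), "non-empty")
})

test_that("primary-ADR selection ranks serious terms first, then listing order", {
  expect_equal(
    select_primary_adr(c("rash", "myelosuppression"), c(FALSE, TRUE)),
    list(term = "myelosuppression", serious = TRUE)
  )
  expect_equal(select_primary_adr("vomiting", FALSE),
               list(term = "vomiting", serious = FALSE))
  expect_equal(
    select_primary_adr(c("nausea", "fever"), c(FALSE, FALSE)),
    list(term = "nausea", serious = FALSE)
  )
  expect_equal(
    select_primary_adr(c("rash", "myelosuppression"), c(FALSE, TRUE),
                       policy = "first_listed")$term,
    "rash"
  )
  expect_error(select_primary_adr(character(0), logical(0)), "no ADR terms")
})

test_that("drug-name normalization maps, trims, case-folds and falls through", {
  dict <- tibble::tibble(raw = "cytarabine inj.", generic = "cytarabine")
  expect_equal(normalize_drug_name("Cytarabine Inj.", dict), "cytarabine")
  expect_warning(
    out <- normalize_drug_name("cytarabine", tibble::tibble(raw = character(),
                                                            generic = character())),
    "not in dictionary"
  )
  expect_equal(out, "cytarabine")
  expect_equal(normalize_drug_name("  PEGASPARGASE "), "pegaspargase")
})

test_that("SOC mapping covers known terms and defaults to Unclassified", {
  expect_equal(map_event_to_soc("Vomiting"), "Gastrointestinal disorders")
  expect_equal(map_event_to_soc("Myelosuppression"),
               "Blood and lymphatic system disorders")
  expect_warning(out <- map_event_to_soc("sparkle"), "Unclassified")
  expect_equal(out, "Unclassified")
})

test_that("severity is serious iff a seriousness criterion is present", {
  expect_equal(classify_severity(character(0)), "normal")
  expect_equal(classify_severity("hospitalization_or_prolongation"), "serious")
  expect_equal(classify_severity(srs_seriousness_criteria), "serious")

  # monotone: adding criteria never demotes a serious report
  subsets <- lapply(0:6, function(k) srs_seriousness_criteria[seq_len(k)])
  sev <- classify_severity(subsets)
  expect_equal(sev, c("normal", rep("serious", 6)))
})

test_that("bin derivation matches the published bin edges", {
  b <- derive_bins(3, 0, 1, 1)
  expect_equal(unlist(b),
               c(age_group = "1-3", onset_bin = "on_the_day",
                 polypharmacy_ge2 = "FALSE", polypharmacy_ge5 = "FALSE",
                 multi_disease = "FALSE"))
  b <- derive_bins(17, 31, 5, 1)
  expect_equal(b$age_group, "15-17")
  expect_equal(b$onset_bin, "over_month")
  expect_true(b$polypharmacy_ge2 && b$polypharmacy_ge5)
  b <- derive_bins(11, 14, 2, 2)
  expect_equal(b$age_group, "7-11")
  expect_equal(b$onset_bin, "d8_14")
  expect_true(b$polypharmacy_ge2 && !b$polypharmacy_ge5 && b$multi_disease)
})

test_that("bin edges are total and disjoint over ages 1-17 and lags >= 0", {
  grid <- expand.grid(age = 1:17, lag = 0:60)
  bins <- derive_bins(grid$age, grid$lag, 1, 1)
  expect_false(any(is.na(bins$age_group)))
  expect_false(any(is.na(bins$onset_bin)))
  expect_true(all(bins$age_group %in% srs_age_groups))
  expect_true(all(bins$onset_bin %in% srs_onset_bins))
  # polypharmacy implication ge5 => ge2
  b <- derive_bins(rep(5, 10), rep(1, 10), 0:9, 1)
  expect_true(all(!b$polypharmacy_ge5 | b$polypharmacy_ge2))
})

test_that("age 0 stays in the corpus but gets no age bin", {
  expect_warning(b <- derive_bins(0, 1, 1, 1), "no age bin")
  expect_true(is.na(b$age_group))
  expect_equal(b$onset_bin, "d1_3")
})

test_that("coding produces one analysis row per report with derived fields", {
  rows <- list(
    raw_row(report_id = "A", adr_terms = "rash|myelosuppression",
            adr_serious = "0|1",
            seriousness_criteria = "hospitalization_or_prolongation"),
    raw_row(report_id = "B", concomitant_drug_count = "6", disease_count = "2")
  )
  coded <- code_reports(parse_reports(write_raw_csv(rows)))
  expect_equal(nrow(coded), 2)
  expect_equal(coded$primary_adr, c("myelosuppression", "rash"))
  expect_equal(coded$severity, c("serious", "normal"))
  expect_equal(coded$soc[1], "Blood and lymphatic system disorders")
  expect_true(coded$polypharmacy_ge5[2] && coded$multi_disease[2])
  expect_equal(nrow(code_reports(parse_reports(write_raw_csv(rows))[0, ])), 0)
})
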