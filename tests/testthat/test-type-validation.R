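reg <- ctg_registry()

simple_findings <- function(...) {
  validate_simple(minimal_record(...), reg)
}

test_that("date values are accepted and rejected per the grammar", {
  ok <- c("January 3, 2004", "March, 2005", "Unknown", "December 31, 1999")
  for (v in ok) {
    expect_equal(nrow(simple_findings(
      paste0("<start_date>", v, "</start_date>"))), 0, label = v)
  }
  bad <- c("Jan 3, 2004", "January 32, 2004", "January 0, 2004",
           "2004-01-03", "January 3 2004", "March,2005", "january 3, 2004")
  for (v in bad) {
    f <- simple_findings(paste0("<start_date>", v, "</start_date>"))
    expect_equal(f$code, "TYPE_MISMATCH", label = v)
    expect_equal(f$severity, "error", label = v)
  }
})

test_that("date type attributes outside Actual/Anticipated/Estimate are flagged", {
  expect_equal(nrow(simple_findings(
    '<start_date type="Actual">January 3, 2004</start_date>')), 0)
  f <- simple_findings('<start_date type="Projected">January 3, 2004</start_date>')
  expect_equal(f$code, "TYPE_MISMATCH")
})

test_that("boolean, integer and age grammars behave as documented", {
  expect_equal(nrow(simple_findings("<has_expanded_access>No</has_expanded_access>")), 0)
  expect_equal(simple_findings(
    "<has_expanded_access>false</has_expanded_access>")$code, "TYPE_MISMATCH")

  expect_equal(nrow(simple_findings("<number_of_arms>3</number_of_arms>")), 0)
  expect_equal(simple_findings(
    "<number_of_arms>two</number_of_arms>")$code, "TYPE_MISMATCH")
  expect_equal(simple_findings(
    "<number_of_arms>-2</number_of_arms>")$code, "TYPE_MISMATCH")

  age <- function(v) paste0("<eligibility><minimum_age>", v,
                            "</minimum_age></eligibility>")
  expect_equal(nrow(simple_findings(age("18 Years"))), 0)
  expect_equal(nrow(simple_findings(age("N/A"))), 0)
  # leading nonzero digit is mandatory
  expect_equal(simple_findings(age("0 Years"))$code, "TYPE_MISMATCH")
  expect_equal(simple_findings(age("18Years"))$code, "TYPE_MISMATCH")
  expect_equal(simple_findings(age("18 Fortnights"))$code, "TYPE_MISMATCH")
})

test_that("every occurrence of a repeated field is checked", {
  f <- simple_findings(
    "<primary_outcome><measure>x</measure></primary_outcome>",
    "<enrollment>12</enrollment>",
    "<number_of_arms>two</number_of_arms>",
    "<start_date>bogus</start_date>")
  expect_equal(sort(f$dictionary_name),
               c("number of arms", "study start date"))
})

test_that("date grammar agrees with a brute-force rule checker", {
  # independent oracle: explicit rules, no regex
  oracle <- function(s) {
    if (s == "Unknown") return(TRUE)
    m <- regmatches(s, regexec("^([A-Za-z]+) ([0-9]{1,2}), ([0-9]{4})$", s))[[1]]
    if (length(m) == 4) {
      day <- suppressWarnings(as.integer(m[3]))
      return(m[2] %in% month.name && !is.na(day) && day >= 1 && day <= 31 &&
               !grepl("^0", m[3]) && m[4] >= "1000" && m[4] <= "2999")
    }
    m <- regmatches(s, regexec("^([A-Za-z]+), ([0-9]{4})$", s))[[1]]
    length(m) == 3 && m[2] %in% month.name && m[3] >= "1000" && m[3] <= "2999"
  }
  months <- c(month.name, "Jan", "january", "Midwinter")
  days <- c(NA, 0:32)
  years <- c("1999", "2017", "0999", "3000")
  rec_tpl <- function(v) minimal_record(paste0("<start_date>", v, "</start_date>"))
  for (mo in months) for (d in days) for (y in years) {
    v <- if (is.na(d)) paste0(mo, ", ", y) else paste0(mo, " ", d, ", ", y)
    accepted <- nrow(validate_simple(rec_tpl(v), reg)) == 0
    expect_equal(accepted, oracle(v), label = v)
  }
  expect_true(oracle("Unknown"))
})

test_that("age normalization uses the fixed conversion table", {
  two_years <- normalize_age("2 Years")
  expect_equal(two_years$minutes_equivalent, 1051200)
  expect_equal(two_years$minutes_equivalent,
               normalize_age("24 Months")$minutes_equivalent)
  expect_equal(normalize_age("90 Minutes")$minutes_equivalent, 90)
  na <- normalize_age("N/A")
  expect_equal(na$unit, "not_applicable")
  expect_true(is.na(na$minutes_equivalent))
  expect_error(normalize_age("two years"), class = "ctg_value_error")
})

test_that("age normalization is order-preserving over an exhaustive grid", {
  units <- c("Minutes", "Hours", "Days", "Weeks", "Months", "Years")
  factors <- c(1, 60, 1440, 10080, 43800, 525600)
  grid <- expand.grid(mag = 1:60, unit = seq_along(units))
  true_minutes <- grid$mag * factors[grid$unit]
  computed <- vapply(seq_len(nrow(grid)), function(i) {
    normalize_age(paste0(grid$mag[i], " ", units[grid$unit[i]]))$minutes_equivalent
  }, numeric(1))
  expect_equal(computed, true_minutes)
  ord <- order(true_minutes)
  expect_true(all(diff(computed[ord]) >= 0))
})

test_that("rogue enumerated values are flagged and members pass", {
  enum_findings <- function(...) validate_enumerated(minimal_record(...), reg)
  f <- enum_findings("<study_design_info><primary_purpose>Educational/Counseling/Training</primary_purpose></study_design_info>")
  expect_equal(f$code, "ROGUE_VALUE")
  expect_equal(f$severity, "warning")
  f <- enum_findings("<study_design_info><allocation>Random Sample</allocation></study_design_info>")
  expect_equal(f$dictionary_name, "allocation")
  expect_equal(f$code, "ROGUE_VALUE")
  # matching is case-sensitive
  f <- enum_findings("<study_design_info><allocation>randomized</allocation></study_design_info>")
  expect_equal(f$code, "ROGUE_VALUE")
  expect_equal(nrow(enum_findings(
    "<study_design_info><allocation>Randomized</allocation></study_design_info>")), 0)
  expect_equal(nrow(enum_findings("<phase>Phase 2</phase>")), 0)
})

test_that("record-form model and masking syntax yields a note, not a rogue", {
  enum_findings <- function(...) validate_enumerated(minimal_record(...), reg)
  f <- enum_findings("<study_design_info><masking>Double(Participant, Care Provider)</masking></study_design_info>")
  expect_equal(f$code, "FORMAT_VARIANT")
  expect_equal(f$severity, "note")
  f <- enum_findings("<study_design_info><intervention_model>Parallel Group Assignment</intervention_model></study_design_info>")
  expect_equal(f$code, "FORMAT_VARIANT")
  expect_equal(nrow(enum_findings(
    "<study_design_info><masking>No Masking</masking></study_design_info>")), 0)
  # inconsistent count word or unknown role is rogue, not a variant
  f <- enum_findings("<study_design_info><masking>Double(Investigator)</masking></study_design_info>")
  expect_equal(f$code, "ROGUE_VALUE")
  f <- enum_findings("<study_design_info><masking>Single(Janitor)</masking></study_design_info>")
  expect_equal(f$code, "ROGUE_VALUE")
})

test_that("canonicalization maps record forms to dictionary forms", {
  expect_equal(
    canonicalize_enumerated("interventional study model",
                            "Parallel Group Assignment", reg),
    "Parallel")
  expect_equal(
    canonicalize_enumerated("interventional study model",
                            "Single Group Assignment", reg),
    "Single Group")
  expect_equal(canonicalize_enumerated("masking", "Single(Investigator)", reg),
               "Investigator")
  expect_equal(
    sort(canonicalize_enumerated("masking",
                                 "Double(Participant, Care Provider)", reg)),
    c("Care Provider", "Participant"))
  expect_error(
    canonicalize_enumerated("masking", "Double(Investigator)", reg),
    class = "ctg_canonicalization_error")
  expect_equal(canonicalize_enumerated("allocation", "Randomized", reg),
               "Randomized")
  expect_error(canonicalize_enumerated("allocation", "Random Sample", reg),
               class = "ctg_canonicalization_error")
})
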