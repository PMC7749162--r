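reg <- ctg_registry()

test_that("era classification honors the Final Rule boundary and day imputation", {
  expect_equal(classify_era("January 17, 2017"), "pre_final_rule")
  expect_equal(classify_era("January 18, 2017"), "post_final_rule")
  expect_equal(classify_era("January 19, 2017"), "post_final_rule")
  # day-absent dates compare as the first of the month
  expect_equal(classify_era("January, 2017"), "pre_final_rule")
  expect_equal(classify_era("February, 2017"), "post_final_rule")
  expect_equal(classify_era("Unknown"), "unknown_start_date")
  expect_equal(classify_era(NA_character_), "unknown_start_date")
  expect_true(parse_ctg_date("January, 2017")$day_imputed)
  expect_false(parse_ctg_date("January 18, 2017")$day_imputed)
})

test_that("completeness audit rejects non-interventional records", {
  rec <- minimal_record(study_type = "Observational")
  expect_error(audit_completeness(rec, reg), class = "ctg_precondition_error")
})

test_that("a fully populated record has empty missing sets", {
  rep <- audit_completeness(clean_record(), reg)
  expect_equal(rep$missing_required[[1]], character(0))
  expect_equal(rep$missing_conditional[[1]], character(0))
  expect_equal(rep$missing_recommended[[1]], character(0))
  expect_true(rep$contact_rule_satisfied)
})

test_that("why-study-stopped is missing only when the study ended early", {
  terminated <- minimal_record(
    "<overall_status>Terminated</overall_status>",
    "<start_date>March 3, 2018</start_date>")
  rep <- audit_completeness(terminated, reg)
  expect_true("why study stopped" %in% rep$missing_conditional[[1]])
  expect_false("why study stopped" %in% rep$missing_required[[1]])

  completed <- minimal_record(
    "<overall_status>Completed</overall_status>",
    "<start_date>March 3, 2018</start_date>")
  rep <- audit_completeness(completed, reg)
  expect_false("why study stopped" %in% rep$missing_conditional[[1]])

  # pre-rule termination: recommended, not required
  pre <- minimal_record(
    "<overall_status>Terminated</overall_status>",
    "<start_date>March 3, 2012</start_date>")
  rep <- audit_completeness(pre, reg)
  expect_true("why study stopped" %in% rep$missing_recommended[[1]])
  expect_false("why study stopped" %in% rep$missing_conditional[[1]])
})

test_that("pre-rule records do not count recommended-only fields as required", {
  rec <- minimal_record("<start_date>June 1, 2010</start_date>")
  rep <- audit_completeness(rec, reg)
  expect_false(any(c("official title", "study completion date") %in%
                     rep$missing_required[[1]]))
  expect_true(all(c("official title", "study completion date") %in%
                    rep$missing_recommended[[1]]))
  post <- minimal_record("<start_date>June 1, 2018</start_date>")
  rep_post <- audit_completeness(post, reg)
  expect_true(all(c("official title", "study completion date") %in%
                    rep_post$missing_required[[1]]))
})

test_that("zero listed arms makes arm information and number of arms missing", {
  rec <- clean_record()
  rec$design$arms <- rec$design$arms[0, ]
  rec$number_of_arms_raw <- NA_character_
  rec <- read_trial_record(write_trial_record(rec))
  rep <- audit_completeness(rec, reg)
  expect_true(all(c("arm information", "number of arms") %in%
                    rep$missing_required[[1]]))
})

test_that("the contact rule accepts an overall contact or per-site contacts", {
  sites <- function(k, with_contact) paste0(
    "<location><facility><name>Site</name><address><city>X</city>",
    "<country>Y</country></address></facility><status>Completed</status>",
    if (with_contact) "<contact><last_name>A B, M.D.</last_name></contact>",
    "</location>") |> rep(k) |> paste(collapse = "")
  overall <- "<overall_contact><last_name>C D, M.D.</last_name></overall_contact>"

  rep <- audit_completeness(minimal_record(overall, sites(50, FALSE)), reg)
  expect_true(rep$overall_contact_present)
  expect_false(rep$all_sites_have_contact)
  expect_true(rep$contact_rule_satisfied)

  rep <- audit_completeness(minimal_record(sites(2, TRUE)), reg)
  expect_true(rep$contact_rule_satisfied)

  rep <- audit_completeness(minimal_record(sites(2, FALSE)), reg)
  expect_false(rep$contact_rule_satisfied)

  # no contact anywhere, no sites: rule unsatisfied
  rep <- audit_completeness(minimal_record(), reg)
  expect_false(rep$contact_rule_satisfied)
})

test_that("principal-investigator classification partitions the four cases", {
  rp <- function(type) paste0(
    "<responsible_party><responsible_party_type>", type,
    "</responsible_party_type></responsible_party>")
  official <- "<overall_official><last_name>E F, M.D.</last_name></overall_official>"
  expect_equal(classify_pi(minimal_record(rp("Sponsor"), official)),
               "official_with_nonscientific_rp")
  expect_equal(classify_pi(minimal_record(rp("Sponsor-Investigator"))),
               "rp_investigator_only")
  expect_equal(classify_pi(minimal_record(rp("Principal Investigator"))),
               "rp_investigator_only")
  expect_equal(classify_pi(minimal_record(rp("Sponsor"))), "no_pi")
  expect_equal(classify_pi(minimal_record(rp("Sponsor-Investigator"), official)),
               "both")

  # partition property over a generated mix
  gen <- generate_corpus(corpus_config(
    60, seed = 3,
    pi_mix = c(no_pi = 0.25, rp_investigator_only = 0.25,
               official_with_nonscientific_rp = 0.25, both = 0.25)))
  cats <- vapply(gen$records$record, classify_pi, character(1))
  expect_equal(length(cats), 60)
  expect_equal(sum(table(cats)), 60)
  expect_setequal(names(table(cats)),
                  c("no_pi", "rp_investigator_only",
                    "official_with_nonscientific_rp", "both"))
})

test_that("contact-detail tallies count provided details and their gaps", {
  no_email <- minimal_record(
    "<overall_contact><last_name>A</last_name><phone>1</phone></overall_contact>")
  expect_equal(audit_contact_details(list(no_email)),
               tibble::tibble(n_contacts = 1L, n_missing_phone = 0L,
                              n_missing_email = 1L))
  empty <- minimal_record()
  expect_equal(audit_contact_details(list(empty))$n_contacts, 0L)

  both <- minimal_record(
    "<overall_contact><last_name>A</last_name></overall_contact>",
    "<location><facility><name>S</name></facility>",
    "<contact><last_name>B</last_name><email>e@x</email></contact></location>")
  tall <- audit_contact_details(list(both, no_email, empty))
  expect_equal(tall$n_contacts, 3L)
  expect_equal(tall$n_missing_phone, 2L)
  expect_equal(tall$n_missing_email, 2L)
})

test_that("adding a value never grows a missing set (monotonicity)", {
  base <- minimal_record("<start_date>June 1, 2018</start_date>")
  base_missing <- unlist(audit_completeness(base, reg)[
    , c("missing_required", "missing_conditional", "missing_recommended")])
  richer <- minimal_record(
    "<start_date>June 1, 2018</start_date>",
    "<brief_title>T</brief_title>",
    "<enrollment>10</enrollment>",
    "<official_title>OT</official_title>")
  richer_missing <- unlist(audit_completeness(richer, reg)[
    , c("missing_required", "missing_conditional", "missing_recommended")])
  expect_true(all(richer_missing %in% base_missing))
  expect_true(length(richer_missing) < length(base_missing))
})

test_that("era rollup bins unknown start dates with the pre-rule column", {
  rec_pre <- audit_completeness(
    minimal_record("<start_date>June 1, 2010</start_date>"), reg)
  rec_unknown <- audit_completeness(minimal_record(), reg)
  tab <- summarize_completeness(dplyr::bind_rows(rec_pre, rec_unknown), "era")
  row <- dplyr::filter(tab, field == "enrollment")
  expect_equal(row$missing_pre_final_rule, 2)
  expect_equal(row$missing_all, 2)
  # a missing start date is itself tabulated
  expect_equal(dplyr::filter(tab, field == "study start date")$missing_all, 1)
})
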