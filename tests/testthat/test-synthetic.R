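test_that("generation is a pure function of the configuration", {
  cfg <- corpus_config(12, seed = 99,
                       study_type_mix = c(Interventional = 0.75,
                                          Observational = 0.25),
                       criteria_class_plan = c(headers_only = 3))
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  xml_of <- function(gen) vapply(gen$records$record, function(r)
    as.character(write_trial_record(r)), character(1))
  expect_identical(xml_of(a), xml_of(b))
  expect_identical(a$truth, b$truth)
  # a different seed moves the plants
  c <- generate_corpus(corpus_config(12, seed = 100,
                                     study_type_mix = c(Interventional = 0.75,
                                                        Observational = 0.25),
                                     criteria_class_plan = c(headers_only = 3)))
  expect_false(identical(xml_of(a), xml_of(c)))
})

test_that("exact-counts mode plants mixes as apportioned counts", {
  gen <- generate_corpus(corpus_config(
    40, seed = 1,
    study_type_mix = c(Interventional = 0.5, Observational = 0.5),
    era_mix = c(pre_final_rule = 0.75, post_final_rule = 0.25),
    agency_mix = c(NIH = 0.1, Industry = 0.4, Other = 0.5)))
  tr <- gen$truth$assignments
  expect_equal(sum(tr$study_type == "Interventional"), 20)
  expect_equal(sum(tr$era == "pre_final_rule"), 30)
  expect_equal(as.vector(table(tr$agency_class)[c("NIH", "Industry", "Other")]),
               c(4L, 16L, 20L))
  # realized eras match the written start dates
  eras <- vapply(gen$records$record, classify_era, character(1))
  expect_equal(eras, tr$era)
})

test_that("infeasible plans fail with the offending entry named", {
  expect_error(
    generate_corpus(corpus_config(4, missing_plan = list(allocation = 10))),
    "allocation", class = "ctg_config_error")
  expect_error(
    generate_corpus(corpus_config(4, criteria_class_plan = c(missing = 9))),
    class = "ctg_config_error")
  expect_error(
    generate_corpus(corpus_config(4, criteria_class_plan = c(malformed_headers = 1),
                                  multi_group_count = 3)),
    class = "ctg_config_error")
  expect_error(corpus_config(4, study_type_mix = c(Bogus = 1)),
               class = "ctg_config_error")
})

test_that("a clean corpus round-trips through the reader and writer", {
  skip_if_not_installed("withr")
  gen <- generate_corpus(corpus_config(5, seed = 8))
  dir <- withr::local_tempdir()
  write_corpus(gen$records, gen$truth, dir)
  expect_length(list.files(dir, pattern = "\\.xml$"), 5)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))

  back <- read_trial_corpus(dir)
  expect_equal(back$record_id, gen$records$record_id)
  expect_identical(
    lapply(back$record, function(r) r$raw_values),
    lapply(gen$records$record, function(r) r$raw_values))
})

test_that("the manifest detects corpus tampering", {
  skip_if_not_installed("withr")
  gen <- generate_corpus(corpus_config(3, seed = 8))
  dir <- withr::local_tempdir()
  write_corpus(gen$records, gen$truth, dir)
  expect_true(verify_manifest(dir)$ok)

  # regenerating with the same seed reproduces the same checksum
  dir2 <- withr::local_tempdir()
  gen2 <- generate_corpus(corpus_config(3, seed = 8))
  m1 <- jsonlite::read_json(file.path(dir, "manifest.json"))
  m2 <- write_corpus(gen2$records, gen2$truth, dir2)
  expect_equal(m1$corpus_checksum, unname(m2$corpus_checksum))

  writeLines("tampered", file.path(dir, gen$records$file[2]))
  v <- verify_manifest(dir)
  expect_false(v$ok)
  expect_equal(v$mismatched, gen$records$file[2])
  unlink(file.path(dir, gen$records$file[1]))
  v <- verify_manifest(dir)
  expect_equal(v$missing, gen$records$file[1])
})

test_that("rates mode plants counts near the configured rates", {
  cfg <- headline_profile(n_records = 300, seed = 21)
  gen <- generate_corpus(cfg)
  tr <- gen$truth$assignments
  # 4-binomial-SD bands around each configured rate
  in_band <- function(count, n, rate) {
    abs(count - n * rate) <= 4 * sqrt(n * rate * (1 - rate)) + 1e-9
  }
  expect_true(in_band(sum(tr$criteria_class == "correct"), 300, 0.607))
  expect_true(in_band(sum(tr$condition_in_lexicon), 300, 0.62))
  expect_true(in_band(sum(tr$pi_category == "no_pi"), 300, 0.12))
  expect_true(in_band(length(gen$truth$contacts$no_overall_contact), 300, 0.74))
})
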