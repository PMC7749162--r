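test_that("a minimal record parses to empty collections and absent optionals", {
  rec <- minimal_record()
  expect_s3_class(rec, "trial_record")
  expect_equal(rec$record_id, "NCT00000001")
  expect_equal(rec$study_type, "Interventional")
  expect_equal(nrow(rec$interventions), 0)
  expect_equal(nrow(rec$design$arms), 0)
  expect_equal(nrow(rec$contacts$locations), 0)
  expect_length(rec$conditions, 0)
  expect_true(is.na(rec$start_date_raw))
  expect_null(rec$contacts$overall_contact)
})

test_that("full names and degrees inside last_name are preserved verbatim", {
  rec <- minimal_record(
    "<overall_official><last_name>Sarah Smith, M.D.</last_name>
     <role>Study Principal Investigator</role></overall_official>")
  expect_equal(rec$parties$overall_officials$last_name, "Sarah Smith, M.D.")
})

test_that("raw_values keeps every occurrence in document order", {
  rec <- minimal_record(
    "<condition>Asthma</condition>",
    "<condition>Asthma</condition>",
    "<condition>Hay Fever</condition>")
  vals <- rec$raw_values$value[rec$raw_values$xml_path == "condition"]
  expect_equal(vals, c("Asthma", "Asthma", "Hay Fever"))
  expect_equal(rec$conditions, vals)
})

test_that("date attributes and day-absent dates survive the reader", {
  rec <- minimal_record('<start_date type="Anticipated">March, 2005</start_date>')
  expect_equal(rec$start_date_raw, "March, 2005")
  expect_equal(rec$start_date_type, "Anticipated")
  doc <- write_trial_record(rec)
  node <- xml2::xml_find_first(doc, "//start_date")
  expect_equal(xml2::xml_text(node), "March, 2005")
  expect_equal(xml2::xml_attr(node, "type"), "Anticipated")
})

test_that("ill-formed XML and missing identifiers raise typed errors", {
  expect_error(read_trial_record("<clinical_study><oops"),
               class = "ctg_parse_error")
  expect_error(
    read_trial_record("<clinical_study><study_type>Interventional</study_type></clinical_study>"),
    class = "ctg_structure_error")
})

test_that("write-then-read is the identity on the retained field set", {
  skip_if_not_installed("withr")
  gen <- generate_corpus(corpus_config(
    8, seed = 11,
    study_type_mix = c(Interventional = 0.7, Observational = 0.3)))
  compare_fields <- function(a, b) {
    for (f in c("record_id", "secondary_ids", "study_type", "brief_title",
                "brief_summary", "official_title", "overall_status",
                "why_stopped", "start_date_raw", "start_date_type", "phase",
                "enrollment_raw", "number_of_arms_raw", "agency",
                "agency_class", "conditions")) {
      expect_identical(a[[f]], b[[f]], label = f)
    }
    expect_identical(a$interventions, b$interventions)
    expect_identical(a$design, b$design)
    expect_identical(a$parties, b$parties)
    expect_identical(a$contacts, b$contacts)
    expect_identical(a$outcomes, b$outcomes)
    expect_identical(a$eligibility, b$eligibility)
  }
  for (rec in gen$records$record) {
    back <- read_trial_record(write_trial_record(rec))
    compare_fields(rec, back)
    # a second round trip is byte-stable
    expect_identical(as.character(write_trial_record(rec)),
                     as.character(write_trial_record(back)))
  }
})

test_that("empty collections emit no elements", {
  rec <- minimal_record()
  doc <- write_trial_record(rec)
  expect_length(xml2::xml_find_all(doc, "//arm_group"), 0)
  expect_length(xml2::xml_find_all(doc, "//location"), 0)
})

test_that("corpus reading is ordered, error-isolating and deterministic", {
  skip_if_not_installed("withr")
  dir <- withr::local_tempdir()
  writeLines(record_xml(nct_id = "NCT00000002"), file.path(dir, "b.xml"))
  writeLines(record_xml(nct_id = "NCT00000001"), file.path(dir, "a.xml"))
  writeLines("<clinical_study><broken", file.path(dir, "c.xml"))
  writeLines("not xml at all", file.path(dir, "notes.txt"))

  expect_warning(corpus <- read_trial_corpus(dir), "non-XML")
  expect_equal(corpus$file, c("a.xml", "b.xml"))
  expect_equal(corpus$record_id, c("NCT00000001", "NCT00000002"))
  errs <- attr(corpus, "parse_errors")
  expect_equal(errs$file, "c.xml")

  again <- suppressWarnings(read_trial_corpus(dir))
  expect_identical(corpus$record_id, again$record_id)
  expect_error(read_trial_corpus(file.path(dir, "missing")),
               class = "ctg_io_error")
})

test_that("a zipped corpus reads identically to the directory", {
  skip_if_not_installed("withr")
  dir <- withr::local_tempdir()
  writeLines(record_xml(nct_id = "NCT00000009"), file.path(dir, "r.xml"))
  zip_path <- file.path(withr::local_tempdir(), "corpus.zip")
  withr::with_dir(dir, system2("python", c("-m", "zipfile", "-c",
                                           shQuote(zip_path), "r.xml")))
  corpus <- read_trial_corpus(zip_path)
  expect_equal(corpus$record_id, "NCT00000009")
})

test_that("JSON Lines export writes one line per record", {
  skip_if_not_installed("withr")
  gen <- generate_corpus(corpus_config(3, seed = 2))
  path <- file.path(withr::local_tempdir(), "records.jsonl")
  export_records_jsonl(gen$records, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$record_id, gen$records$record_id[1])
})
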