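# Shared fixture builders. Records are built from XML strings so that the
# reader, not the generator, defines what the tests exercise.

record_xml <- function(..., nct_id = "NCT00000001",
                       study_type = "Interventional") {
  body <- paste0(c(...), collapse = "\n  ")
  paste0(
    "<clinical_study>\n",
    "  <id_info><nct_id>", nct_id, "</nct_id></id_info>\n  ",
    body,
    "\n  <study_type>", study_type, "</study_type>\n",
    "</clinical_study>")
}

minimal_record <- function(..., nct_id = "NCT00000001",
                           study_type = "Interventional") {
  read_trial_record(record_xml(..., nct_id = nct_id,
                               study_type = study_type))
}

# one fully populated interventional record straight from the generator
clean_record <- function(seed = 7) {
  gen <- generate_corpus(corpus_config(1, seed = seed))
  gen$records$record[[1]]
}

tmp_lexicon_file <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "lex.tsv")
  readr::write_tsv(rows, path)
  path
}
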