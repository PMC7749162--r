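#' Run the full metadata-quality audit over a corpus
#'
#' Applies every audit stage in a single pass over the records:
#' simple-type validation, enumerated-value validation, FDAAA801
#' completeness (interventional records only), eligibility-criteria
#' classification, and (when lexicons are supplied) condition and
#' intervention lexicon coverage. Output is deterministic for a fixed
#' corpus.
#'
#' @param x A `ctg_corpus` tibble, a list of `trial_record`s, or a path
#'   to a corpus directory/zip.
#' @param registry A field registry.
#' @param lexicons Optional lexicon(s) for coverage analysis.
#' @param restrict_to Optional source-id subset for coverage.
#' @param progress_every Log a record counter to standard error every
#'   this many records; `0` disables logging.
#' @return A list of class `ctg_audit_summary`: `overview`, `findings`
#'   (per-record findings tibble), `simple_type` and `enumerated`
#'   per-field tallies, `completeness` (per-record reports),
#'   `missing_by_era`, `missing_by_agency`, `pi_partition`,
#'   `contact_summary`, `criteria` (per-record classes), `criteria_table`,
#'   and `coverage` tables.
#' @export
run_audit <- function(x, registry = ctg_registry(), lexicons = NULL,
                      restrict_to = NULL, progress_every = 0) {
  if (is.character(x)) x <- read_trial_corpus(x)
  records <- as_record_list(x)
  n <- length(records)

  findings <- list()
  reports <- list()
  criteria <- list()
  for (i in seq_len(n)) {
    rec <- records[[i]]
    findings[[length(findings) + 1]] <- validate_simple(rec, registry)
    findings[[length(findings) + 1]] <- validate_enumerated(rec, registry)
    if (identical(rec$study_type, "Interventional")) {
      reports[[length(reports) + 1]] <- audit_completeness(rec, registry)
    }
    criteria[[length(criteria) + 1]] <- mutate(
      classify_criteria(rec$eligibility$criteria_text),
      record_id = rec$record_id, .before = 1)
    if (progress_every > 0 && i %% progress_every == 0) {
      message("audited ", i, "/", n, " records")
    }
  }
  findings <- bind_rows(c(list(empty_findings()), findings))
  criteria_proto <- tibble(
    record_id = character(), format_class = character(),
    multi_group_suspected = logical(), inclusion = list(),
    exclusion = list(), error_codes = list())
  criteria <- bind_rows(c(list(criteria_proto), criteria))
  reports <- if (length(reports) > 0) bind_rows(reports) else NULL

  simple_fields <- registry$dictionary_name[
    registry$value_kind %in% c("boolean", "integer", "date", "age")]
  simple_type <- findings %>%
    filter(.data$code == "TYPE_MISMATCH") %>%
    count(.data$dictionary_name, name = "violations") %>%
    tidyr::complete(dictionary_name = simple_fields,
                    fill = list(violations = 0L)) %>%
    arrange(.data$dictionary_name)

  enum_fields <- registry$dictionary_name[registry$value_kind == "enumerated"]
  enumerated <- findings %>%
    filter(.data$code == "ROGUE_VALUE") %>%
    group_by(.data$dictionary_name) %>%
    summarise(rogue = dplyr::n(),
              example_values = paste(sort(unique(.data$observed)),
                                     collapse = "; "),
              .groups = "drop") %>%
    tidyr::complete(dictionary_name = enum_fields,
                    fill = list(rogue = 0L, example_values = "")) %>%
    arrange(.data$dictionary_name)

  criteria_table <- criteria %>%
    count(.data$format_class, name = "records") %>%
    tidyr::complete(
      format_class = c("correct", "headers_only", "malformed_headers",
                       "missing"),
      fill = list(records = 0L)) %>%
    mutate(pct = round(pct_of(.data$records, n), 1))
  n_multi <- sum(criteria$multi_group_suspected &
                   criteria$format_class %in% c("headers_only",
                                                "malformed_headers"))
  n_reviewable <- sum(criteria$format_class %in% c("headers_only",
                                                   "malformed_headers"))
  multi_group <- if (n_reviewable > 0) {
    extrapolate(n_multi, n_reviewable, n_reviewable)
  } else NULL

  pi_partition <- if (!is.null(reports)) {
    reports %>%
      count(.data$pi_category, name = "records") %>%
      tidyr::complete(pi_category = c("no_pi", "rp_investigator_only",
                                      "official_with_nonscientific_rp", "both"),
                      fill = list(records = 0L)) %>%
      mutate(pct = round(pct_of(.data$records, nrow(reports))))
  } else NULL

  contact_summary <- if (!is.null(reports)) {
    details <- audit_contact_details(records)
    mutate(details,
           n_records = nrow(reports),
           no_overall_contact = sum(!reports$overall_contact_present),
           contact_rule_unsatisfied = sum(!reports$contact_rule_satisfied))
  } else NULL

  coverage <- NULL
  if (!is.null(lexicons)) {
    coverage <- list(
      condition = coverage_by_stratum(records, "condition", lexicons,
                                      restrict_to = restrict_to),
      intervention = coverage_by_stratum(records, "intervention", lexicons,
                                         stratifier = "intervention_type",
                                         restrict_to = restrict_to)
    )
  }

  structure(list(
    overview = tibble(n_records = n,
                      n_interventional = if (is.null(reports)) 0L
                                         else nrow(reports)),
    findings = findings,
    simple_type = simple_type,
    enumerated = enumerated,
    completeness = reports,
    missing_by_era = if (!is.null(reports))
      summarize_completeness(reports, "era") else NULL,
    missing_by_agency = if (!is.null(reports))
      summarize_completeness(reports, "agency_class") else NULL,
    pi_partition = pi_partition,
    contact_summary = contact_summary,
    criteria = criteria,
    criteria_table = criteria_table,
    multi_group = multi_group,
    coverage = coverage
  ), class = "ctg_audit_summary")
}

#' @export
print.ctg_audit_summary <- function(x, ...) {
  ov <- x$overview
  cat("<ctg_audit_summary> ", ov$n_records, " records (",
      ov$n_interventional, " interventional)\n", sep = "")
  cat("  findings: ", nrow(x$findings), " (",
      sum(x$findings$severity != "note"), " problem-level)\n", sep = "")
  cat("  criteria classes: ",
      paste(x$criteria_table$format_class, x$criteria_table$records,
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Render an audit summary to files
#'
#' Writes one file per summary table. Delimited output uses
#' tab-separated values with the criteria-class table's percentages at
#' one decimal place and other percentages as integers, mirroring how
#' such registry audit tables are conventionally printed; JSON output
#' serializes the same tables. File bytes are deterministic for a fixed
#' summary.
#'
#' @param summary A `ctg_audit_summary`.
#' @param dir Destination directory.
#' @param format `"delimited"` or `"json"`.
#' @return Character vector of written file paths, invisibly.
#' @export
render_audit <- function(summary, dir, format = c("delimited", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("Cannot create output directory '", dir, "'."),
          class = "ctg_io_error")
  }
  tables <- list(
    overview = summary$overview,
    simple_type = summary$simple_type,
    enumerated = summary$enumerated,
    missing_by_era = round_pct_cols(summary$missing_by_era, 0),
    missing_by_agency = round_pct_cols(summary$missing_by_agency, 0),
    pi_partition = summary$pi_partition,
    contact_summary = summary$contact_summary,
    criteria_table = round_pct_cols(summary$criteria_table, 1),
    coverage_condition = round_pct_cols(summary$coverage$condition, 0),
    coverage_intervention = round_pct_cols(summary$coverage$intervention, 0)
  )
  tables <- compact(tables)
  written <- character()
  for (nm in names(tables)) {
    if (format == "delimited") {
      path <- file.path(dir, paste0(nm, ".tsv"))
      readr::write_tsv(tables[[nm]], path, progress = FALSE)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(tables[[nm]], path, dataframe = "rows", na = "null",
                           digits = NA)
    }
    written <- c(written, path)
  }
  invisible(written)
}

round_pct_cols <- function(tbl, digits) {
  if (is.null(tbl)) return(NULL)
  pct_cols <- grep("^pct", names(tbl), value = TRUE)
  for (col in pct_cols) tbl[[col]] <- round(tbl[[col]], digits)
  tbl
}
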