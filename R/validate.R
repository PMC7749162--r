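# Simple-type grammars for the registry dialect. The printed dictionary
# patterns are typeset with missing spaces (all printed examples, e.g.
# "January 3, 2004" and "2 Years", contain them), so the grammars below
# require exactly the spacing the examples show.
ctg_grammars <- local({
  months <- paste(month.name, collapse = "|")
  day <- "([1-9]|[12][0-9]|3[01])"
  list(
    boolean = "^(Yes|No)$",
    integer = "^[0-9]+$",
    date = sprintf("^(Unknown|(%s)( %s)?, [12][0-9]{3})$", months, day),
    age = "^(N/A|[1-9][0-9]* (Years?|Months?|Weeks?|Days?|Hours?|Minutes?))$"
  )
})

ctg_date_attr_values <- c("Actual", "Anticipated", "Estimate")

# Fixed age-unit conversion table, in minutes.
ctg_age_minutes <- c(Year = 525600, Month = 43800, Week = 10080,
                     Day = 1440, Hour = 60, Minute = 1)

finding <- function(record_id, dictionary_name, severity, code,
                    observed = NA_character_, detail = "") {
  tibble(record_id = record_id, dictionary_name = dictionary_name,
         severity = severity, code = code,
         observed = observed, detail = detail)
}

empty_findings <- function() {
  tibble(record_id = character(), dictionary_name = character(),
         severity = character(), code = character(),
         observed = character(), detail = character())
}

field_occurrences <- function(record, xml_path) {
  record$raw_values[record$raw_values$xml_path == xml_path, , drop = FALSE]
}

#' Validate simple-typed fields of one record
#'
#' Checks every occurrence of every Boolean, integer, date and age field
#' against its grammar: Booleans must be exactly "Yes" or "No"; integers
#' must be unsigned decimal integers; dates must be "Unknown" or a month
#' name with an optional day (1-31) and a four-digit year ("January 3,
#' 2004"; "March, 2005"), with an optional Actual/Anticipated/Estimate
#' attribute; ages must be "N/A" or a positive integer (no leading zero)
#' followed by one space and a unit word. Violations become findings of
#' code `TYPE_MISMATCH`; a fully conformant record yields no rows.
#'
#' @param record A `trial_record`.
#' @param registry A field registry from [ctg_registry()].
#' @return A findings tibble (`record_id`, `dictionary_name`, `severity`,
#'   `code`, `observed`, `detail`); zero rows when all values conform.
#' @examples
#' rec <- read_trial_record(
#'   "<clinical_study><id_info><nct_id>NCT1</nct_id></id_info>
#'    <study_type>Interventional</study_type>
#'    <start_date>January 3, 2004</start_date></clinical_study>")
#' validate_simple(rec, ctg_registry())
#' @export
validate_simple <- function(record, registry = ctg_registry()) {
  specs <- registry[registry$value_kind %in% names(ctg_grammars), ]
  out <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    occ <- field_occurrences(record, spec$xml_path)
    if (nrow(occ) == 0) next
    rx <- ctg_grammars[[spec$value_kind]]
    for (j in seq_len(nrow(occ))) {
      val <- str_trim(occ$value[j])
      if (!grepl(rx, val)) {
        out[[length(out) + 1]] <- finding(
          record$record_id, spec$dictionary_name, "error", "TYPE_MISMATCH",
          observed = occ$value[j],
          detail = paste0("Value does not match the ", spec$value_kind,
                          " grammar."))
      } else if (spec$value_kind == "date" && !is.na(occ$attr_type[j]) &&
                 !occ$attr_type[j] %in% ctg_date_attr_values) {
        out[[length(out) + 1]] <- finding(
          record$record_id, spec$dictionary_name, "error", "TYPE_MISMATCH",
          observed = occ$attr_type[j],
          detail = "Date type attribute must be Actual, Anticipated or Estimate.")
      }
    }
  }
  if (length(out) == 0) empty_findings() else bind_rows(out)
}

#' Normalize an age value to a common unit
#'
#' Parses a value matching the age grammar into magnitude and unit, and
#' computes a minutes-equivalent under a fixed conversion (Year = 525,600;
#' Month = 43,800; Week = 10,080; Day = 1,440; Hour = 60; Minute = 1), so
#' that equivalent ages written with different units ("2 Years",
#' "24 Months") compare equal. "N/A" maps to a not-applicable unit with no
#' minutes-equivalent.
#'
#' @param raw An age string matching the grammar.
#' @return One-row tibble: `raw`, `magnitude`, `unit`,
#'   `minutes_equivalent` (`NA` for "N/A").
#' @examples
#' normalize_age("2 Years")$minutes_equivalent ==
#'   normalize_age("24 Months")$minutes_equivalent
#' @export
normalize_age <- function(raw) {
  val <- str_trim(raw)
  if (!grepl(ctg_grammars$age, val)) {
    abort(paste0("'", raw, "' does not match the age grammar."),
          class = "ctg_value_error")
  }
  if (val == "N/A") {
    return(tibble(raw = raw, magnitude = NA_integer_,
                  unit = "not_applicable",
                  minutes_equivalent = NA_real_))
  }
  m <- str_match(val, "^([1-9][0-9]*) ([A-Za-z]+)$")
  magnitude <- as.integer(m[2])
  unit <- sub("s$", "", m[3])
  tibble(raw = raw, magnitude = magnitude, unit = unit,
         minutes_equivalent = magnitude * ctg_age_minutes[[unit]])
}

# Parses a record-form masking value: a Single/Double/Triple/Quadruple
# count word followed by a parenthesised role list. Returns NULL when the
# value is not in record form at all, otherwise a list with the roles and
# whether the count word agrees with the number of roles.
parse_masking <- function(value, roles_allowed) {
  m <- str_match(str_trim(value),
                 "^(Single|Double|Triple|Quadruple)\\s*\\(([^()]*)\\)$")
  if (is.na(m[1])) return(NULL)
  count <- match(m[2], c("Single", "Double", "Triple", "Quadruple"))
  roles <- str_trim(str_split(m[3], ",")[[1]])
  roles <- roles[roles != ""]
  list(
    count_word = m[2], count = count, roles = roles,
    roles_valid = length(roles) > 0 && all(roles %in% roles_allowed),
    count_consistent = length(roles) == count
  )
}

#' Validate enumerated fields of one record
#'
#' Checks every occurrence of the dictionary's sixteen enumerated-value
#' fields against the permitted set. Values outside the set yield
#' `ROGUE_VALUE` warnings. For the two fields whose record syntax differs
#' from the dictionary's printed set -- *interventional study model*
#' ("Parallel Group Assignment" rather than "Parallel") and *masking*
#' ("Double(Participant, Care Provider)" rather than a bare role list) --
#' valid record-form values are accepted and a `FORMAT_VARIANT` note
#' records the divergence. Matching is exact and case-sensitive after
#' trimming surrounding whitespace.
#'
#' @inheritParams validate_simple
#' @return A findings tibble; zero rows for a fully conformant record
#'   containing no record-form variants.
#' @export
validate_enumerated <- function(record, registry = ctg_registry()) {
  specs <- registry[registry$value_kind == "enumerated", ]
  out <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    occ <- field_occurrences(record, spec$xml_path)
    if (nrow(occ) == 0) next
    dict_set <- spec$allowed_values_dictionary[[1]]
    record_set <- spec$allowed_values_record_form[[1]]
    for (j in seq_len(nrow(occ))) {
      val <- str_trim(occ$value[j])
      if (identical(record_set, "pattern:masking")) {
        if (val %in% dict_set) next  # "No Masking" is shared syntax
        parsed <- parse_masking(val, dict_set)
        if (!is.null(parsed) && parsed$roles_valid && parsed$count_consistent) {
          out[[length(out) + 1]] <- finding(
            record$record_id, spec$dictionary_name, "note", "FORMAT_VARIANT",
            observed = occ$value[j],
            detail = "Record-form masking syntax; dictionary lists bare roles.")
        } else {
          out[[length(out) + 1]] <- finding(
            record$record_id, spec$dictionary_name, "warning", "ROGUE_VALUE",
            observed = occ$value[j],
            detail = "Value is not in the dictionary's permitted set.")
        }
      } else if (length(record_set) > 0) {
        if (val %in% dict_set) next
        if (val %in% record_set) {
          out[[length(out) + 1]] <- finding(
            record$record_id, spec$dictionary_name, "note", "FORMAT_VARIANT",
            observed = occ$value[j],
            detail = "Record-form syntax diverges from the dictionary value.")
        } else {
          out[[length(out) + 1]] <- finding(
            record$record_id, spec$dictionary_name, "warning", "ROGUE_VALUE",
            observed = occ$value[j],
            detail = "Value is not in the dictionary's permitted set.")
        }
      } else if (!val %in% dict_set) {
        out[[length(out) + 1]] <- finding(
          record$record_id, spec$dictionary_name, "warning", "ROGUE_VALUE",
          observed = occ$value[j],
          detail = "Value is not in the dictionary's permitted set.")
      }
    }
  }
  if (length(out) == 0) empty_findings() else bind_rows(out)
}

#' Map a record-form enumerated value to dictionary form
#'
#' For the *interventional study model*, strips the record syntax's
#' trailing "Assignment" (and the "Group" that the record form adds to
#' "Parallel"); for *masking*, returns the set of masked roles, discarding
#' the Single/Double/Triple/Quadruple count word after checking it equals
#' the number of roles; for every other enumerated field the record form
#' already is the dictionary form.
#'
#' @param field Dictionary name of an enumerated field.
#' @param observed A valid record-form value for that field.
#' @param registry A field registry.
#' @return For masking, the character vector of masked roles; otherwise
#'   the dictionary-form value.
#' @examples
#' canonicalize_enumerated("interventional study model",
#'                         "Parallel Group Assignment")
#' canonicalize_enumerated("masking", "Single(Investigator)")
#' @export
canonicalize_enumerated <- function(field, observed,
                                    registry = ctg_registry()) {
  spec <- registry_lookup(registry, field, "dictionary")
  if (spec$value_kind != "enumerated") {
    abort(paste0("'", field, "' is not an enumerated field."),
          class = "ctg_value_error")
  }
  val <- str_trim(observed)
  dict_set <- spec$allowed_values_dictionary[[1]]
  record_set <- spec$allowed_values_record_form[[1]]

  if (identical(record_set, "pattern:masking")) {
    if (val %in% dict_set) return(val)
    parsed <- parse_masking(val, dict_set)
    if (is.null(parsed) || !parsed$roles_valid) {
      abort(paste0("'", observed, "' is not a valid masking value."),
            class = "ctg_canonicalization_error")
    }
    if (!parsed$count_consistent) {
      abort(paste0("Masking count word '", parsed$count_word, "' implies ",
                   parsed$count, " role(s) but ", length(parsed$roles),
                   " are listed."),
            class = "ctg_canonicalization_error")
    }
    return(parsed$roles)
  }

  if (val %in% dict_set) return(val)
  if (length(record_set) > 0 && val %in% record_set) {
    canon <- str_remove(val, " Assignment$")
    if (canon == "Parallel Group") canon <- "Parallel"
    if (!canon %in% dict_set) {
      abort(paste0("Cannot canonicalize '", observed, "'."),
            class = "ctg_canonicalization_error")
    }
    return(canon)
  }
  abort(paste0("'", observed, "' is not a valid value for '", field, "'."),
        class = "ctg_canonicalization_error")
}

#' Export findings as JSON Lines
#'
#' @param findings A findings tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_findings_jsonl <- function(findings, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(findings))) {
    writeLines(jsonlite::toJSON(as.list(findings[i, ]), auto_unbox = TRUE,
                                na = "null"), con)
  }
  invisible(path)
}
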