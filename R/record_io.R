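#' Read one trial-registration record from public-dialect XML
#'
#' Parses a record in the ClinicalTrials.gov public-XML dialect into a typed
#' in-memory representation. No value coercion or validation happens here:
#' all values, including dates, are stored as raw text (many date-parsing
#' libraries behave unpredictably on day-absent dates such as "March, 2005",
#' so interpretation is deferred to the validation stage). Every leaf
#' element of the document, including elements the audit does not promote to
#' typed fields, is preserved in `raw_values` in document order.
#'
#' @param x A file path, an XML string, or an `xml2::xml_document`.
#' @return A `trial_record`: a list with the record identity, study type,
#'   design, conditions and interventions, eligibility text, parties,
#'   contacts, outcome measures and a `raw_values` tibble
#'   (`xml_path`, `value`, `attr_type`).
#' @examples
#' rec <- read_trial_record(
#'   "<clinical_study><id_info><nct_id>NCT00000001</nct_id></id_info>
#'    <study_type>Interventional</study_type></clinical_study>")
#' rec$study_type
#' @export
read_trial_record <- function(x) {
  doc <- as_xml_doc(x)
  root <- xml2::xml_root(doc)

  record_id <- xpath1(root, ".//nct_id")
  if (is.na(record_id)) {
    abort("Record has no <nct_id> identifier.", class = "ctg_structure_error")
  }

  leaves <- xml2::xml_find_all(root, ".//*[not(*)]")
  raw_values <- tibble(
    xml_path = map_chr(leaves, rel_path, root = root),
    value = xml2::xml_text(leaves),
    attr_type = map_chr(leaves, function(n) {
      a <- xml2::xml_attr(n, "type")
      if (is.na(a)) NA_character_ else a
    })
  )

  date_field <- function(path) {
    node <- xml2::xml_find_first(root, paste0("./", path))
    if (inherits(node, "xml_missing")) {
      list(value = NA_character_, type = NA_character_)
    } else {
      list(value = xml2::xml_text(node), type = xml2::xml_attr(node, "type"))
    }
  }

  interventions <- map_dfr(
    xml2::xml_find_all(root, "./intervention"),
    function(n) tibble(
      intervention_type = xpath1(n, "./intervention_type"),
      name = xpath1(n, "./intervention_name"),
      description = xpath1(n, "./description")
    )
  )
  if (nrow(interventions) == 0) {
    interventions <- tibble(intervention_type = character(),
                            name = character(), description = character())
  }

  arms <- map_dfr(
    xml2::xml_find_all(root, "./arm_group"),
    function(n) tibble(
      label = xpath1(n, "./arm_group_label"),
      arm_type = xpath1(n, "./arm_group_type"),
      description = xpath1(n, "./description")
    )
  )
  if (nrow(arms) == 0) {
    arms <- tibble(label = character(), arm_type = character(),
                   description = character())
  }

  officials <- map_dfr(
    xml2::xml_find_all(root, "./overall_official"),
    function(n) tibble(
      last_name = xpath1(n, "./last_name"),
      role = xpath1(n, "./role"),
      affiliation = xpath1(n, "./affiliation")
    )
  )
  if (nrow(officials) == 0) {
    officials <- tibble(last_name = character(), role = character(),
                        affiliation = character())
  }

  contact_at <- function(node, path) {
    n <- xml2::xml_find_first(node, path)
    if (inherits(n, "xml_missing")) return(NULL)
    list(last_name = xpath1(n, "./last_name"),
         phone = xpath1(n, "./phone"),
         email = xpath1(n, "./email"))
  }

  locations <- map_dfr(
    xml2::xml_find_all(root, "./location"),
    function(n) {
      ct <- contact_at(n, "./contact")
      tibble(
        facility_name = xpath1(n, "./facility/name"),
        city = xpath1(n, "./facility/address/city"),
        country = xpath1(n, "./facility/address/country"),
        status = xpath1(n, "./status"),
        contact_last_name = if (is.null(ct)) NA_character_ else ct$last_name,
        contact_phone = if (is.null(ct)) NA_character_ else ct$phone,
        contact_email = if (is.null(ct)) NA_character_ else ct$email,
        has_contact = !is.null(ct)
      )
    }
  )
  if (nrow(locations) == 0) {
    locations <- tibble(
      facility_name = character(), city = character(), country = character(),
      status = character(), contact_last_name = character(),
      contact_phone = character(), contact_email = character(),
      has_contact = logical()
    )
  }

  outcome_rows <- function(tag, rank) {
    map_dfr(
      xml2::xml_find_all(root, paste0("./", tag)),
      function(n) tibble(
        rank = rank,
        measure = xpath1(n, "./measure"),
        time_frame = xpath1(n, "./time_frame"),
        description = xpath1(n, "./description")
      )
    )
  }
  outcomes <- bind_rows(outcome_rows("primary_outcome", "primary"),
                        outcome_rows("secondary_outcome", "secondary"))
  if (nrow(outcomes) == 0) {
    outcomes <- tibble(rank = character(), measure = character(),
                       time_frame = character(), description = character())
  }

  bool_paths <- c(
    "has_expanded_access", "oversight_info/has_dmc",
    "oversight_info/is_fda_regulated_drug",
    "oversight_info/is_fda_regulated_device",
    "oversight_info/is_unapproved_device", "oversight_info/is_ppsd",
    "oversight_info/is_us_export", "expanded_access_type_individual",
    "expanded_access_type_intermediate", "expanded_access_type_treatment",
    "eligibility/gender_based"
  )
  booleans <- tibble(
    xml_path = bool_paths,
    value = map_chr(bool_paths, function(p) xpath1(root, paste0("./", p)))
  ) %>% filter(!is.na(.data$value))

  sd <- date_field("start_date")
  cd <- date_field("completion_date")
  pcd <- date_field("primary_completion_date")
  enr_node <- xml2::xml_find_first(root, "./enrollment")

  record <- structure(list(
    record_id = record_id,
    secondary_ids = xml2::xml_text(
      xml2::xml_find_all(root, "./id_info/secondary_id")),
    study_type = xpath1(root, "./study_type"),
    brief_title = xpath1(root, "./brief_title"),
    brief_summary = xpath1(root, "./brief_summary/textblock"),
    official_title = xpath1(root, "./official_title"),
    overall_status = xpath1(root, "./overall_status"),
    why_stopped = xpath1(root, "./why_stopped"),
    start_date_raw = sd$value, start_date_type = sd$type,
    completion_date_raw = cd$value, completion_date_type = cd$type,
    primary_completion_date_raw = pcd$value,
    primary_completion_date_type = pcd$type,
    verification_date_raw = xpath1(root, "./verification_date"),
    phase = xpath1(root, "./phase"),
    enrollment_raw = if (inherits(enr_node, "xml_missing")) NA_character_
                     else xml2::xml_text(enr_node),
    enrollment_type = if (inherits(enr_node, "xml_missing")) NA_character_
                      else xml2::xml_attr(enr_node, "type"),
    number_of_arms_raw = xpath1(root, "./number_of_arms"),
    number_of_groups_raw = xpath1(root, "./number_of_groups"),
    agency = xpath1(root, "./sponsors/lead_sponsor/agency"),
    agency_class = xpath1(root, "./sponsors/lead_sponsor/agency_class"),
    conditions = xml2::xml_text(xml2::xml_find_all(root, "./condition")),
    interventions = interventions,
    eligibility = list(
      criteria_text = xpath1(root, "./eligibility/criteria/textblock"),
      gender = xpath1(root, "./eligibility/gender"),
      minimum_age = xpath1(root, "./eligibility/minimum_age"),
      maximum_age = xpath1(root, "./eligibility/maximum_age"),
      healthy_volunteers = xpath1(root, "./eligibility/healthy_volunteers"),
      sampling_method = xpath1(root, "./eligibility/sampling_method"),
      study_pop = xpath1(root, "./eligibility/study_pop/textblock")
    ),
    design = list(
      allocation = xpath1(root, "./study_design_info/allocation"),
      intervention_model = xpath1(root, "./study_design_info/intervention_model"),
      masking = xpath1(root, "./study_design_info/masking"),
      primary_purpose = xpath1(root, "./study_design_info/primary_purpose"),
      observational_model = xpath1(root, "./study_design_info/observational_model"),
      time_perspective = xpath1(root, "./study_design_info/time_perspective"),
      arms = arms
    ),
    parties = list(
      responsible_party_type = xpath1(root, "./responsible_party/responsible_party_type"),
      rp_investigator_full_name = xpath1(root, "./responsible_party/investigator_full_name"),
      rp_investigator_affiliation = xpath1(root, "./responsible_party/investigator_affiliation"),
      rp_investigator_title = xpath1(root, "./responsible_party/investigator_title"),
      overall_officials = officials
    ),
    contacts = list(
      overall_contact = contact_at(root, "./overall_contact"),
      locations = locations
    ),
    outcomes = outcomes,
    booleans = booleans,
    raw_values = raw_values
  ), class = "trial_record")
  record
}

as_xml_doc <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      abort(paste0("Not well-formed XML: ", conditionMessage(e)),
            class = "ctg_parse_error")
    }
  )
}

xpath1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
}

rel_path <- function(node, root) {
  p <- xml2::xml_path(node)
  p <- gsub("\\[[0-9]+\\]", "", p)
  p <- sub(paste0("^/", xml2::xml_name(root), "/"), "", p)
  p
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record> ", x$record_id, " (", x$study_type %||% "?", ")\n",
      sep = "")
  cat("  ", nrow(x$raw_values), " raw values; ",
      length(x$conditions), " condition(s); ",
      nrow(x$interventions), " intervention(s); ",
      nrow(x$contacts$locations), " location(s)\n", sep = "")
  invisible(x)
}

#' Write a trial record back to public-dialect XML
#'
#' Emits the record's retained (typed) fields with the public-dialect
#' element names in a fixed element order, so output bytes are
#' deterministic for a given record. Empty collections emit no elements.
#'
#' @param record A `trial_record`.
#' @param path Optional file path; when given the document is also written
#'   to disk.
#' @return The `xml2::xml_document`, invisibly when `path` is given.
#' @export
write_trial_record <- function(record, path = NULL) {
  doc <- xml2::xml_new_root("clinical_study")

  add_leaf <- function(parent, name, value, type = NULL) {
    if (is.null(value) || length(value) == 0 || all(is.na(value))) return(invisible())
    node <- xml2::xml_add_child(parent, name)
    xml2::xml_text(node) <- as.character(value)
    if (!is.null(type) && !is.na(type)) xml2::xml_attr(node, "type") <- type
    invisible(node)
  }

  id_info <- xml2::xml_add_child(doc, "id_info")
  add_leaf(id_info, "nct_id", record$record_id)
  for (sid in record$secondary_ids %||% character()) {
    add_leaf(id_info, "secondary_id", sid)
  }
  add_leaf(doc, "brief_title", record$brief_title)
  add_leaf(doc, "official_title", record$official_title)
  if (!is.na(record$brief_summary %||% NA)) {
    bs <- xml2::xml_add_child(doc, "brief_summary")
    add_leaf(bs, "textblock", record$brief_summary)
  }

  if (!is.na(record$agency %||% NA) || !is.na(record$agency_class %||% NA)) {
    sponsors <- xml2::xml_add_child(doc, "sponsors")
    lead <- xml2::xml_add_child(sponsors, "lead_sponsor")
    add_leaf(lead, "agency", record$agency)
    add_leaf(lead, "agency_class", record$agency_class)
  }

  add_leaf(doc, "overall_status", record$overall_status)
  add_leaf(doc, "why_stopped", record$why_stopped)
  add_leaf(doc, "start_date", record$start_date_raw, record$start_date_type)
  add_leaf(doc, "completion_date", record$completion_date_raw,
           record$completion_date_type)
  add_leaf(doc, "primary_completion_date", record$primary_completion_date_raw,
           record$primary_completion_date_type)
  add_leaf(doc, "verification_date", record$verification_date_raw)
  add_leaf(doc, "phase", record$phase)
  add_leaf(doc, "study_type", record$study_type)

  oversight_paths <- record$booleans$xml_path[
    startsWith(record$booleans$xml_path, "oversight_info/")]
  if (length(oversight_paths) > 0) {
    ov <- xml2::xml_add_child(doc, "oversight_info")
    for (p in oversight_paths) {
      add_leaf(ov, sub("^oversight_info/", "", p),
               record$booleans$value[record$booleans$xml_path == p])
    }
  }
  for (p in c("has_expanded_access", "expanded_access_type_individual",
              "expanded_access_type_intermediate",
              "expanded_access_type_treatment")) {
    if (p %in% record$booleans$xml_path) {
      add_leaf(doc, p, record$booleans$value[record$booleans$xml_path == p])
    }
  }

  d <- record$design
  if (any(!is.na(c(d$allocation, d$intervention_model, d$masking,
                   d$primary_purpose, d$observational_model,
                   d$time_perspective)))) {
    sdi <- xml2::xml_add_child(doc, "study_design_info")
    add_leaf(sdi, "allocation", d$allocation)
    add_leaf(sdi, "intervention_model", d$intervention_model)
    add_leaf(sdi, "primary_purpose", d$primary_purpose)
    add_leaf(sdi, "observational_model", d$observational_model)
    add_leaf(sdi, "time_perspective", d$time_perspective)
    add_leaf(sdi, "masking", d$masking)
  }

  for (i in seq_len(nrow(record$outcomes))) {
    row <- record$outcomes[i, ]
    tag <- if (row$rank == "primary") "primary_outcome" else "secondary_outcome"
    node <- xml2::xml_add_child(doc, tag)
    add_leaf(node, "measure", row$measure)
    add_leaf(node, "time_frame", row$time_frame)
    add_leaf(node, "description", row$description)
  }

  add_leaf(doc, "number_of_arms", record$number_of_arms_raw)
  add_leaf(doc, "number_of_groups", record$number_of_groups_raw)
  add_leaf(doc, "enrollment", record$enrollment_raw, record$enrollment_type)
  for (cond in record$conditions) add_leaf(doc, "condition", cond)

  for (i in seq_len(nrow(record$design$arms))) {
    row <- record$design$arms[i, ]
    node <- xml2::xml_add_child(doc, "arm_group")
    add_leaf(node, "arm_group_label", row$label)
    add_leaf(node, "arm_group_type", row$arm_type)
    add_leaf(node, "description", row$description)
  }

  for (i in seq_len(nrow(record$interventions))) {
    row <- record$interventions[i, ]
    node <- xml2::xml_add_child(doc, "intervention")
    add_leaf(node, "intervention_type", row$intervention_type)
    add_leaf(node, "intervention_name", row$name)
    add_leaf(node, "description", row$description)
  }

  e <- record$eligibility
  if (any(!is.na(unlist(e)))) {
    el <- xml2::xml_add_child(doc, "eligibility")
    if (!is.na(e$study_pop %||% NA)) {
      sp <- xml2::xml_add_child(el, "study_pop")
      add_leaf(sp, "textblock", e$study_pop)
    }
    add_leaf(el, "sampling_method", e$sampling_method)
    if (!is.na(e$criteria_text %||% NA)) {
      cr <- xml2::xml_add_child(el, "criteria")
      add_leaf(cr, "textblock", e$criteria_text)
    }
    add_leaf(el, "gender", e$gender)
    if ("eligibility/gender_based" %in% record$booleans$xml_path) {
      add_leaf(el, "gender_based", record$booleans$value[
        record$booleans$xml_path == "eligibility/gender_based"])
    }
    add_leaf(el, "minimum_age", e$minimum_age)
    add_leaf(el, "maximum_age", e$maximum_age)
    add_leaf(el, "healthy_volunteers", e$healthy_volunteers)
  }

  for (i in seq_len(nrow(record$parties$overall_officials))) {
    row <- record$parties$overall_officials[i, ]
    node <- xml2::xml_add_child(doc, "overall_official")
    add_leaf(node, "last_name", row$last_name)
    add_leaf(node, "role", row$role)
    add_leaf(node, "affiliation", row$affiliation)
  }

  oc <- record$contacts$overall_contact
  if (!is.null(oc)) {
    node <- xml2::xml_add_child(doc, "overall_contact")
    add_leaf(node, "last_name", oc$last_name)
    add_leaf(node, "phone", oc$phone)
    add_leaf(node, "email", oc$email)
  }

  p <- record$parties
  if (any(!is.na(c(p$responsible_party_type, p$rp_investigator_full_name,
                   p$rp_investigator_affiliation, p$rp_investigator_title)))) {
    rp <- xml2::xml_add_child(doc, "responsible_party")
    add_leaf(rp, "responsible_party_type", p$responsible_party_type)
    add_leaf(rp, "investigator_affiliation", p$rp_investigator_affiliation)
    add_leaf(rp, "investigator_full_name", p$rp_investigator_full_name)
    add_leaf(rp, "investigator_title", p$rp_investigator_title)
  }

  locs <- record$contacts$locations
  for (i in seq_len(nrow(locs))) {
    row <- locs[i, ]
    node <- xml2::xml_add_child(doc, "location")
    if (!is.na(row$facility_name) || !is.na(row$city) || !is.na(row$country)) {
      fac <- xml2::xml_add_child(node, "facility")
      add_leaf(fac, "name", row$facility_name)
      if (!is.na(row$city) || !is.na(row$country)) {
        addr <- xml2::xml_add_child(fac, "address")
        add_leaf(addr, "city", row$city)
        add_leaf(addr, "country", row$country)
      }
    }
    add_leaf(node, "status", row$status)
    if (isTRUE(row$has_contact)) {
      ct <- xml2::xml_add_child(node, "contact")
      add_leaf(ct, "last_name", row$contact_last_name)
      add_leaf(ct, "phone", row$contact_phone)
      add_leaf(ct, "email", row$contact_email)
    }
  }

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Read a corpus of trial-record XML files
#'
#' Reads every `.xml` file in a directory (or zip archive) in lexicographic
#' filename order, one record per file. Files that fail to parse do not
#' abort the read: they are collected into a parse-error table attached to
#' the result, and skipped entries produce a warning.
#'
#' @param path Directory or `.zip` archive of record files.
#' @param pattern Filename regular expression (default `\\.xml$`).
#' @return A tibble of class `ctg_corpus` with columns `file`, `record_id`
#'   and a `record` list-column of `trial_record` objects; the attribute
#'   `parse_errors` is a tibble (`file`, `message`) of failed files.
#' @export
read_trial_corpus <- function(path, pattern = "\\.xml$") {
  if (length(path) != 1 || !file.exists(path)) {
    abort(paste0("Cannot read corpus at '", path, "'."), class = "ctg_io_error")
  }
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("ctg_corpus_")
    dir.create(exdir)
    unzip(path, exdir = exdir)
    path <- exdir
  }
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                           recursive = TRUE))
  skipped <- setdiff(
    list.files(path, full.names = TRUE, recursive = TRUE), files)
  # corpus sidecar files written alongside the records are expected
  skipped <- skipped[!basename(skipped) %in%
                       c("ground_truth.json", "manifest.json")]
  if (length(skipped) > 0) {
    warn(paste0("Skipping ", length(skipped), " non-XML entr",
                if (length(skipped) == 1) "y" else "ies", " in corpus."))
  }
  records <- list()
  errors <- list()
  for (f in files) {
    res <- tryCatch(read_trial_record(f), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- tibble(file = basename(f),
                                             message = conditionMessage(res))
    } else {
      records[[length(records) + 1]] <- tibble(
        file = basename(f), record_id = res$record_id, record = list(res))
    }
  }
  out <- if (length(records) > 0) bind_rows(records) else
    tibble(file = character(), record_id = character(), record = list())
  attr(out, "parse_errors") <- if (length(errors) > 0) bind_rows(errors) else
    tibble(file = character(), message = character())
  class(out) <- c("ctg_corpus", class(out))
  out
}

#' Export trial records as JSON Lines
#'
#' One record per line, with the typed field set serialized as JSON. Meant
#' for debugging and downstream tooling, not as a round-trip format.
#'
#' @param records A `ctg_corpus` tibble or list of `trial_record`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_records_jsonl <- function(records, path) {
  records <- as_record_list(records)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    slim <- rec[setdiff(names(rec), "raw_values")]
    writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, na = "null",
                                dataframe = "rows"), con)
  }
  invisible(path)
}

as_record_list <- function(x) {
  if (inherits(x, "trial_record")) return(list(x))
  if (is_tibble(x) && "record" %in% names(x)) return(x$record)
  if (is.list(x)) return(x)
  abort("Expected a trial_record, a list of them, or a ctg_corpus tibble.")
}
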