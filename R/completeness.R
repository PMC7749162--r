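#' Parse a registry-dialect date
#'
#' Interprets a date written in the registry's grammar ("January 3, 2004",
#' "March, 2005", "Unknown"). Day-absent dates are imputed to the first of
#' the month for comparison purposes, and flagged, because the Final Rule
#' cutoff (January 18, 2017) makes a day-absent "January, 2017" ambiguous
#' between eras.
#'
#' @param raw Date text, or `NA`.
#' @return A list: `date` (a `Date`, or `NA` for "Unknown"/absent/
#'   non-conformant input), `day_imputed` (flag), `conformant` (flag).
#' @export
parse_ctg_date <- function(raw) {
  if (is.null(raw) || is.na(raw) || str_trim(raw) == "" ||
      str_trim(raw) == "Unknown") {
    return(list(date = as.Date(NA),
                day_imputed = FALSE,
                conformant = !is.null(raw) && !is.na(raw) &&
                  str_trim(raw) == "Unknown"))
  }
  val <- str_trim(raw)
  if (!grepl(ctg_grammars$date, val)) {
    return(list(date = as.Date(NA), day_imputed = FALSE, conformant = FALSE))
  }
  m <- str_match(val, "^([A-Za-z]+)( ([0-9]{1,2}))?, ([0-9]{4})$")
  month <- match(m[2], month.name)
  day_imputed <- is.na(m[4])
  day <- if (day_imputed) 1L else as.integer(m[4])
  list(date = as.Date(sprintf("%s-%02d-%02d", m[5], month, day)),
       day_imputed = day_imputed, conformant = TRUE)
}

#' Classify a record's Final Rule era
#'
#' The Final Rule's updated required-element definitions apply to trials
#' with start dates on or after 2017-01-18. Day-absent start dates compare
#' as the first of the month; "Unknown", absent, or grammar-violating
#' start dates yield `unknown_start_date`.
#'
#' @param record A `trial_record`, or a raw start-date string.
#' @return One of `"pre_final_rule"`, `"post_final_rule"`,
#'   `"unknown_start_date"`.
#' @examples
#' classify_era("January 17, 2017")
#' classify_era("January 18, 2017")
#' @export
classify_era <- function(record) {
  raw <- if (inherits(record, "trial_record")) record$start_date_raw else record
  parsed <- parse_ctg_date(raw)
  if (is.na(parsed$date)) return("unknown_start_date")
  if (parsed$date >= ctg_final_rule_date) "post_final_rule" else "pre_final_rule"
}

# Presence predicates for the audited field set, keyed by dictionary name.
# Each returns TRUE when the field is PRESENT for the record. A field with
# multiple permitted occurrences is present iff at least one occurrence is
# listed; composite sub-fields that attach to listed parents (outcome time
# frames, facility name/city/country, site status) are present iff every
# listed parent carries them.
ctg_presence_checks <- function() {
  has_path <- function(path) function(record) {
    nrow(field_occurrences(record, path)) > 0
  }
  list(
    "brief title" = has_path("brief_title"),
    "brief summary" = has_path("brief_summary/textblock"),
    "study phase" = has_path("phase"),
    "study type" = function(record) !is.na(record$study_type),
    "condition" = function(record) length(record$conditions) > 0,
    "intervention name" = has_path("intervention/intervention_name"),
    "intervention type" = has_path("intervention/intervention_type"),
    "eligibility criteria" = function(record) {
      txt <- record$eligibility$criteria_text
      !is.na(txt %||% NA) && str_trim(txt) != ""
    },
    "sex" = has_path("eligibility/gender"),
    "age limits" = function(record) {
      !is.na(record$eligibility$minimum_age %||% NA) &&
        !is.na(record$eligibility$maximum_age %||% NA)
    },
    "overall recruitment status" = function(record) !is.na(record$overall_status),
    "sponsor" = function(record) !is.na(record$agency),
    "responsible party type" = function(record) {
      !is.na(record$parties$responsible_party_type)
    },
    "secondary id" = has_path("id_info/secondary_id"),
    "official title" = function(record) !is.na(record$official_title),
    "primary purpose" = function(record) !is.na(record$design$primary_purpose),
    "interventional study model" = function(record) {
      !is.na(record$design$intervention_model)
    },
    "allocation" = function(record) !is.na(record$design$allocation),
    "masking" = function(record) !is.na(record$design$masking),
    "number of arms" = function(record) !is.na(record$number_of_arms_raw),
    "arm information" = function(record) nrow(record$design$arms) > 0,
    "intervention description" = function(record) {
      nrow(record$interventions) > 0 &&
        !anyNA(record$interventions$description)
    },
    "study start date" = function(record) !is.na(record$start_date_raw),
    "primary completion date" = function(record) {
      !is.na(record$primary_completion_date_raw)
    },
    "study completion date" = function(record) !is.na(record$completion_date_raw),
    "enrollment" = function(record) !is.na(record$enrollment_raw),
    "outcome measures" = function(record) {
      sum(record$outcomes$rank == "primary") > 0
    },
    "outcome time frame" = function(record) {
      prim <- record$outcomes[record$outcomes$rank == "primary", ]
      nrow(prim) == 0 || !anyNA(prim$time_frame)
    },
    "outcome description" = function(record) {
      prim <- record$outcomes[record$outcomes$rank == "primary", ]
      nrow(prim) == 0 || !anyNA(prim$description)
    },
    "accepts healthy volunteers" = function(record) {
      !is.na(record$eligibility$healthy_volunteers)
    },
    "why study stopped" = function(record) !is.na(record$why_stopped),
    "individual site status" = function(record) {
      locs <- record$contacts$locations
      nrow(locs) == 0 || !anyNA(locs$status)
    },
    "availability of expanded access" = has_path("has_expanded_access"),
    "facility information" = function(record) {
      nrow(record$contacts$locations) > 0
    },
    "facility name, city, or country" = function(record) {
      locs <- record$contacts$locations
      nrow(locs) == 0 ||
        !any(is.na(locs$facility_name) | is.na(locs$city) | is.na(locs$country))
    }
  )
}

# Audited fields whose absence is only tabulated when listed parents exist;
# they are skipped when the parent group is itself missing.
ctg_subfield_parents <- c(
  "outcome time frame" = "outcome measures",
  "outcome description" = "outcome measures",
  "facility name, city, or country" = "facility information",
  "individual site status" = "facility information"
)

# Fields whose requirement is conditional, with the registry predicate that
# activates them.
ctg_conditional_fields <- c(
  "why study stopped" = "cond_study_stopped",
  "individual site status" = "cond_has_locations"
)

#' Audit one interventional record for the FDAAA801 required fields
#'
#' Evaluates the 28 audited required fields (the 13 FDAAA801 fields that
#' are conditionally unknowable, internal, post-2017 additions, or
#' administrative are excluded). A field permitting multiple occurrences is
#' missing iff zero occurrences are listed. Conditionally required fields
#' (why study stopped; individual site status) are missing iff absent
#' *and* their condition is active. Fields that became required only with
#' the Final Rule (official title, why study stopped, study start date,
#' study completion date) are reported in `missing_recommended` rather
#' than `missing_required` for records whose start date precedes the
#' Final Rule's effective date, so era-agnostic missingness tabulations
#' remain possible. Contact information is satisfied either by an overall
#' contact for the trial or by a contact at every listed site.
#'
#' @param record A `trial_record` with `study_type` "Interventional"
#'   (completeness rules are defined only for interventional trials;
#'   anything else is an error).
#' @param registry A field registry.
#' @return A one-row tibble: `record_id`, `era`, `era_day_imputed`,
#'   `agency_class`, list-columns `missing_required`, `missing_conditional`
#'   and `missing_recommended`, `pi_category`, `overall_contact_present`,
#'   `all_sites_have_contact`, `contact_rule_satisfied`, `n_locations`.
#' @export
audit_completeness <- function(record, registry = ctg_registry()) {
  if (!identical(record$study_type, "Interventional")) {
    abort(paste0("Completeness is audited only for interventional records; ",
                 "got study type '", record$study_type %||% "<absent>", "'."),
          class = "ctg_precondition_error")
  }
  era <- classify_era(record)
  day_imputed <- parse_ctg_date(record$start_date_raw)$day_imputed

  checks <- ctg_presence_checks()
  missing <- names(checks)[!map_lgl(checks, function(f) isTRUE(f(record)))]

  # sub-fields of a missing parent group are not independently tabulated
  for (child in names(ctg_subfield_parents)) {
    if (ctg_subfield_parents[[child]] %in% missing) {
      missing <- setdiff(missing, child)
    }
  }

  conditional <- intersect(missing, names(ctg_conditional_fields))
  cond_active <- map_lgl(conditional, function(f) {
    pred <- ctg_condition_predicates[[ctg_conditional_fields[[f]]]]
    isTRUE(pred(record))
  })
  missing_conditional <- conditional[cond_active]
  missing <- setdiff(missing, conditional)

  # pre-Final-Rule records: the four recommended-only fields are missing
  # but not *required*-missing
  missing_recommended <- character()
  if (era != "post_final_rule") {
    missing_recommended <- intersect(missing, ctg_pre_rule_recommended)
    missing <- setdiff(missing, missing_recommended)
    pre_rule_cond <- intersect(missing_conditional, ctg_pre_rule_recommended)
    missing_recommended <- c(missing_recommended, pre_rule_cond)
    missing_conditional <- setdiff(missing_conditional, pre_rule_cond)
  }

  oc <- record$contacts$overall_contact
  overall_contact_present <- !is.null(oc) &&
    any(!is.na(c(oc$last_name, oc$phone, oc$email)))
  locs <- record$contacts$locations
  site_has_contact <- locs$has_contact &
    (!is.na(locs$contact_last_name) | !is.na(locs$contact_phone) |
       !is.na(locs$contact_email))
  all_sites_have_contact <- nrow(locs) > 0 && all(site_has_contact)

  tibble(
    record_id = record$record_id,
    era = era,
    era_day_imputed = day_imputed,
    agency_class = record$agency_class %||% NA_character_,
    missing_required = list(sort(missing)),
    missing_conditional = list(sort(missing_conditional)),
    missing_recommended = list(sort(missing_recommended)),
    pi_category = classify_pi(record),
    overall_contact_present = overall_contact_present,
    all_sites_have_contact = all_sites_have_contact,
    contact_rule_satisfied = overall_contact_present ||
      (nrow(locs) > 0 && all_sites_have_contact),
    n_locations = nrow(locs)
  )
}

#' Classify how a record designates its principal investigator
#'
#' A principal investigator may appear in the responsible-party element
#' (when the responsible party type is "Principal Investigator" or
#' "Sponsor-Investigator"), in the overall-official element, in both, or
#' in neither.
#'
#' @param record A `trial_record`.
#' @return One of `"no_pi"`, `"rp_investigator_only"`,
#'   `"official_with_nonscientific_rp"`, `"both"`.
#' @export
classify_pi <- function(record) {
  rp_is_investigator <- isTRUE(
    record$parties$responsible_party_type %in%
      c("Principal Investigator", "Sponsor-Investigator"))
  official_present <- nrow(record$parties$overall_officials) > 0
  if (rp_is_investigator && official_present) "both"
  else if (rp_is_investigator) "rp_investigator_only"
  else if (official_present) "official_with_nonscientific_rp"
  else "no_pi"
}

#' Count provided contact details and their missing sub-fields
#'
#' Tallies every contact detail provided anywhere in the corpus (overall
#' trial contacts and site-level contacts). A detail counts as provided
#' iff at least one of its sub-fields (name, phone, email) is present.
#'
#' @param records A `ctg_corpus` tibble or list of `trial_record`s.
#' @return One-row tibble: `n_contacts`, `n_missing_phone`,
#'   `n_missing_email`.
#' @export
audit_contact_details <- function(records) {
  records <- as_record_list(records)
  n <- 0L; no_phone <- 0L; no_email <- 0L
  tally <- function(last_name, phone, email) {
    if (any(!is.na(c(last_name, phone, email)))) {
      n <<- n + 1L
      if (is.na(phone)) no_phone <<- no_phone + 1L
      if (is.na(email)) no_email <<- no_email + 1L
    }
  }
  for (rec in records) {
    oc <- rec$contacts$overall_contact
    if (!is.null(oc)) tally(oc$last_name, oc$phone, oc$email)
    locs <- rec$contacts$locations
    for (i in seq_len(nrow(locs))) {
      if (isTRUE(locs$has_contact[i])) {
        tally(locs$contact_last_name[i], locs$contact_phone[i],
              locs$contact_email[i])
      }
    }
  }
  tibble(n_contacts = n, n_missing_phone = no_phone, n_missing_email = no_email)
}

#' Tabulate completeness reports into a missing-fields table
#'
#' Rolls per-record completeness reports up into a per-field table of
#' missing counts and percentages, split by Final Rule era (records with
#' unknown start dates are tabulated with the pre-rule column, the only
#' binning consistent with counting a missing start date itself) and
#' overall. Missingness is era-agnostic here: a recommended-only field
#' missing from a pre-rule record still counts as missing, as the
#' era-specific requirement status is a property of the requirement, not
#' of the observation.
#'
#' @param reports Row-bound output of [audit_completeness()].
#' @param by Either `"era"` (default) or `"agency_class"`.
#' @return A tibble with one row per audited field and missing counts and
#'   percentages per stratum plus overall.
#' @export
summarize_completeness <- function(reports, by = c("era", "agency_class")) {
  by <- match.arg(by)
  fields <- names(ctg_presence_checks())
  all_missing <- map(seq_len(nrow(reports)), function(i) {
    unique(c(reports$missing_required[[i]], reports$missing_conditional[[i]],
             reports$missing_recommended[[i]]))
  })
  stratum <- if (by == "era") {
    if_else(reports$era == "post_final_rule", "post_final_rule",
            "pre_final_rule")
  } else {
    if_else(is.na(reports$agency_class), "absent", reports$agency_class)
  }
  strata <- sort(unique(stratum))
  rows <- map_dfr(fields, function(f) {
    hit <- map_lgl(all_missing, function(m) f %in% m)
    row <- tibble(field = f, missing_all = sum(hit),
                  pct_all = pct_of(sum(hit), nrow(reports)))
    for (s in strata) {
      n_s <- sum(stratum == s)
      row[[paste0("missing_", s)]] <- sum(hit & stratum == s)
      row[[paste0("pct_", s)]] <- pct_of(sum(hit & stratum == s), n_s)
    }
    row
  })
  rows
}

pct_of <- function(count, denom) {
  if (denom == 0) 0 else 100 * count / denom
}
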