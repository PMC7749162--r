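# Word lists for synthetic record text. Names deliberately reproduce the
# registry's "full name and degrees inside the last-name field"
# irregularity, so downstream consumers must handle it.
ctg_person_names <- c(
  "Sarah Smith, M.D.", "James Lee, Ph.D.", "Maria Garcia, M.D., Ph.D.",
  "Wei Chen, M.D.", "Anna Kowalski, Dr. med.", "John Okafor, M.B.B.S.",
  "Priya Patel, M.D.", "Thomas Muller, M.D."
)
ctg_sponsor_names <- list(
  "NIH" = c("National Cancer Institute", "National Heart, Lung, and Blood Institute"),
  "U.S. Fed" = c("Department of Veterans Affairs", "Centers for Disease Control and Prevention"),
  "Industry" = c("Helix Therapeutics", "Borealis Pharma", "Cardinal Devices"),
  "Other" = c("University Hospital Basel", "Karolinska Institutet",
              "Massachusetts General Hospital", "University of Toronto")
)
ctg_cities <- c("Boston", "Houston", "Toronto", "Leiden", "Kyoto", "Lyon")
ctg_countries <- c("United States", "Canada", "Netherlands", "Japan", "France")
ctg_intervention_types <- c(
  "Drug", "Device", "Biologic/Vaccine", "Procedure/Surgery", "Radiation",
  "Behavioral", "Genetic", "Dietary Supplement", "Combination Product",
  "Diagnostic Test", "Other"
)

# Deterministic sub-seed per defect family, split from the master seed so
# editing one plan entry does not reshuffle unrelated placements.
family_seed <- function(seed, family_id) {
  (as.integer(seed) %% 100000L) * 13751L + family_id * 7919L
}

# Largest-remainder apportionment of n among categories with the given
# probabilities; exact_counts mode turns mixes into integer counts.
apportion <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Build a synthetic-corpus generator configuration
#'
#' Configures the seeded generator: corpus size, mixes over study type /
#' Final Rule era / agency class / principal-investigator designation, and
#' the defect plans each audit stage must later recover. In
#' `"exact_counts"` mode (the default, which turns recovery checks into
#' equalities) plan entries are integer counts planted by sampling
#' eligible records without replacement; in `"rates"` mode entries are
#' per-record probabilities.
#'
#' @param n_records Number of records.
#' @param seed Master seed; every defect family derives its own stream
#'   from it.
#' @param study_type_mix,era_mix,agency_mix,pi_mix Named probability
#'   vectors (normalized internally).
#' @param missing_plan Named list: audited field name -> planted count
#'   (or rate) of interventional records missing it.
#' @param rogue_plan Data frame with columns `field`, `value`, `count`:
#'   enumerated fields to seed with out-of-dictionary values.
#' @param criteria_class_plan Named counts (or rates) over the criteria
#'   format classes `correct`, `headers_only`, `malformed_headers`,
#'   `missing`; unassigned records are `correct`.
#' @param multi_group_count Number of `malformed_headers` blocks built as
#'   multi-participant-group exemplars (must not exceed the
#'   `malformed_headers` plan).
#' @param lexicon_membership List with optional entries `condition` (count
#'   or rate of records whose condition term is drawn from the MESH
#'   section of the lexicon) and `intervention` (count/rate, or a named
#'   vector per intervention type, of records whose intervention name is
#'   drawn from the lexicon's union key set).
#' @param contact_plan Named counts (or rates): `no_overall_contact`
#'   (records), `sites_without_contact` (site slots),
#'   `missing_phone` / `missing_email` (provided contact details).
#' @param mode `"exact_counts"` or `"rates"`.
#' @param lexicon Lexicon used to draw condition/intervention terms;
#'   defaults to the bundled synthetic fixture lexicon.
#' @return A `ctg_corpus_config` list.
#' @export
corpus_config <- function(n_records, seed = 1L,
                          study_type_mix = c(Interventional = 1),
                          era_mix = c(pre_final_rule = 0.5,
                                      post_final_rule = 0.5),
                          agency_mix = c(Other = 1),
                          pi_mix = c(official_with_nonscientific_rp = 1),
                          missing_plan = list(),
                          rogue_plan = NULL,
                          criteria_class_plan = NULL,
                          multi_group_count = 0,
                          lexicon_membership = NULL,
                          contact_plan = list(),
                          mode = c("exact_counts", "rates"),
                          lexicon = NULL) {
  mode <- match.arg(mode)
  check_mix <- function(mix, allowed, what) {
    if (!all(names(mix) %in% allowed)) {
      abort(paste0("Unknown ", what, " level(s): ",
                   paste(setdiff(names(mix), allowed), collapse = ", ")),
            class = "ctg_config_error")
    }
    mix / sum(mix)
  }
  cfg <- structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    study_type_mix = check_mix(study_type_mix,
      c("Interventional", "Observational", "Expanded Access"), "study type"),
    era_mix = check_mix(era_mix, c("pre_final_rule", "post_final_rule"),
                        "era"),
    agency_mix = check_mix(agency_mix, c("NIH", "U.S. Fed", "Industry", "Other"),
                           "agency class"),
    pi_mix = check_mix(pi_mix, c("no_pi", "rp_investigator_only",
                                 "official_with_nonscientific_rp", "both"),
                       "PI category"),
    missing_plan = missing_plan,
    rogue_plan = if (is.null(rogue_plan)) NULL else as_tibble(rogue_plan),
    criteria_class_plan = criteria_class_plan,
    multi_group_count = multi_group_count,
    lexicon_membership = lexicon_membership,
    contact_plan = contact_plan,
    mode = mode,
    lexicon = lexicon
  ), class = "ctg_corpus_config")
  cfg
}

#' A generator preset echoing headline registry statistics
#'
#' Convenience preset for demonstration reports: rate-mode plans set to
#' headline percentages observed in the registry at large (roughly 61%
#' correctly formatted criteria with 24%/15%/0.3% in the other classes,
#' 74% of records without an overall contact, a 12/7.5/54/27 split of
#' principal-investigator designations, 10% of interventional records
#' without listed arms, 24% without allocation, 62% MeSH condition
#' coverage and 46% intervention coverage).
#'
#' @param n_records Corpus size.
#' @param seed Master seed.
#' @return A `ctg_corpus_config`.
#' @export
headline_profile <- function(n_records = 1000, seed = 1L) {
  corpus_config(
    n_records = n_records, seed = seed,
    study_type_mix = c(Interventional = 0.792, Observational = 0.203,
                       `Expanded Access` = 0.005),
    era_mix = c(pre_final_rule = 0.807, post_final_rule = 0.193),
    agency_mix = c(NIH = 0.029, `U.S. Fed` = 0.013, Industry = 0.289,
                   Other = 0.669),
    pi_mix = c(no_pi = 0.12, rp_investigator_only = 0.075,
               official_with_nonscientific_rp = 0.54, both = 0.265),
    missing_plan = list("arm information" = 0.10, "number of arms" = 0.10,
                        "allocation" = 0.24, "intervention description" = 0.19,
                        "outcome description" = 0.37),
    criteria_class_plan = c(correct = 0.607, headers_only = 0.244,
                            malformed_headers = 0.146, missing = 0.003),
    multi_group_count = 0.05,
    lexicon_membership = list(condition = 0.62, intervention = 0.46),
    contact_plan = list(no_overall_contact = 0.74, missing_phone = 0.21,
                        missing_email = 0.22),
    mode = "rates"
  )
}

plan_count <- function(entry, n_eligible, mode, seed, what) {
  if (mode == "rates") {
    if (entry < 0 || entry > 1) {
      abort(paste0("Rate for ", what, " must be in [0, 1]."),
            class = "ctg_config_error")
    }
    set.seed(seed)
    return(rbinom(1, n_eligible, entry))
  }
  k <- as.integer(entry)
  if (k < 0 || k > n_eligible) {
    abort(paste0("Planted count for ", what, " (", k,
                 ") exceeds the ", n_eligible, " eligible slot(s)."),
          class = "ctg_config_error")
  }
  k
}

seeded_sample <- function(x, k, seed) {
  set.seed(seed)
  if (length(x) == 1 && is.numeric(x)) x <- x  # guard sample()'s scalar rule
  x[sample.int(length(x), k)]
}

criteria_exemplar <- function(class, condition, variant = 1L,
                              multi_group = FALSE) {
  correct <- paste0(
    "Inclusion Criteria:\n",
    "- Adults aged 18 to 65 years\n",
    "- Confirmed diagnosis of ", condition, "\n",
    "- Able to provide written informed consent\n",
    "Exclusion Criteria:\n",
    "- Pregnancy or breastfeeding\n",
    "- Participation in another interventional trial")
  if (class == "correct") return(correct)
  if (class == "headers_only") {
    return(paste0(
      "Inclusion Criteria:\n",
      "Patients are eligible if they are adults with ", condition,
      " and provide informed consent.\n",
      "- Stable dose of background medication\n",
      "Exclusion Criteria:\n",
      "- Pregnancy or breastfeeding"))
  }
  if (class == "malformed_headers") {
    if (multi_group) {
      return(paste0(
        "Inclusion Criteria - Cohort A:\n",
        "- Adults with ", condition, "\n",
        "Exclusion Criteria - Cohort A:\n",
        "- Pregnancy\n",
        "Inclusion Criteria - Cohort B (healthy volunteers):\n",
        "- No chronic illness"))
    }
    variants <- c(
      paste0("Key Inclusion Criteria:\n- Adults with ", condition,
             "\nExclusion Criteria:\n- Pregnancy"),
      paste0("INCLUSION:\n- Adults with ", condition,
             "\nEXCLUSION:\n- Pregnancy"),
      paste0("Inclusion Criteria:\n- Adults with ", condition,
             "\n- No exclusions apply"))
    return(variants[(variant - 1L) %% length(variants) + 1L])
  }
  NA_character_
}

random_date <- function(era, rng_seed, i) {
  # deterministic per record: hash the index into the era's window
  set.seed(rng_seed + i)
  if (era == "pre_final_rule") {
    year <- sample(2005:2016, 1)
  } else {
    year <- sample(2017:2019, 1)
  }
  month <- if (era == "post_final_rule" && year == 2017)
    sample(2:12, 1) else sample(1:12, 1)
  day <- sample(1:28, 1)
  sprintf("%s %d, %d", month.name[month], day, year)
}

#' Generate a seeded synthetic corpus with a recoverable defect profile
#'
#' Builds `n_records` schema-conformant records, then plants the
#' configured defects: missing required fields, rogue enumerated values,
#' eligibility-criteria format classes, lexicon membership of condition
#' and intervention terms, and degraded contact information. With all
#' plans zero the corpus passes every audit stage with no problem-level
#' findings. Generation is a pure function of the configuration: the same
#' config yields byte-identical corpora.
#'
#' Plans interact in a fixed order (criteria, lexicon, missing fields --
#' facility removal first -- rogue values, contacts); records whose
#' facilities were removed are not eligible for site-level plants, and
#' start-date removal is drawn from pre-Final-Rule records so the era
#' binning of other plants is undisturbed.
#'
#' @param config A `ctg_corpus_config` from [corpus_config()].
#' @return A list with `records` (a `ctg_corpus` tibble) and `truth` (the
#'   realized per-record assignment of every planted defect, class, era
#'   and lexicon membership).
#' @export
generate_corpus <- function(config) {
  n <- config$n_records
  seed <- config$seed
  mode <- config$mode
  lex <- config$lexicon %||% ctg_fixture_lexicon()
  lex_tab <- as_lexicon_table(lex)
  mesh_terms_all <- sort(unique(
    lex_tab$term_norm[lex_tab$source_id == "MESH"]))
  union_terms <- sort(unique(lex_tab$term_norm))
  # preferred-name casing for drawing values (normalization is case-folding,
  # so drawing the cased form still matches)
  cased <- function(keys) {
    vapply(keys, function(k) k, character(1))
  }
  condition_pool_in <- cased(mesh_terms_all)
  intervention_pool_in <- cased(union_terms)

  record_ids <- sprintf("NCT%08d", seq_len(n))

  draw_mix <- function(mix, family_id) {
    lv <- names(mix)
    if (mode == "exact_counts") {
      counts <- apportion(n, mix)
      assign_vec <- rep(lv, counts)
    } else {
      set.seed(family_seed(seed, family_id))
      assign_vec <- sample(lv, n, replace = TRUE, prob = mix)
    }
    seeded_sample(assign_vec, n, family_seed(seed, family_id) + 1L)
  }

  study_type <- draw_mix(config$study_type_mix, 1L)
  era <- draw_mix(config$era_mix, 2L)
  agency_class <- draw_mix(config$agency_mix, 3L)
  pi_cat <- draw_mix(config$pi_mix, 4L)
  itype <- ctg_intervention_types[(seq_len(n) - 1L) %% 11L + 1L]

  ## -- criteria class plan ----------------------------------------------
  criteria_class <- rep("correct", n)
  if (!is.null(config$criteria_class_plan)) {
    plan <- config$criteria_class_plan
    bad <- setdiff(names(plan),
                   c("correct", "headers_only", "malformed_headers", "missing"))
    if (length(bad) > 0) {
      abort(paste0("Unknown criteria class(es): ", paste(bad, collapse = ", ")),
            class = "ctg_config_error")
    }
    if (mode == "exact_counts") {
      if (sum(unlist(plan)) > n) {
        abort("criteria_class_plan counts exceed n_records.",
              class = "ctg_config_error")
      }
      counts <- unlist(plan)
    } else {
      counts <- apportion(n, unlist(plan) /
                            max(sum(unlist(plan)), 1))
      names(counts) <- names(plan)
    }
    pool <- seq_len(n)
    fs <- family_seed(seed, 5L)
    for (cl in setdiff(names(counts), "correct")) {
      k <- min(counts[[cl]], length(pool))
      pick <- seeded_sample(pool, k, fs + match(cl, names(counts)))
      criteria_class[pick] <- cl
      pool <- setdiff(pool, pick)
    }
  }
  multi_group <- rep(FALSE, n)
  mg <- config$multi_group_count
  if (mode == "rates" && mg > 0 && mg < 1) {
    mg <- round(mg * n)
  }
  if (mg > 0) {
    malformed_idx <- which(criteria_class == "malformed_headers")
    if (mg > length(malformed_idx)) {
      abort("multi_group_count exceeds the planted malformed_headers count.",
            class = "ctg_config_error")
    }
    multi_group[seeded_sample(malformed_idx, mg, family_seed(seed, 55L))] <- TRUE
  }

  ## -- lexicon membership ------------------------------------------------
  cond_in <- rep(TRUE, n)
  int_in <- rep(TRUE, n)
  lm <- config$lexicon_membership
  if (!is.null(lm)) {
    if (!is.null(lm$condition)) {
      k <- plan_count(lm$condition, n, mode, family_seed(seed, 6L),
                      "condition lexicon membership")
      cond_in <- rep(FALSE, n)
      cond_in[seeded_sample(seq_len(n), k, family_seed(seed, 6L) + 1L)] <- TRUE
    }
    if (!is.null(lm$intervention)) {
      if (length(lm$intervention) > 1 || !is.null(names(lm$intervention))) {
        int_in <- rep(FALSE, n)
        for (ty in names(lm$intervention)) {
          elig <- which(itype == ty)
          k <- plan_count(lm$intervention[[ty]], length(elig), mode,
                          family_seed(seed, 7L) + match(ty, ctg_intervention_types),
                          paste0("intervention membership (", ty, ")"))
          int_in[seeded_sample(elig, k,
                               family_seed(seed, 7L) + 100L +
                                 match(ty, ctg_intervention_types))] <- TRUE
        }
      } else {
        k <- plan_count(lm$intervention, n, mode, family_seed(seed, 7L),
                        "intervention lexicon membership")
        int_in <- rep(FALSE, n)
        int_in[seeded_sample(seq_len(n), k, family_seed(seed, 7L) + 1L)] <- TRUE
      }
    }
  }

  ## -- base records -------------------------------------------------------
  set.seed(family_seed(seed, 10L))
  cond_pick <- sample.int(length(condition_pool_in), n, replace = TRUE)
  int_pick <- sample.int(length(intervention_pool_in), n, replace = TRUE)
  name_pick <- sample.int(length(ctg_person_names), n, replace = TRUE)
  city_pick <- sample.int(length(ctg_cities), n, replace = TRUE)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    condition <- if (cond_in[i]) condition_pool_in[cond_pick[i]] else
      sprintf("unclassified syndrome %03d", i)
    ivname <- if (int_in[i]) intervention_pool_in[int_pick[i]] else
      sprintf("investigational product %03d", i)
    criteria <- criteria_exemplar(criteria_class[i], condition,
                                  variant = i, multi_group = multi_group[i])
    sponsors <- ctg_sponsor_names[[agency_class[i]]]
    person <- ctg_person_names[name_pick[i]]
    city <- ctg_cities[city_pick[i]]
    country <- ctg_countries[(city_pick[i] - 1L) %% length(ctg_countries) + 1L]
    interventional <- study_type[i] == "Interventional"

    start_raw <- random_date(era[i], family_seed(seed, 11L), i)
    comp_raw <- random_date(era[i], family_seed(seed, 12L), i)

    officials <- if (pi_cat[i] %in% c("official_with_nonscientific_rp", "both")) {
      tibble(last_name = person, role = "Study Principal Investigator",
             affiliation = sponsors[1])
    } else {
      tibble(last_name = character(), role = character(),
             affiliation = character())
    }
    rp_type <- switch(pi_cat[i],
      no_pi = "Sponsor",
      official_with_nonscientific_rp = "Sponsor",
      rp_investigator_only = "Principal Investigator",
      both = "Sponsor-Investigator")

    locations <- tibble(
      facility_name = paste0(sponsors[1], " Site ", 1:2),
      city = city, country = country, status = "Completed",
      contact_last_name = person,
      contact_phone = sprintf("+1 555 01%02d", (i + 0:1) %% 100),
      contact_email = sprintf("site%d.trial%04d@example.org", 1:2, i),
      has_contact = TRUE
    )

    rec <- structure(list(
      record_id = record_ids[i],
      secondary_ids = sprintf("PROTO-%05d", i),
      study_type = study_type[i],
      brief_title = paste0("Trial of ", ivname, " for ", condition),
      brief_summary = paste0("A study evaluating ", ivname, " in participants with ",
                             condition, "."),
      official_title = paste0("A Phase 2 Study Evaluating the Efficacy and Safety of ",
                              ivname, " in Participants With ", condition),
      overall_status = "Completed",
      why_stopped = NA_character_,
      start_date_raw = start_raw, start_date_type = "Actual",
      completion_date_raw = comp_raw, completion_date_type = "Actual",
      primary_completion_date_raw = comp_raw,
      primary_completion_date_type = "Actual",
      verification_date_raw = "January, 2019",
      phase = if (interventional) "Phase 2" else "N/A",
      enrollment_raw = "100", enrollment_type = "Actual",
      number_of_arms_raw = if (interventional) "2" else NA_character_,
      number_of_groups_raw = if (study_type[i] == "Observational") "2" else NA_character_,
      agency = sponsors[1 + (i %% length(sponsors))],
      agency_class = agency_class[i],
      conditions = condition,
      interventions = tibble(intervention_type = itype[i], name = ivname,
                             description = "Administered per protocol."),
      eligibility = list(
        criteria_text = criteria,
        gender = "All",
        minimum_age = "18 Years", maximum_age = "65 Years",
        healthy_volunteers = "No",
        sampling_method = if (study_type[i] == "Observational")
          "Probability Sample" else NA_character_,
        study_pop = if (study_type[i] == "Observational")
          "Adults attending the study clinics." else NA_character_
      ),
      design = list(
        allocation = if (interventional) "Randomized" else NA_character_,
        intervention_model = if (interventional)
          "Parallel Group Assignment" else NA_character_,
        masking = if (interventional)
          "Double(Participant, Investigator)" else NA_character_,
        primary_purpose = if (interventional) "Treatment" else NA_character_,
        observational_model = if (study_type[i] == "Observational")
          "Cohort" else NA_character_,
        time_perspective = if (study_type[i] == "Observational")
          "Prospective" else NA_character_,
        arms = if (interventional) tibble(
          label = c(ivname, "Placebo"),
          arm_type = c("Experimental", "Placebo Comparator"),
          description = c("Active treatment arm.", "Matching placebo arm.")
        ) else tibble(label = character(), arm_type = character(),
                      description = character())
      ),
      parties = list(
        responsible_party_type = rp_type,
        rp_investigator_full_name = if (rp_type %in%
          c("Principal Investigator", "Sponsor-Investigator")) person else NA_character_,
        rp_investigator_affiliation = if (rp_type %in%
          c("Principal Investigator", "Sponsor-Investigator")) sponsors[1] else NA_character_,
        rp_investigator_title = if (rp_type %in%
          c("Principal Investigator", "Sponsor-Investigator"))
          "Principal Investigator" else NA_character_,
        overall_officials = officials
      ),
      contacts = list(
        overall_contact = list(
          last_name = person,
          phone = sprintf("+1 555 02%02d", i %% 100),
          email = sprintf("contact.trial%04d@example.org", i)
        ),
        locations = locations
      ),
      outcomes = tibble(
        rank = "primary",
        measure = paste0("Change from baseline in ", condition, " severity score"),
        time_frame = "12 weeks",
        description = "Assessed by blinded central review."
      ),
      booleans = tibble(
        xml_path = c("has_expanded_access", "oversight_info/has_dmc",
                     "eligibility/gender_based"),
        value = c("No", "Yes", "No")
      ),
      raw_values = NULL
    ), class = "trial_record")
    records[[i]] <- rec
  }

  truth_missing <- list()
  interventional_idx <- which(study_type == "Interventional")

  ## -- missing-field plan (facility removal first) -----------------------
  facility_removed <- integer()
  plan_fields <- names(config$missing_plan)
  plan_fields <- c(intersect("facility information", plan_fields),
                   setdiff(plan_fields, "facility information"))
  appliers <- missing_field_appliers()
  for (f in plan_fields) {
    if (!f %in% names(appliers)) {
      abort(paste0("No missing-field applier for '", f, "'."),
            class = "ctg_config_error")
    }
    elig <- interventional_idx
    if (f %in% c("individual site status", "facility name, city, or country")) {
      elig <- setdiff(elig, facility_removed)
    }
    if (f == "study start date") {
      elig <- intersect(elig, which(era == "pre_final_rule"))
    }
    fid <- 20L + match(f, sort(names(appliers)))
    k <- plan_count(config$missing_plan[[f]], length(elig), mode,
                    family_seed(seed, fid), paste0("missing_plan['", f, "']"))
    pick <- seeded_sample(elig, k, family_seed(seed, fid) + 1L)
    for (i in pick) records[[i]] <- appliers[[f]](records[[i]])
    if (f == "facility information") facility_removed <- pick
    if (k > 0) {
      truth_missing[[length(truth_missing) + 1]] <-
        tibble(record_id = record_ids[pick], field = f)
    }
  }

  ## -- rogue-value plan ---------------------------------------------------
  truth_rogue <- list()
  if (!is.null(config$rogue_plan) && nrow(config$rogue_plan) > 0) {
    setters <- rogue_value_setters()
    for (r in seq_len(nrow(config$rogue_plan))) {
      f <- config$rogue_plan$field[r]
      if (!f %in% names(setters)) {
        abort(paste0("No rogue-value setter for '", f, "'."),
              class = "ctg_config_error")
      }
      st <- setters[[f]]
      elig <- which(map_lgl(records, st$eligible))
      k <- plan_count(config$rogue_plan$count[r], length(elig), mode,
                      family_seed(seed, 60L + r),
                      paste0("rogue_plan['", f, "']"))
      pick <- seeded_sample(elig, k, family_seed(seed, 60L + r) + 1L)
      for (i in pick) {
        records[[i]] <- st$set(records[[i]], config$rogue_plan$value[r])
      }
      if (k > 0) {
        truth_rogue[[length(truth_rogue) + 1]] <- tibble(
          record_id = record_ids[pick], field = f,
          value = config$rogue_plan$value[r])
      }
    }
  }

  ## -- contact plan -------------------------------------------------------
  cp <- config$contact_plan
  no_oc_ids <- character()
  if (!is.null(cp$no_overall_contact)) {
    k <- plan_count(cp$no_overall_contact, n, mode, family_seed(seed, 70L),
                    "contact_plan$no_overall_contact")
    pick <- seeded_sample(seq_len(n), k, family_seed(seed, 70L) + 1L)
    for (i in pick) records[[i]]$contacts$overall_contact <- NULL
    no_oc_ids <- record_ids[pick]
  }
  sites_wo_ids <- tibble(record_id = character(), site = integer())
  if (!is.null(cp$sites_without_contact)) {
    slots <- map_dfr(setdiff(seq_len(n), facility_removed), function(i) {
      nloc <- nrow(records[[i]]$contacts$locations)
      if (nloc == 0) return(tibble(rec = integer(), site = integer()))
      tibble(rec = i, site = seq_len(nloc))
    })
    k <- plan_count(cp$sites_without_contact, nrow(slots), mode,
                    family_seed(seed, 71L), "contact_plan$sites_without_contact")
    set.seed(family_seed(seed, 71L) + 1L)
    pick <- slots[sample.int(nrow(slots), k), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      i <- pick$rec[r]; s <- pick$site[r]
      records[[i]]$contacts$locations$has_contact[s] <- FALSE
      records[[i]]$contacts$locations$contact_last_name[s] <- NA_character_
      records[[i]]$contacts$locations$contact_phone[s] <- NA_character_
      records[[i]]$contacts$locations$contact_email[s] <- NA_character_
    }
    sites_wo_ids <- tibble(record_id = record_ids[pick$rec], site = pick$site)
  }
  # degrade provided contacts: enumerate surviving contact slots
  contact_slots <- map_dfr(seq_len(n), function(i) {
    out <- list()
    if (!is.null(records[[i]]$contacts$overall_contact)) {
      out[[length(out) + 1]] <- tibble(rec = i, kind = "overall", site = 0L)
    }
    locs <- records[[i]]$contacts$locations
    for (s in seq_len(nrow(locs))) {
      if (isTRUE(locs$has_contact[s])) {
        out[[length(out) + 1]] <- tibble(rec = i, kind = "site", site = s)
      }
    }
    if (length(out) == 0) tibble(rec = integer(), kind = character(),
                                 site = integer()) else bind_rows(out)
  })
  degrade <- function(entry, field, family) {
    if (is.null(entry)) return(invisible())
    k <- plan_count(entry, nrow(contact_slots), mode, family_seed(seed, family),
                    paste0("contact_plan$", field))
    set.seed(family_seed(seed, family) + 1L)
    pick <- contact_slots[sample.int(nrow(contact_slots), k), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      i <- pick$rec[r]
      if (pick$kind[r] == "overall") {
        records[[i]]$contacts$overall_contact[[field]] <<- NA_character_
      } else {
        col <- paste0("contact_", field)
        records[[i]]$contacts$locations[[col]][pick$site[r]] <<- NA_character_
      }
    }
    nrow(pick)
  }
  n_missing_phone <- degrade(cp$missing_phone, "phone", 72L)
  n_missing_email <- degrade(cp$missing_email, "email", 73L)

  ## -- finalize: round-trip through the writer/reader so raw_values and
  ## typed views agree exactly with what a consumer of the XML would see
  records <- map(records, function(r) read_trial_record(write_trial_record(r)))

  corpus <- tibble(
    file = paste0(record_ids, ".xml"),
    record_id = record_ids,
    record = records
  )
  attr(corpus, "parse_errors") <- tibble(file = character(),
                                         message = character())
  class(corpus) <- c("ctg_corpus", class(corpus))

  truth <- list(
    config_seed = seed,
    n_records = n,
    assignments = tibble(
      record_id = record_ids, study_type = study_type, era = era,
      agency_class = agency_class, pi_category = pi_cat,
      criteria_class = criteria_class, multi_group = multi_group,
      intervention_type = itype,
      condition_in_lexicon = cond_in, intervention_in_lexicon = int_in),
    missing = if (length(truth_missing) > 0) bind_rows(truth_missing) else
      tibble(record_id = character(), field = character()),
    rogue = if (length(truth_rogue) > 0) bind_rows(truth_rogue) else
      tibble(record_id = character(), field = character(), value = character()),
    contacts = list(
      no_overall_contact = no_oc_ids,
      sites_without_contact = sites_wo_ids,
      n_missing_phone = n_missing_phone %||% 0L,
      n_missing_email = n_missing_email %||% 0L)
  )
  list(records = corpus, truth = truth)
}

# Mutators that remove one audited field from a record.
missing_field_appliers <- function() {
  list(
    "brief title" = function(r) { r$brief_title <- NA_character_; r },
    "brief summary" = function(r) { r$brief_summary <- NA_character_; r },
    "official title" = function(r) { r$official_title <- NA_character_; r },
    "study phase" = function(r) { r$phase <- NA_character_; r },
    "condition" = function(r) { r$conditions <- character(); r },
    "secondary id" = function(r) { r$secondary_ids <- character(); r },
    "intervention name" = function(r) {
      r$interventions$name <- NA_character_; r },
    "intervention type" = function(r) {
      r$interventions$intervention_type <- NA_character_; r },
    "intervention description" = function(r) {
      r$interventions$description <- NA_character_; r },
    "eligibility criteria" = function(r) {
      r$eligibility$criteria_text <- NA_character_; r },
    "sex" = function(r) { r$eligibility$gender <- NA_character_; r },
    "age limits" = function(r) {
      r$eligibility$minimum_age <- NA_character_
      r$eligibility$maximum_age <- NA_character_; r },
    "overall recruitment status" = function(r) {
      r$overall_status <- NA_character_; r },
    "sponsor" = function(r) { r$agency <- NA_character_; r },
    "responsible party type" = function(r) {
      r$parties$responsible_party_type <- NA_character_; r },
    "primary purpose" = function(r) {
      r$design$primary_purpose <- NA_character_; r },
    "interventional study model" = function(r) {
      r$design$intervention_model <- NA_character_; r },
    "allocation" = function(r) { r$design$allocation <- NA_character_; r },
    "masking" = function(r) { r$design$masking <- NA_character_; r },
    "number of arms" = function(r) {
      r$number_of_arms_raw <- NA_character_; r },
    "arm information" = function(r) {
      r$design$arms <- r$design$arms[0, ]; r },
    "study start date" = function(r) {
      r$start_date_raw <- NA_character_
      r$start_date_type <- NA_character_; r },
    "primary completion date" = function(r) {
      r$primary_completion_date_raw <- NA_character_
      r$primary_completion_date_type <- NA_character_; r },
    "study completion date" = function(r) {
      r$completion_date_raw <- NA_character_
      r$completion_date_type <- NA_character_; r },
    "enrollment" = function(r) {
      r$enrollment_raw <- NA_character_
      r$enrollment_type <- NA_character_; r },
    "outcome measures" = function(r) { r$outcomes <- r$outcomes[0, ]; r },
    "outcome time frame" = function(r) {
      r$outcomes$time_frame[1] <- NA_character_; r },
    "outcome description" = function(r) {
      r$outcomes$description[1] <- NA_character_; r },
    "accepts healthy volunteers" = function(r) {
      r$eligibility$healthy_volunteers <- NA_character_; r },
    "why study stopped" = function(r) {
      r$overall_status <- "Terminated"
      r$why_stopped <- NA_character_; r },
    "individual site status" = function(r) {
      if (nrow(r$contacts$locations) > 0)
        r$contacts$locations$status[1] <- NA_character_
      r },
    "availability of expanded access" = function(r) {
      r$booleans <- r$booleans[r$booleans$xml_path != "has_expanded_access", ]
      r },
    "facility information" = function(r) {
      r$contacts$locations <- r$contacts$locations[0, ]; r },
    "facility name, city, or country" = function(r) {
      if (nrow(r$contacts$locations) > 0)
        r$contacts$locations$city[1] <- NA_character_
      r }
  )
}

# Mutators that plant a rogue value in an enumerated field. Eligibility
# requires the field to be PRESENT on the record, so rogue plants never
# overwrite (and thereby undo) a planted missing-field defect for the
# same field.
rogue_value_setters <- function() {
  is_int <- function(r) identical(r$study_type, "Interventional")
  is_obs <- function(r) identical(r$study_type, "Observational")
  list(
    "primary purpose" = list(
      eligible = function(r) is_int(r) && !is.na(r$design$primary_purpose),
      set = function(r, v) { r$design$primary_purpose <- v; r }),
    "allocation" = list(
      eligible = function(r) is_int(r) && !is.na(r$design$allocation),
      set = function(r, v) { r$design$allocation <- v; r }),
    "interventional study model" = list(
      eligible = function(r) is_int(r) && !is.na(r$design$intervention_model),
      set = function(r, v) { r$design$intervention_model <- v; r }),
    "masking" = list(
      eligible = function(r) is_int(r) && !is.na(r$design$masking),
      set = function(r, v) { r$design$masking <- v; r }),
    "arm type" = list(
      eligible = function(r) nrow(r$design$arms) > 0 &&
        !is.na(r$design$arms$arm_type[1]),
      set = function(r, v) { r$design$arms$arm_type[1] <- v; r }),
    "observational study model" = list(
      eligible = function(r) is_obs(r) && !is.na(r$design$observational_model),
      set = function(r, v) { r$design$observational_model <- v; r }),
    "time perspective" = list(
      eligible = function(r) is_obs(r) && !is.na(r$design$time_perspective),
      set = function(r, v) { r$design$time_perspective <- v; r }),
    "sampling method" = list(
      eligible = function(r) is_obs(r) && !is.na(r$eligibility$sampling_method),
      set = function(r, v) { r$eligibility$sampling_method <- v; r }),
    "overall recruitment status" = list(
      eligible = function(r) !is.na(r$overall_status),
      set = function(r, v) { r$overall_status <- v; r }),
    "study phase" = list(
      eligible = function(r) !is.na(r$phase),
      set = function(r, v) { r$phase <- v; r }),
    "sex" = list(
      eligible = function(r) !is.na(r$eligibility$gender),
      set = function(r, v) { r$eligibility$gender <- v; r }),
    "intervention type" = list(
      eligible = function(r) nrow(r$interventions) > 0 &&
        !is.na(r$interventions$intervention_type[1]),
      set = function(r, v) { r$interventions$intervention_type[1] <- v; r }),
    "individual site status" = list(
      eligible = function(r) nrow(r$contacts$locations) > 0 &&
        !is.na(r$contacts$locations$status[1]),
      set = function(r, v) { r$contacts$locations$status[1] <- v; r }),
    "responsible party type" = list(
      eligible = function(r) !is.na(r$parties$responsible_party_type),
      set = function(r, v) { r$parties$responsible_party_type <- v; r })
  )
}

#' Write a generated corpus to disk with its ground truth and manifest
#'
#' One XML file per record, the ground truth as JSON, and a manifest
#' listing each file's MD5 digest plus a whole-corpus checksum, so a
#' regenerated or copied corpus can be verified byte-for-byte.
#'
#' @param corpus A `ctg_corpus` tibble (from [generate_corpus()]).
#' @param truth The ground-truth list (or `NULL` to skip).
#' @param dir Destination directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_corpus <- function(corpus, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("Cannot create corpus directory '", dir, "'."),
          class = "ctg_io_error")
  }
  for (i in seq_len(nrow(corpus))) {
    write_trial_record(corpus$record[[i]], file.path(dir, corpus$file[i]))
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, na = "null", digits = NA)
  }
  digests <- tools::md5sum(file.path(dir, corpus$file))
  manifest <- list(
    files = tibble(file = corpus$file, md5 = unname(digests)),
    corpus_checksum = checksum_of(unname(digests))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

checksum_of <- function(digests) {
  tmp <- tempfile()
  writeLines(digests, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Verify a written corpus against its manifest
#'
#' @param dir Corpus directory containing `manifest.json`.
#' @return A list: `ok` (flag), `mismatched` / `missing` file names.
#' @export
verify_manifest <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  files <- mf$files$file
  present <- file.exists(file.path(dir, files))
  digests <- rep(NA_character_, length(files))
  digests[present] <- unname(tools::md5sum(file.path(dir, files[present])))
  mismatched <- files[present & digests != mf$files$md5]
  missing <- files[!present]
  ok <- length(mismatched) == 0 && length(missing) == 0 &&
    identical(checksum_of(digests), mf$corpus_checksum)
  list(ok = ok, mismatched = mismatched, missing = missing)
}
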