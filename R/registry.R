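#' Load the built-in field registry
#'
#' The registry is the machine-readable form of the ClinicalTrials.gov data
#' dictionary: one row per dictionary element (149 in all, with composite
#' elements expanded into sub-specifications), carrying the element's type
#' category, permitted value sets, requirement status, the predicate
#' governing conditionally required elements, and the mapping between
#' dictionary, XML, FDAAA801 and WHO Trial Registration Data Set names.
#'
#' Value sets are stored in two forms where the registry dialect diverges
#' from the dictionary: `allowed_values_dictionary` holds the dictionary's
#' printed set, and `allowed_values_record_form` the syntax that actually
#' appears in public XML records (e.g. "Parallel Group Assignment" rather
#' than "Parallel"; masking values such as "Double(Participant, Care
#' Provider)" are described by a pattern rather than a finite set).
#'
#' @param overrides Optional data frame of spec fields to replace built-ins.
#'   Must contain a `dictionary_name` column naming existing elements; every
#'   other column present replaces the corresponding registry column for the
#'   matching rows. List-valued columns (`allowed_values_dictionary`,
#'   `allowed_values_record_form`) may be given as pipe-separated strings.
#' @return A tibble of class `ctg_registry`, one row per field
#'   specification.
#' @examples
#' reg <- ctg_registry()
#' dplyr::filter(reg, dictionary_name == "allocation")$allowed_values_dictionary
#' ctg_registry(overrides = data.frame(
#'   dictionary_name = "enrollment", requirement = "optional"))
#' @export
ctg_registry <- function(overrides = NULL) {
  path <- system.file("extdata", "field_registry.tsv", package = "ctgaudit",
                      mustWork = TRUE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      xsd_typed = readr::col_logical(),
      final_rule_only = readr::col_logical(),
      .default = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  reg <- raw %>%
    mutate(
      allowed_values_dictionary = split_set(.data$allowed_dict),
      allowed_values_record_form = split_set(.data$allowed_record),
      applicability = split_set(.data$applicability)
    ) %>%
    select(-"allowed_dict", -"allowed_record") %>%
    rename(
      fdaaa_field = "fdaaa_field", who_field = "who_field",
      requirement_condition_id = "condition_id",
      required_only_after_final_rule = "final_rule_only"
    )

  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    if (!"dictionary_name" %in% names(overrides)) {
      abort("`overrides` must contain a `dictionary_name` column.",
            class = "ctg_config_error")
    }
    unknown <- setdiff(overrides$dictionary_name, reg$dictionary_name)
    if (length(unknown) > 0) {
      abort(paste0("Unknown dictionary element(s) in overrides: ",
                   paste(unknown, collapse = ", ")),
            class = "ctg_config_error")
    }
    set_cols <- c("allowed_values_dictionary", "allowed_values_record_form",
                  "applicability")
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$dictionary_name[i], reg$dictionary_name)
      for (col in setdiff(names(overrides), "dictionary_name")) {
        if (!col %in% names(reg)) {
          abort(paste0("Unknown registry column in overrides: ", col),
                class = "ctg_config_error")
        }
        val <- overrides[[col]][[i]]
        if (col %in% set_cols && is.character(val) && length(val) == 1) {
          val <- split_set(val)[[1]]
        }
        if (is.list(reg[[col]])) {
          reg[[col]][[j]] <- val
        } else {
          reg[[col]][j] <- val
        }
      }
    }
  }
  class(reg) <- c("ctg_registry", class(reg))
  reg
}

split_set <- function(x) {
  out <- str_split(x, stringr::fixed("|"))
  map(out, function(v) v[v != ""])
}

#' Resolve a field name in any of the four naming systems
#'
#' Resolves a name to its field specification. Names may come from the data
#' dictionary, the XML dialect (full slash-delimited path, or a path leaf
#' when unambiguous), FDAAA801, or the WHO Trial Registration Data Set.
#' Matching is exact after trimming surrounding whitespace.
#'
#' @param registry A registry from [ctg_registry()].
#' @param name The name to resolve.
#' @param namespace One of `"dictionary"`, `"xml"`, `"fdaaa"`, `"who"`.
#' @return The matching one-row specification tibble.
#' @examples
#' reg <- ctg_registry()
#' registry_lookup(reg, "number_of_arms", "xml")$value_kind
#' registry_lookup(reg, "Primary Disease or Condition Being Studied",
#'                 "fdaaa")$dictionary_name
#' @export
registry_lookup <- function(registry, name,
                            namespace = c("dictionary", "xml", "fdaaa", "who")) {
  namespace <- match.arg(namespace)
  name <- str_trim(name)
  keys <- switch(namespace,
    dictionary = registry$dictionary_name,
    xml = registry$xml_path,
    fdaaa = registry$fdaaa_field,
    who = registry$who_field
  )
  hit <- which(keys == name & keys != "")
  if (namespace == "xml" && length(hit) == 0) {
    # fall back to path-leaf matching when the leaf is unambiguous
    leaves <- map_chr(str_split(keys, "/"), function(p) p[length(p)])
    hit <- which(leaves == name & keys != "")
    if (length(hit) > 1) {
      abort(paste0("XML leaf '", name, "' is ambiguous; candidates: ",
                   paste(keys[hit], collapse = ", ")),
            class = "ctg_lookup_error")
    }
  }
  if (length(hit) == 0) {
    near <- near_misses(name, keys[keys != ""])
    abort(paste0("No ", namespace, " element named '", name, "'.",
                 if (length(near) > 0)
                   paste0(" Did you mean: ", paste(near, collapse = ", "), "?")
                 else ""),
          class = "ctg_lookup_error")
  }
  registry[hit[1], ]
}

near_misses <- function(name, keys, n = 3) {
  keys <- unique(keys)
  d <- as.vector(adist(tolower(name), tolower(keys), partial = FALSE))
  keys[order(d)][seq_len(min(n, length(keys)))]
}

# Built-in predicates for conditionally required elements. Each predicate
# takes a trial_record and says whether the requirement is active.
ctg_condition_predicates <- list(
  # why-study-stopped is required only when the study ended early
  cond_study_stopped = function(record) {
    isTRUE(record$overall_status %in% c("Suspended", "Terminated", "Withdrawn"))
  },
  # individual site status is required only when facilities are listed
  cond_has_locations = function(record) {
    nrow(record$contacts$locations) > 0
  }
)
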