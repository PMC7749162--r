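#' Normalize a term for exact matching
#'
#' The declared normalization behind "exact match": trim surrounding
#' whitespace, collapse internal whitespace runs, and (unless
#' `strict_case`) case-fold. Registry values capitalize inconsistently, so
#' case-folding is the default; a strict-case mode is provided.
#'
#' @param x Character vector of terms.
#' @param strict_case Keep case distinctions.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x, strict_case = FALSE) {
  out <- str_squish(x)
  if (!strict_case) out <- tolower(out)
  out
}

#' Load a terminology lexicon from a delimited file
#'
#' A lexicon is a table of preferred names and their globally unique term
#' identifiers for one or more source vocabularies (e.g. exported MeSH /
#' MedDRA / SNOMED-CT subsets). The file must be tab-delimited with
#' columns `source_id`, `preferred_name`, `identifier`. Preferred names
#' are normalized on load; duplicate names within a source merge their
#' identifier sets.
#'
#' @param path Path to the delimited file.
#' @param strict_case Keep case distinctions in the normalized keys.
#' @return A tibble of class `ctg_lexicon` with columns `source_id`,
#'   `term_norm` and an `identifiers` list-column.
#' @export
read_lexicon <- function(path, strict_case = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  needed <- c("source_id", "preferred_name", "identifier")
  if (!all(needed %in% names(raw))) {
    abort(paste0("Lexicon file must have columns ",
                 paste(needed, collapse = ", "), "."),
          class = "ctg_load_error")
  }
  bad <- which(is.na(raw$source_id) | is.na(raw$preferred_name) |
                 is.na(raw$identifier))
  if (length(bad) > 0) {
    abort(paste0("Malformed lexicon row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "ctg_load_error")
  }
  lex <- raw %>%
    mutate(term_norm = normalize_term(.data$preferred_name,
                                      strict_case = strict_case)) %>%
    group_by(.data$source_id, .data$term_norm) %>%
    summarise(identifiers = list(sort(unique(.data$identifier))),
              .groups = "drop")
  class(lex) <- c("ctg_lexicon", class(lex))
  attr(lex, "strict_case") <- strict_case
  lex
}

#' The bundled synthetic fixture lexicon
#'
#' A small, synthetic stand-in for exported vocabulary subsets, used by the
#' synthetic-corpus generator and the test suite. It is not real MeSH /
#' MedDRA / SNOMED-CT content; term-to-source assignments are fabricated
#' (with deliberate overlap between sources so union-coverage logic is
#' exercised).
#'
#' @inheritParams read_lexicon
#' @return A `ctg_lexicon` tibble.
#' @export
ctg_fixture_lexicon <- function(strict_case = FALSE) {
  read_lexicon(system.file("extdata", "synthetic_lexicon.tsv",
                           package = "ctgaudit", mustWork = TRUE),
               strict_case = strict_case)
}

as_lexicon_table <- function(lexicons) {
  if (inherits(lexicons, "ctg_lexicon") || is_tibble(lexicons)) {
    return(as_tibble(lexicons))
  }
  if (is.list(lexicons)) return(bind_rows(map(lexicons, as_tibble)))
  abort("`lexicons` must be a ctg_lexicon or a list of them.")
}

#' Measure exact-match coverage of free-text values against lexicons
#'
#' Counts, per source vocabulary, how many of the supplied values have an
#' exact (normalized) match among the lexicon's preferred names. Values
#' are treated as a bag: every listed occurrence counts once, matching
#' registry denominators which are listing counts, not unique strings.
#' The `union` row counts values matched by at least one source.
#'
#' @param values Character vector (bag) of free-text values.
#' @param lexicons A `ctg_lexicon` (possibly spanning several sources) or
#'   a list of them.
#' @param restrict_to Optional subset of source ids to consider.
#' @param strict_case Use case-sensitive matching.
#' @param stratum Optional stratum label attached to every row.
#' @return A tibble of class `ctg_coverage`: one row per source plus a
#'   `union` row, with `matched`, `total_values`, `pct` and `stratum`.
#' @examples
#' lex <- ctg_fixture_lexicon()
#' match_terms(c("Diabetes Mellitus", "unlisted thing"), lex)
#' @export
match_terms <- function(values, lexicons, restrict_to = NULL,
                        strict_case = FALSE, stratum = NA_character_) {
  lex <- as_lexicon_table(lexicons)
  if (!is.null(restrict_to)) lex <- lex[lex$source_id %in% restrict_to, ]
  sources <- sort(unique(lex$source_id))
  total <- length(values)
  vnorm <- normalize_term(values, strict_case = strict_case)
  matched_any <- rep(FALSE, total)
  rows <- map_dfr(sources, function(s) {
    keys <- lex$term_norm[lex$source_id == s]
    hit <- vnorm %in% keys
    matched_any <<- matched_any | hit
    tibble(source_id = s, matched = sum(hit), total_values = total,
           pct = pct_of(sum(hit), total), stratum = stratum)
  })
  out <- bind_rows(rows, tibble(
    source_id = "union", matched = sum(matched_any), total_values = total,
    pct = pct_of(sum(matched_any), total), stratum = stratum))
  out$unmatched <- out$total_values - out$matched
  class(out) <- c("ctg_coverage", class(out))
  out
}

#' Lexicon coverage of condition or intervention values across a corpus
#'
#' Collects every listed condition or intervention value across the corpus
#' (bag semantics) and measures per-vocabulary coverage, optionally
#' stratified by intervention type (one coverage table per type plus an
#' all-strata table).
#'
#' @param records A `ctg_corpus` tibble or list of `trial_record`s.
#' @param field `"condition"` or `"intervention"`.
#' @param lexicons As in [match_terms()].
#' @param stratifier `NULL` or `"intervention_type"` (the latter only with
#'   `field = "intervention"`).
#' @param restrict_to,strict_case As in [match_terms()].
#' @return A `ctg_coverage` tibble; with a stratifier, rows for each
#'   stratum plus `stratum = "all"`.
#' @export
coverage_by_stratum <- function(records, field = c("condition", "intervention"),
                                lexicons, stratifier = NULL,
                                restrict_to = NULL, strict_case = FALSE) {
  field <- match.arg(field)
  if (!is.null(stratifier)) {
    if (!identical(stratifier, "intervention_type") || field != "intervention") {
      abort("The only supported stratifier is 'intervention_type', with field = 'intervention'.",
            class = "ctg_config_error")
    }
  }
  records <- as_record_list(records)
  if (field == "condition") {
    values <- unlist(map(records, function(r) r$conditions))
    values <- values %||% character()
    return(match_terms(values, lexicons, restrict_to, strict_case,
                       stratum = "all"))
  }
  iv <- map_dfr(records, function(r) r$interventions)
  if (nrow(iv) == 0) {
    iv <- tibble(intervention_type = character(), name = character())
  }
  all_tab <- match_terms(iv$name, lexicons, restrict_to, strict_case,
                         stratum = "all")
  if (is.null(stratifier)) return(all_tab)
  strata <- sort(unique(iv$intervention_type))
  per <- map_dfr(strata, function(s) {
    match_terms(iv$name[iv$intervention_type == s], lexicons, restrict_to,
                strict_case, stratum = s)
  })
  out <- bind_rows(per, all_tab)
  class(out) <- c("ctg_coverage", class(out))
  out
}
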