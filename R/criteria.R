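# Default bullet-marker set: the PRS-prepopulated hyphen plus common
# variants (asterisk, typographic bullet, numbered items like "1." / "2)").
ctg_default_bullets <- c("-", "*", "•", "numbered")

bullet_regex <- function(bullets = ctg_default_bullets) {
  parts <- c()
  literal <- setdiff(bullets, "numbered")
  if (length(literal) > 0) {
    # "-" must sit first inside the character class
    cls <- c(if ("-" %in% literal) "-", setdiff(literal, "-"))
    parts <- c(parts, paste0("[", paste0(cls, collapse = ""), "]"))
  }
  if ("numbered" %in% bullets) parts <- c(parts, "[0-9]+[.)]")
  paste0("^\\s*(", paste(parts, collapse = "|"), ")\\s*\\S")
}

canonical_header_regex <- "^(inclusion|exclusion) criteria:?$"
header_stem_regex <- "(inclusion|exclusion)\\s+criteria"

is_canonical_header <- function(line) {
  grepl(canonical_header_regex, tolower(str_squish(line)))
}

header_kind <- function(line) {
  m <- str_match(tolower(str_squish(line)), "^(inclusion|exclusion)")
  m[, 2]
}

is_header_like <- function(line) {
  grepl(header_stem_regex, tolower(str_squish(line)))
}

#' Classify an eligibility-criteria text block
#'
#' The expected format is the headers "Inclusion Criteria" and "Exclusion
#' Criteria", each followed by a bulleted list with one criterion per
#' bullet. Blocks are classified as:
#'
#' * `correct` -- both canonical headers present and every non-blank body
#'   line is a bullet line; the criteria are parsed into inclusion and
#'   exclusion lists.
#' * `headers_only` -- both canonical headers present but at least one
#'   body line is not bulleted (typically paragraph-style sentences
#'   interspersed with bullets).
#' * `malformed_headers` -- a header is missing, misspelled, or a variant
#'   ("Key Inclusion Criteria", "INCLUSION:").
#' * `missing` -- the block is absent or whitespace-only.
#'
#' Header matching is case-insensitive after whitespace normalization and
#' tolerates a trailing colon only. With `headers_required = FALSE` the
#' block is treated as a single already-split criteria field: header
#' errors cannot occur, and the block is `correct` iff every non-blank
#' line is a bullet line.
#'
#' @param text The text block, or `NA`.
#' @param bullets Bullet-marker set; any of `"-"`, `"*"`, `"•"` and
#'   `"numbered"` (digits followed by `.` or `)`).
#' @param headers_required Set to `FALSE` for separate per-field
#'   (headerless) classification.
#' @return One-row tibble: `format_class`, `multi_group_suspected`,
#'   list-columns `inclusion` and `exclusion` (non-empty only for
#'   `correct` blocks), and an `error_codes` list-column with machine
#'   codes (`MISSING_OR_MALFORMED_HEADERS`, `NONBULLETED_BODY`).
#' @examples
#' classify_criteria(
#'   "Inclusion Criteria:\n- age > 18\nExclusion Criteria:\n- pregnancy")
#' @export
classify_criteria <- function(text, bullets = ctg_default_bullets,
                              headers_required = TRUE) {
  result <- function(class, multi = FALSE, inclusion = character(),
                     exclusion = character(), codes = character()) {
    tibble(format_class = class, multi_group_suspected = multi,
           inclusion = list(inclusion), exclusion = list(exclusion),
           error_codes = list(codes))
  }
  if (is.null(text) || length(text) == 0 || is.na(text) ||
      str_trim(text) == "") {
    return(result("missing"))
  }
  lines <- str_split(text, "\n")[[1]]
  nonblank <- lines[str_trim(lines) != ""]
  brx <- bullet_regex(bullets)
  is_bullet <- function(line) grepl(brx, line)

  if (!headers_required) {
    if (all(map_lgl(nonblank, is_bullet))) {
      items <- strip_bullets(nonblank, brx)
      return(result("correct", inclusion = items))
    }
    return(result("headers_only", codes = "NONBULLETED_BODY"))
  }

  canonical <- map_lgl(nonblank, is_canonical_header)
  kinds <- header_kind(nonblank)
  has_incl <- any(canonical & kinds == "inclusion", na.rm = TRUE)
  has_excl <- any(canonical & kinds == "exclusion", na.rm = TRUE)
  multi <- detect_multi_group(text)

  if (!(has_incl && has_excl)) {
    return(result("malformed_headers", multi = multi,
                  codes = "MISSING_OR_MALFORMED_HEADERS"))
  }
  body <- nonblank[!canonical]
  if (!all(map_lgl(body, is_bullet))) {
    return(result("headers_only", multi = multi, codes = "NONBULLETED_BODY"))
  }

  # parse: bullets following each canonical header
  section <- NA_character_
  inclusion <- character(); exclusion <- character()
  for (i in seq_along(nonblank)) {
    if (canonical[i]) {
      section <- kinds[i]
    } else if (!is.na(section)) {
      item <- strip_bullets(nonblank[i], brx)
      if (section == "inclusion") inclusion <- c(inclusion, item)
      else exclusion <- c(exclusion, item)
    }
  }
  result("correct", multi = multi, inclusion = inclusion,
         exclusion = exclusion)
}

strip_bullets <- function(lines, brx) {
  marker <- sub("\\\\S$", "", brx)
  out <- str_trim(sub(marker, "", lines))
  out[out != ""]
}

#' Flag criteria blocks that define criteria for multiple participant groups
#'
#' A precision-oriented heuristic: a block is suspected of defining
#' separate criteria for sub-groups when more than two header-like lines
#' are found, or when a header-like line carries a qualifier naming a
#' group ("Inclusion Criteria - Cohort A", "Inclusion criteria for
#' healthy volunteers:"). Intended as an assist for manual review, not a
#' replacement for it.
#'
#' @param text The criteria text block.
#' @return Logical flag.
#' @export
detect_multi_group <- function(text) {
  if (is.null(text) || is.na(text) || str_trim(text) == "") return(FALSE)
  lines <- str_split(text, "\n")[[1]]
  lines <- lines[str_trim(lines) != ""]
  headerish <- lines[map_lgl(lines, is_header_like)]
  if (length(headerish) > 2) return(TRUE)
  any(map_lgl(headerish, function(line) {
    tail_txt <- str_match(tolower(str_squish(line)),
                          paste0(header_stem_regex, "(.*)$"))[, 3]
    !is.na(tail_txt) && str_trim(sub(":$", "", tail_txt)) != ""
  }))
}

#' Split a criteria block into separate inclusion and exclusion fields
#'
#' Extracts the body text under each header-like line into separate
#' inclusion and exclusion texts, emulating a registry design in which
#' inclusion and exclusion criteria are separate structured fields and no
#' user-supplied headers exist.
#'
#' @param text The criteria text block.
#' @return A list with `inclusion` and `exclusion` text blocks (possibly
#'   `NA` when a section is absent).
#' @export
split_criteria_fields <- function(text) {
  if (is.null(text) || is.na(text) || str_trim(text) == "") {
    return(list(inclusion = NA_character_, exclusion = NA_character_))
  }
  lines <- str_split(text, "\n")[[1]]
  section <- NA_character_
  acc <- list(inclusion = character(), exclusion = character())
  for (line in lines) {
    if (is_header_like(line) || grepl("^(inclusion|exclusion):?$",
                                      tolower(str_squish(line)))) {
      section <- header_kind(line)
    } else if (!is.na(section) && str_trim(line) != "") {
      acc[[section]] <- c(acc[[section]], line)
    }
  }
  list(
    inclusion = if (length(acc$inclusion) > 0)
      paste(acc$inclusion, collapse = "\n") else NA_character_,
    exclusion = if (length(acc$exclusion) > 0)
      paste(acc$exclusion, collapse = "\n") else NA_character_
  )
}

#' Extrapolate a sample proportion to a population count
#'
#' Computes the sample proportion, its 95% (by default) Wilson score
#' interval, and the population-scale point estimate
#' `round(proportion * population_size)`.
#'
#' @param sample_positive Number of positives in the sample.
#' @param sample_size Sample size (at least 1).
#' @param population_size Size of the population sampled from.
#' @param conf Confidence level for the Wilson interval.
#' @return An object of class `ctg_extrapolation`; see [generics::tidy()].
#' @examples
#' ex <- extrapolate(55, 400, 117906)
#' ex$point_estimate
#' @export
extrapolate <- function(sample_positive, sample_size, population_size,
                        conf = 0.95) {
  if (sample_size < 1 || sample_positive < 0 ||
      sample_positive > sample_size || population_size < sample_size) {
    abort("Require 0 <= sample_positive <= sample_size >= 1 and population_size >= sample_size.",
          class = "ctg_value_error")
  }
  p <- sample_positive / sample_size
  ci <- wilson_interval(sample_positive, sample_size, conf)
  structure(list(
    sample_positive = sample_positive, sample_size = sample_size,
    population_size = population_size, proportion = p,
    point_estimate = round(p * population_size),
    ci_low = ci[1], ci_high = ci[2],
    estimate_low = round(ci[1] * population_size),
    estimate_high = round(ci[2] * population_size),
    conf = conf
  ), class = "ctg_extrapolation")
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' @export
print.ctg_extrapolation <- function(x, ...) {
  cat(sprintf(
    "Sample %d/%d (%.1f%%) of population %d\n  point estimate %d, %d%% CI [%.4f, %.4f]\n",
    x$sample_positive, x$sample_size, 100 * x$proportion,
    x$population_size, x$point_estimate, round(100 * x$conf),
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Smallest sample size for a target margin of error
#'
#' The smallest n for which a normal-approximation margin of error on a
#' proportion, `z * sqrt(p(1-p)/n)`, does not exceed the target margin,
#' i.e. the smallest n with `z^2 p (1-p) / n <= margin^2`.
#'
#' @param confidence Confidence level (e.g. 0.95).
#' @param margin Target margin of error on the proportion scale.
#' @param worst_case_proportion Planning value for p; 0.5 is the
#'   conservative worst case.
#' @return Integer sample size.
#' @examples
#' sample_size_for_margin(0.95, 0.05)  # 385
#' @export
sample_size_for_margin <- function(confidence, margin,
                                   worst_case_proportion = 0.5) {
  if (margin <= 0 || margin >= 1 || confidence <= 0 || confidence >= 1 ||
      worst_case_proportion < 0 || worst_case_proportion > 1) {
    abort("Require 0 < margin < 1, 0 < confidence < 1, 0 <= p <= 1.",
          class = "ctg_value_error")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  exact <- z^2 * worst_case_proportion * (1 - worst_case_proportion) / margin^2
  n <- ceiling(exact)
  if (n < 1) n <- 1
  as.integer(n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname extrapolate
#' @param x A `ctg_extrapolation`.
#' @param ... Unused.
#' @export
tidy.ctg_extrapolation <- function(x, ...) {
  tibble(estimate = x$proportion, conf.low = x$ci_low, conf.high = x$ci_high,
         point_estimate = x$point_estimate,
         estimate_low = x$estimate_low, estimate_high = x$estimate_high)
}

#' @rdname extrapolate
#' @export
glance.ctg_extrapolation <- function(x, ...) {
  tibble(sample_positive = x$sample_positive, sample_size = x$sample_size,
         population_size = x$population_size, conf = x$conf)
}
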