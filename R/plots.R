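#' Plot lexicon coverage
#'
#' Column chart of the percentage of values exactly matched per source
#' vocabulary (and per stratum when present), in the style of
#' per-ontology coverage figures.
#'
#' @param coverage A `ctg_coverage` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, ...) {
  dat <- as_tibble(coverage)
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$source_id, -.data$pct), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Source vocabulary", y = "Values matched (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if (!all(is.na(dat$stratum)) && length(unique(dat$stratum)) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' @rdname plot_coverage
#' @param object A `ctg_coverage` tibble.
#' @export
autoplot.ctg_coverage <- function(object, ...) plot_coverage(object, ...)

#' Plot missing-field percentages
#'
#' Bar chart of the percentage of interventional records missing each
#' audited required field, optionally split by Final Rule era or agency
#' class (whichever strata the table carries).
#'
#' @param missing_table A table from [summarize_completeness()] (or the
#'   `missing_by_era` / `missing_by_agency` component of an audit
#'   summary).
#' @param min_pct Drop fields below this overall percentage (declutters
#'   the near-universal fields).
#' @return A ggplot object.
#' @export
plot_missingness <- function(missing_table, min_pct = 0.5) {
  dat <- missing_table %>%
    filter(.data$pct_all >= min_pct) %>%
    select("field", dplyr::starts_with("pct_")) %>%
    tidyr::pivot_longer(-"field", names_to = "stratum", values_to = "pct",
                        names_prefix = "pct_")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$field, .data$pct), y = .data$pct,
    fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Records missing field (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the eligibility-criteria format-class distribution
#'
#' @param summary A `ctg_audit_summary` (or its `criteria_table`).
#' @return A ggplot object.
#' @export
plot_criteria_classes <- function(summary) {
  tbl <- if (inherits(summary, "ctg_audit_summary"))
    summary$criteria_table else summary
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$format_class,
                                    y = .data$pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Criteria format class", y = "Records (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
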