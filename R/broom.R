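#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a validation report
#'
#' @param x A `mi2cast_report`.
#' @param ... Unused.
#' @return A plain tibble of findings.
#' @export
tidy.mi2cast_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "statement_ref") <- NULL
  out
}

#' One-row summary of a validation report
#'
#' @param x A `mi2cast_report`.
#' @param ... Unused.
#' @return A tibble with finding counts by severity, the statement key and
#'   the [compliance_level()].
#' @export
glance.mi2cast_report <- function(x, ...) {
  tibble::tibble(
    statement_key = attr(x, "statement_ref"),
    n_error = sum(x$severity == "ERROR"),
    n_warning = sum(x$severity == "WARNING"),
    n_info = sum(x$severity == "INFO"),
    compliance = compliance_level(x)
  )
}

#' Plot findings of a validation report
#'
#' Bar chart of finding counts per rule, filled by severity.
#'
#' @param object A `mi2cast_report` or the findings tibble of
#'   [validate_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi2cast_report <- function(object, ...) {
  plot_findings(tibble::as_tibble(object))
}

#' @rdname autoplot.mi2cast_report
#' @param findings A findings tibble with `rule_id` and `severity` columns.
#' @export
plot_findings <- function(findings) {
  severities <- c("ERROR", "WARNING", "INFO")
  df <- dplyr::count(tibble::as_tibble(findings), .data$rule_id,
                     .data$severity)
  df$severity <- factor(df$severity, levels = severities)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule_id, y = .data$n,
                                   fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(ERROR = "#b2182b", WARNING = "#ef8a62", INFO = "#67a9cf"),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = "findings", fill = "severity") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
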