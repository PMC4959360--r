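# Tidier and plotting methods for fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-group summary of an anonymization
#'
#' One row per released QID-group: report and distinct-case counts, the
#' group's information loss, and its worst effective disclosure confidence
#' relative to threshold.
#'
#' @param x An `ms_anon` object from [anonymize()].
#' @param ... Unused.
#' @return A tibble with columns `group`, `n_reports`, `n_cases`, `il`,
#'   `max_confidence`, `max_over_threshold`.
#' @export
tidy.ms_anon <- function(x, ...) {
  groups <- group_rows_of(x$data)
  rows <- lapply(names(groups), function(g) {
    sub <- x$data[groups[[g]], , drop = FALSE]
    cases <- collapse_cases(sub)
    cf <- .effective_conf(cases, x$policy$value, x$e)
    tibble::tibble(
      group = as.integer(g), n_reports = nrow(sub), n_cases = nrow(cases),
      il = information_loss(sub, x$schema),
      max_confidence = max(cf),
      max_over_threshold = max(cf - x$policy$theta)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$group)
}

#' One-row summary of an anonymization
#'
#' @param x An `ms_anon` object from [anonymize()].
#' @param ... Unused.
#' @return A one-row tibble: `n_groups`, `n_reports`, `n_cases`, `nil`,
#'   `dr`, `n_forced`, `n_merges`, `n_dropped`.
#' @export
glance.ms_anon <- function(x, ...) {
  if (nrow(x$data) == 0L) {
    return(tibble::tibble(n_groups = 0L, n_reports = 0L, n_cases = 0L,
                          nil = NA_real_, dr = NA_real_, n_forced = 0L,
                          n_merges = x$merges, n_dropped = x$dropped))
  }
  tibble::tibble(
    n_groups = nrow(x$groups),
    n_reports = nrow(x$data),
    n_cases = dplyr::n_distinct(x$data$case_id),
    nil = normalized_information_loss(x$data, x$schema),
    dr = as.numeric(dangerous_ratio(x$data, x$policy, x$e)),
    n_forced = length(x$forced),
    n_merges = x$merges,
    n_dropped = x$dropped
  )
}

#' Plot the QID-group structure of an anonymization
#'
#' Distinct-case count per released group, with the privacy parameter `k`
#' marked; every bar must reach the dashed line.
#'
#' @param object An `ms_anon` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_anon <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$group), y = .data$n_cases)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "QID-group", y = "distinct cases",
                  title = sprintf("Group sizes under MS(%d, theta*)-bounding",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a before/after signal comparison
#'
#' PRR on the original table against PRR on the anonymized table, one point
#' per rule; preserved signals sit on the identity line.
#'
#' @param object An `srs_signal_comparison` from [compare_signals()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srs_signal_comparison <- function(object, ...) {
  lab <- paste0(object$drug, " -> ", object$reaction,
                ifelse(is.na(object$condition), "",
                       paste0(" | ", object$condition)))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$prr_original,
                               y = .data$prr_anonymized)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = lab), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "PRR (original)", y = "PRR (anonymized)",
                  title = "ADR signal strength before vs after anonymization") +
    ggplot2::theme_minimal()
}

#' @export
glance.ms_compliance <- function(x, ...) {
  tibble::tibble(satisfied = is_satisfied(x), n_violations = nrow(x),
                 n_size_violations = sum(x$type == "group_size"),
                 n_confidence_violations = sum(x$type == "confidence"))
}
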