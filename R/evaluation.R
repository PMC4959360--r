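# Anonymization quality: data utility via normalized information loss and
# residual privacy risk via the dangerous ratio.

#' Normalized information loss of a released table
#'
#' `NIL = sum_g IL(g) / (n_g * |QID|)`: the summed group information loss
#' normalized by the number of QID-groups times the number of QID
#' attributes. Larger values mean poorer utility. Group membership counts
#' the released reports (post-split), not super records. The normalization
#' can exceed 1 for very large generalized groups; the raw value is
#' returned and a message flags the exceedance rather than clamping.
#'
#' @param data A released report tibble with a `.group` column (or a QID
#'   signature grouping via `schema`).
#' @param schema An [srs_schema()].
#' @return A non-negative number.
#' @export
normalized_information_loss <- function(data, schema) {
  groups <- group_rows_of(data, schema)
  if (length(groups) == 0L) stop("no QID-groups in 'data'")
  il <- vapply(groups, function(rows) {
    information_loss(data[rows, , drop = FALSE], schema)
  }, numeric(1))
  nil <- sum(il) / (length(groups) * length(qid_names(schema)))
  if (nil > 1) {
    message("normalized_information_loss: value ", signif(nil, 4),
            " exceeds 1 (large generalized groups)")
  }
  nil
}

#' Dangerous ratio of a released table
#'
#' The fraction of QID-groups containing at least one unsafe sensitive
#' value — one whose effective disclosure confidence,
#' `max(conf, conf_external)`, exceeds its policy threshold. The policy need
#' not be the one used to anonymize; cross-policy evaluation is how
#' competing models are compared.
#'
#' @param data A released report tibble with `.group` (or grouped by QID
#'   signature via `schema`).
#' @param policy A `sensitive_policy`.
#' @param e Optional `ext_knowledge` table.
#' @param schema Optional [srs_schema()] for signature grouping.
#' @return A number in \[0, 1\], with attribute `dangerous_groups`: a tibble
#'   of offending groups and their unsafe values.
#' @export
dangerous_ratio <- function(data, policy, e = NULL, schema = NULL) {
  groups <- group_rows_of(data, schema)
  if (length(groups) == 0L) stop("no QID-groups in 'data'")
  bad <- list()
  for (g in names(groups)) {
    cases <- collapse_cases(data[groups[[g]], , drop = FALSE])
    cf <- .effective_conf(cases, policy$value, e)
    unsafe <- which(cf > policy$theta + 1e-9)
    if (length(unsafe) > 0L) {
      bad[[length(bad) + 1L]] <- tibble::tibble(
        group = g, value = policy$value[unsafe], confidence = cf[unsafe],
        threshold = policy$theta[unsafe])
    }
  }
  dangerous <- if (length(bad) > 0L) dplyr::bind_rows(bad) else
    tibble::tibble(group = character(0), value = character(0),
                   confidence = numeric(0), threshold = numeric(0))
  structure(length(unique(dangerous$group)) / length(groups),
            dangerous_groups = dangerous)
}

#' Quality report for a released table
#'
#' Convenience wrapper bundling [normalized_information_loss()] and
#' [dangerous_ratio()] into one row.
#'
#' @inheritParams dangerous_ratio
#' @param schema An [srs_schema()] (required here, for NIL).
#' @return A one-row tibble: `n_groups`, `nil`, `dr`, `n_dangerous`.
#' @export
anonymization_quality <- function(data, policy, schema, e = NULL) {
  dr <- dangerous_ratio(data, policy, e, schema)
  tibble::tibble(
    n_groups = length(group_rows_of(data, schema)),
    nil = normalized_information_loss(data, schema),
    dr = as.numeric(dr),
    n_dangerous = length(unique(attr(dr, "dangerous_groups")$group))
  )
}
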