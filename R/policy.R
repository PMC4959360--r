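# The MS(k, theta*)-bounding model: which sensitive values are protected,
# at what disclosure-probability threshold, and whether a (grouped) table
# complies. Confidence denominators count DISTINCT CASES, not reports:
# follow-up duplicates must not dilute an attacker's inference.

#' Build a sensitive-value policy with a uniform threshold
#'
#' Every protected value receives the same disclosure-probability bound.
#'
#' @param s_set Character vector of protected sensitive values.
#' @param theta Threshold in (0, 1].
#' @return A tibble of class `sensitive_policy` with columns `value`, `theta`.
#' @export
build_uniform_policy <- function(s_set, theta) {
  .check_theta(theta)
  new_policy(s_set, rep_len(theta, length(s_set)))
}

#' Build a level-wise sensitive-value policy
#'
#' Values are split into three sensitivity levels: "high sensitive" values
#' receive a tight bound, "non-sensitive" values receive 1 (no protection),
#' and everything else a default bound.
#'
#' @param all_values All sensitive values in scope.
#' @param high,nonsensitive Disjoint subsets of `all_values`.
#' @param theta_high Threshold for `high` (default 0.2).
#' @param theta_default Threshold for the remaining values (default 0.4).
#' @return A `sensitive_policy`.
#' @export
build_levelwise_policy <- function(all_values, high = character(),
                                   nonsensitive = character(),
                                   theta_high = 0.2, theta_default = 0.4) {
  .check_theta(theta_high); .check_theta(theta_default)
  overlap <- intersect(high, nonsensitive)
  if (length(overlap) > 0L) {
    stop("value(s) in both 'high' and 'nonsensitive': ",
         paste(overlap, collapse = ", "))
  }
  theta <- rep_len(theta_default, length(all_values))
  theta[all_values %in% high] <- theta_high
  theta[all_values %in% nonsensitive] <- 1
  new_policy(all_values, theta)
}

#' Build a frequency-based sensitive-value policy
#'
#' Encodes "the more frequently a symptom occurs, the less sensitive it is":
#' symptoms are ranked by descending case frequency (fraction of distinct
#' cases containing the symptom); the top `top_frac` share receive threshold
#' `theta_top` (default 1, unprotected), the bottom `bottom_frac` share
#' `theta_bottom` (default 0.2), and the rest `theta_mid` (default 0.4).
#' Bucket sizes are `ceiling(frac * m)`; the top bucket wins ties, and equal
#' frequencies are ordered lexicographically for determinism.
#'
#' @param data A report tibble with an `sa` list-column.
#' @param top_frac,bottom_frac Bucket proportions; their sum must not
#'   exceed 1.
#' @param theta_top,theta_mid,theta_bottom Thresholds per bucket.
#' @return A `sensitive_policy` covering every symptom observed in `data`.
#' @export
build_frequency_policy <- function(data, top_frac = 0.1, bottom_frac = 0.1,
                                   theta_top = 1, theta_mid = 0.4,
                                   theta_bottom = 0.2) {
  stopifnot(top_frac >= 0, bottom_frac >= 0, top_frac + bottom_frac <= 1)
  freq <- sensitive_frequencies(data)
  m <- nrow(freq)
  if (m == 0L) stop("no sensitive values observed in 'data'")
  freq <- freq[order(-freq$frequency, freq$value), ]
  n_top <- min(m, ceiling(top_frac * m - 1e-9))
  n_bot <- min(m - n_top, ceiling(bottom_frac * m - 1e-9))
  theta <- rep_len(theta_mid, m)
  if (n_top > 0L) theta[seq_len(n_top)] <- theta_top
  if (n_bot > 0L) theta[(m - n_bot + 1L):m] <- theta_bottom
  new_policy(freq$value, theta)
}

#' Empirical case frequencies of sensitive values
#'
#' For each sensitive term, the fraction of distinct cases whose (unioned)
#' SA set contains it.
#'
#' @param data A report tibble with `case_id` and `sa` columns.
#' @return A tibble with columns `value`, `n_cases`, `frequency`, sorted by
#'   descending frequency.
#' @export
sensitive_frequencies <- function(data) {
  cases <- collapse_cases(data)
  n <- nrow(cases)
  counts <- table(unlist(lapply(cases$sa, unique)))
  out <- tibble::tibble(value = as.character(names(counts)),
                        n_cases = as.integer(counts),
                        frequency = as.integer(counts) / max(n, 1L))
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$value)
}

new_policy <- function(values, theta) {
  if (length(values) == 0L) stop("sensitive-value set must be non-empty")
  stopifnot(all(theta > 0), all(theta <= 1))
  out <- tibble::tibble(value = as.character(values), theta = as.numeric(theta))
  if (anyDuplicated(out$value)) {
    stop("duplicate sensitive value in policy: ",
         out$value[duplicated(out$value)][1])
  }
  class(out) <- c("sensitive_policy", class(out))
  out
}

.check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1) {
    stop("theta must be a single probability in (0, 1]")
  }
}

# ---- confidence -------------------------------------------------------------

# collapse reports to one row per distinct case: SA/QSA unioned
collapse_cases <- function(data) {
  if (nrow(data) == 0L) {
    return(tibble::tibble(case_id = character(0),
                          sa = list(), qsa = list()))
  }
  dplyr::summarise(
    data,
    sa = list(sort(unique(unlist(.data$sa)))),
    qsa = list(sort(unique(unlist(.data$qsa)))),
    .by = "case_id"
  )
}

#' Disclosure confidence of a sensitive value within a group
#'
#' The probability that a member of the QID-group has sensitive value `s`:
#' the number of distinct cases whose SA set contains `s` over the number of
#' distinct cases in the group.
#'
#' @param group A report tibble (the rows of one QID-group).
#' @param s A sensitive value.
#' @return A probability in \[0, 1\].
#' @export
conf <- function(group, s) {
  cases <- collapse_cases(group)
  stopifnot(nrow(cases) > 0L)
  mean(vapply(cases$sa, function(v) s %in% v, NA))
}

#' Disclosure confidence after linking an external knowledge table
#'
#' Models an attacker who links the group's drugs (QSA) to the diseases they
#' treat. Each distinct case contributes 1 if its SA set contains `s`
#' directly; otherwise, with `U` the union of the disease sets of the case's
#' drugs, it contributes `1/|U|` when `s` is in `U` and 0 when not (the
#' attacker's inference is uniform over the candidate diseases). The group
#' confidence is the mean contribution over distinct cases. Drugs absent
#' from the table contribute nothing (with a warning).
#'
#' @param group A report tibble (the rows of one QID-group).
#' @param s A sensitive value (disease or symptom term).
#' @param e An `ext_knowledge` table, or `NULL` (contributions fall back to
#'   direct SA containment only).
#' @return A probability in \[0, 1\].
#' @export
conf_external <- function(group, s, e) {
  cases <- collapse_cases(group)
  stopifnot(nrow(cases) > 0L)
  contrib <- vapply(seq_len(nrow(cases)), function(i) {
    if (s %in% cases$sa[[i]]) return(1)
    u <- ext_disease_union(e, cases$qsa[[i]], warn_missing = TRUE)
    if (length(u) > 0L && s %in% u) 1 / length(u) else 0
  }, numeric(1))
  mean(contrib)
}

# max(conf, conf_external) for every value in `values`, vectorized over one
# group's collapsed cases; used by compliance checking and dangerous_ratio
.effective_conf <- function(cases, values, e) {
  n <- nrow(cases)
  direct <- vapply(values, function(s)
    sum(vapply(cases$sa, function(v) s %in% v, NA)), numeric(1))
  unions <- lapply(cases$qsa, function(d) ext_disease_union(e, d))
  extern <- vapply(values, function(s) {
    sum(vapply(seq_len(n), function(i) {
      if (s %in% cases$sa[[i]]) return(1)
      u <- unions[[i]]
      if (length(u) > 0L && s %in% u) 1 / length(u) else 0
    }, numeric(1)))
  }, numeric(1))
  pmax(direct, extern) / n
}

# ---- compliance -------------------------------------------------------------

# split a grouped table into a named list of row-index vectors
group_rows_of <- function(data, schema = NULL) {
  if (".group" %in% names(data)) {
    key <- as.character(data$.group)
  } else {
    if (is.null(schema)) {
      stop("data carries no .group column; supply a schema to group by QID signature")
    }
    qids <- qid_names(schema)
    key <- do.call(paste, c(lapply(qids, function(nm) as.character(data[[nm]])),
                            sep = " | "))
  }
  split(seq_len(nrow(data)), key)
}

#' Check a released table against MS(k, theta*)-bounding
#'
#' Verifies, for every QID-group, that (1) the group contains at least `k`
#' distinct cases and (2) for every protected sensitive value, the
#' disclosure confidence — with or without external linkage, i.e.
#' `max(conf, conf_external)` — does not exceed its threshold.
#'
#' Groups are taken from the `.group` column when present, otherwise rows
#' sharing an identical QID signature form a group (requires `schema`).
#'
#' @param data The released report tibble.
#' @param k Minimum number of distinct cases per group.
#' @param policy A `sensitive_policy`.
#' @param e Optional `ext_knowledge` table.
#' @param schema Optional [srs_schema()], needed only when `data` has no
#'   `.group` column.
#' @return A tibble of class `ms_compliance` listing every violation
#'   (columns `group`, `type`, `value`, `confidence`, `threshold`,
#'   `n_cases`), with attribute `satisfied` (`TRUE` iff no rows).
#' @export
check_ms_bounding <- function(data, k, policy, e = NULL, schema = NULL) {
  stopifnot(k >= 1)
  groups <- group_rows_of(data, schema)
  viol <- list()
  for (g in names(groups)) {
    cases <- collapse_cases(data[groups[[g]], , drop = FALSE])
    n <- nrow(cases)
    if (n < k) {
      viol[[length(viol) + 1L]] <- tibble::tibble(
        group = g, type = "group_size", value = NA_character_,
        confidence = NA_real_, threshold = NA_real_, n_cases = n)
    }
    cf <- .effective_conf(cases, policy$value, e)
    bad <- which(cf > policy$theta + 1e-9)
    if (length(bad) > 0L) {
      viol[[length(viol) + 1L]] <- tibble::tibble(
        group = g, type = "confidence", value = policy$value[bad],
        confidence = cf[bad], threshold = policy$theta[bad], n_cases = n)
    }
  }
  out <- if (length(viol) > 0L) dplyr::bind_rows(viol) else
    tibble::tibble(group = character(0), type = character(0),
                   value = character(0), confidence = numeric(0),
                   threshold = numeric(0), n_cases = integer(0))
  structure(out, satisfied = nrow(out) == 0L,
            class = c("ms_compliance", class(out)))
}

#' Is a compliance report satisfied?
#'
#' @param x An `ms_compliance` object from [check_ms_bounding()].
#' @return `TRUE` iff no violations were found.
#' @export
is_satisfied <- function(x) {
  stopifnot(inherits(x, "ms_compliance"))
  isTRUE(attr(x, "satisfied"))
}

#' Warn about thresholds below a value's global frequency
#'
#' Generalization can never push a group's confidence for `s` below the
#' dataset-wide case frequency `P(s)`: every threshold must satisfy
#' `theta_s >= P(s)` or the bound is unattainable by generalization alone.
#'
#' @param data A report tibble.
#' @param policy A `sensitive_policy`.
#' @return A tibble of warnings (columns `value`, `frequency`, `threshold`);
#'   zero rows when every threshold is attainable.
#' @export
validate_thresholds <- function(data, policy) {
  freq <- sensitive_frequencies(data)
  joined <- dplyr::inner_join(freq, policy, by = "value")
  bad <- joined[joined$frequency > joined$theta + 1e-9, ]
  out <- tibble::tibble(value = bad$value, frequency = bad$frequency,
                        threshold = bad$theta)
  if (nrow(out) > 0L) {
    warning("threshold below global frequency for: ",
            paste(out$value, collapse = ", "),
            " - the bound cannot be met by generalization alone",
            call. = FALSE)
  }
  out
}
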