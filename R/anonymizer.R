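# Greedy clustering anonymizer.
#
# Stage 1: reports sharing a CaseID are merged into super records; groups are
# grown greedily from a seed record, always adding the candidate minimizing
# delta-IL' = delta-IL x PR (information-loss increase times privacy risk),
# until the group holds >= k distinct cases and every protected sensitive
# value's effective confidence is within its threshold.
# Stage 2: leftover records are placed into the least-cost groups, super
# records are split back into their original reports, and each group's QID
# values are generalized to a common signature.

#' Merge follow-up reports into super records
#'
#' All reports sharing a `case_id` are combined into one record: numeric QID
#' values are generalized to the members' `[min-max]` interval, categorical
#' QID values to their lowest common ancestor, and SA/QSA sets are unioned.
#' This keeps follow-ups of one case in the same QID-group, so duplicates can
#' neither shrink a group's effective size nor bias signal counts.
#'
#' @param data A report tibble.
#' @param schema An [srs_schema()].
#' @return A tibble with one row per distinct case (in order of first
#'   appearance): `case_id`, `member_isrs` (list-column), the QID columns,
#'   `sa`, `qsa`.
#' @export
combine_case_records <- function(data, schema) {
  qids <- qid_names(schema)
  ids <- unique(data$case_id)
  rows <- lapply(ids, function(cid) {
    sub <- data[data$case_id == cid, , drop = FALSE]
    out <- tibble::tibble(case_id = cid, member_isrs = list(sub$isr))
    for (nm in qids) {
      row <- schema_row(schema, nm)
      if (row$kind == "numeric") {
        iv <- parse_interval(sub[[nm]])
        out[[nm]] <- format_interval(min(iv$lo), max(iv$hi))
      } else {
        vals <- unique(as.character(sub[[nm]]))
        out[[nm]] <- if (length(vals) == 1L) vals else
          lca(schema_hierarchy(schema, nm), vals)
      }
    }
    out$sa <- list(sort(unique(unlist(sub$sa))))
    out$qsa <- list(sort(unique(unlist(sub$qsa))))
    out
  })
  dplyr::bind_rows(rows)
}

#' Information loss of a QID-group
#'
#' `IL(g) = |g| * (sum_i range_i(g)/range_i(D) + sum_j h(C_j, g)/h(C_j))`:
#' the group size times the sum, over numeric QID attributes, of the group's
#' value range normalized by the attribute's global domain range, plus, over
#' categorical QID attributes, the height of the group's lowest common
#' ancestor normalized by the hierarchy height. A group homogeneous in every
#' QID attribute loses nothing.
#'
#' @param group A report (or super-record) tibble; `|g|` is its row count.
#' @param schema An [srs_schema()] with domains and hierarchies for every
#'   QID attribute.
#' @return A non-negative number.
#' @export
information_loss <- function(group, schema) {
  stopifnot(nrow(group) > 0L)
  nrow(group) * .il_terms(group, schema)
}

# the per-record part of IL: sum of normalized ranges and LCA heights
.il_terms <- function(group, schema) {
  total <- 0
  for (nm in qid_names(schema)) {
    row <- schema_row(schema, nm)
    if (row$kind == "numeric") {
      iv <- parse_interval(group[[nm]])
      if (anyNA(iv$lo)) stop("missing value in numeric QID '", nm, "'")
      if (min(iv$lo) < row$min || max(iv$hi) > row$max) {
        stop("value of '", nm, "' outside declared domain [",
             row$min, ", ", row$max, "]")
      }
      total <- total + (max(iv$hi) - min(iv$lo)) / (row$max - row$min)
    } else {
      h <- schema_hierarchy(schema, nm)
      total <- total + lca_height(h, as.character(group[[nm]])) / hierarchy_height(h)
    }
  }
  total
}

#' Information-loss increase from adding a record to a group
#'
#' `delta_il(g, r) = IL(g + r) - IL(g)`; non-negative for non-empty groups,
#' since adding a record can only widen extents and raise LCA heights.
#'
#' @param group A report tibble (the group).
#' @param r A one-row tibble (the candidate record).
#' @param schema An [srs_schema()].
#' @return A non-negative number.
#' @export
delta_il <- function(group, r, schema) {
  information_loss(dplyr::bind_rows(group, r), schema) -
    information_loss(group, schema)
}

#' Breach capacity of a sensitive value in a group
#'
#' The maximum number of members of a group that may carry sensitive value
#' `s` without breaching its threshold: `floor(max(k, n) * theta_s)`, where
#' `n` is the group's distinct-case count. During greedy selection this is
#' evaluated on the post-inclusion group.
#'
#' @param n Group size (distinct cases), or a report tibble whose distinct
#'   cases are counted.
#' @param k The minimum group size of the privacy model.
#' @param theta_s The threshold of `s`.
#' @return A non-negative integer.
#' @export
eta <- function(n, k, theta_s) {
  if (is.data.frame(n)) n <- nrow(collapse_cases(n))
  floor(max(k, n) * theta_s + 1e-9)   # guard against 5*0.6 -> 2.999...
}

#' Privacy risk of adding a record to a group
#'
#' For each protected sensitive value `s` carried by the candidate record,
#' the marginal risk is `sigma_s / (eta_s - sigma_s)` — how close the
#' group's current count of `s` (`sigma_s`) sits to the post-inclusion
#' breach capacity `eta_s` — or infinite when the capacity is already
#' exhausted. The record's total risk is 1 plus the sum over its protected
#' values (the unit increment keeps information loss effective when all of
#' the record's sensitive values are new to the group).
#'
#' @param group A report tibble (the group).
#' @param r A one-row tibble (the candidate; its `sa` entry holds the
#'   sensitive values).
#' @param k Minimum group size.
#' @param policy A `sensitive_policy`.
#' @return A number `>= 1`, or `Inf` when the inclusion would breach a
#'   threshold.
#' @export
privacy_risk <- function(group, r, k, policy) {
  cases <- collapse_cases(group)
  s_r <- intersect(unlist(r$sa), policy$value)
  if (length(s_r) == 0L) return(1)
  n_after <- nrow(cases) + !(r$case_id[1] %in% cases$case_id)
  total <- 1
  for (s in s_r) {
    sigma <- sum(vapply(cases$sa, function(v) s %in% v, NA))
    cap <- eta(n_after, k, policy$theta[match(s, policy$value)])
    if (cap <= sigma) return(Inf)
    total <- total + sigma / (cap - sigma)
  }
  total
}

#' Combined greedy selection metric
#'
#' `delta_il_prime(g, r) = delta_il(g, r) * privacy_risk(g, r)`; infinite
#' privacy risk propagates (a record whose inclusion breaches a threshold is
#' never selected, regardless of information loss).
#'
#' @inheritParams privacy_risk
#' @param schema An [srs_schema()].
#' @return A non-negative number or `Inf`.
#' @export
delta_il_prime <- function(group, r, k, policy, schema) {
  pr <- privacy_risk(group, r, k, policy)
  if (is.infinite(pr)) return(Inf)
  delta_il(group, r, schema) * pr
}

#' Select the best candidate record for a group
#'
#' Returns the candidate minimizing [delta_il_prime()]; ties are broken by
#' smaller [delta_il()], then by `case_id` order. When every candidate
#' scores infinite (each would breach a threshold), `NULL` is returned.
#'
#' @inheritParams delta_il_prime
#' @param candidates A tibble of candidate records.
#' @return A one-row tibble, or `NULL`.
#' @export
select_best_record <- function(group, candidates, k, policy, schema) {
  stopifnot(nrow(candidates) > 0L)
  dprime <- dil <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, , drop = FALSE]
    dil[i] <- delta_il(group, r, schema)
    pr <- privacy_risk(group, r, k, policy)
    dprime[i] <- if (is.infinite(pr)) Inf else dil[i] * pr
  }
  if (all(is.infinite(dprime))) return(NULL)
  candidates[order(dprime, dil, candidates$case_id)[1], , drop = FALSE]
}

#' Select the seed record for a new group
#'
#' The first group is seeded by a uniformly random candidate (under the
#' caller's RNG state); each later group is seeded by the candidate most
#' distinguished from the previous group's seed — the one maximizing the
#' information loss of the pair — so that successive groups start far apart
#' in QID space. Ties are broken by `case_id` order.
#'
#' @param prev_seed A one-row tibble (the previous group's seed), or `NULL`
#'   for the first group.
#' @param candidates A tibble of candidate records.
#' @param schema An [srs_schema()].
#' @return A one-row tibble.
#' @export
select_seed_record <- function(prev_seed, candidates, schema) {
  stopifnot(nrow(candidates) > 0L)
  if (is.null(prev_seed)) {
    return(candidates[sample.int(nrow(candidates), 1L), , drop = FALSE])
  }
  pair_il <- vapply(seq_len(nrow(candidates)), function(i) {
    information_loss(dplyr::bind_rows(prev_seed, candidates[i, ]), schema)
  }, numeric(1))
  candidates[order(-pair_il, candidates$case_id)[1], , drop = FALSE]
}

# ==== vectorized engine ======================================================
# The tibble-level operations above define the semantics; the engine below
# restates them on preindexed matrices so clustering scales to thousands of
# super records. Equivalence is covered by tests.

.anon_prep <- function(supers, schema, policy, e) {
  n <- nrow(supers)
  qids <- qid_names(schema)
  num <- qids[vapply(qids, function(nm) schema_row(schema, nm)$kind == "numeric", NA)]
  cat <- setdiff(qids, num)
  lo <- hi <- matrix(0, n, length(num), dimnames = list(NULL, num))
  domr <- numeric(length(num)); names(domr) <- num
  dmin <- numeric(length(num)); names(dmin) <- num
  for (nm in num) {
    row <- schema_row(schema, nm)
    iv <- parse_interval(supers[[nm]])
    if (anyNA(iv$lo)) stop("missing value in numeric QID '", nm, "'")
    if (min(iv$lo) < row$min || max(iv$hi) > row$max) {
      stop("value of '", nm, "' outside declared domain [", row$min, ", ",
           row$max, "]")
    }
    lo[, nm] <- iv$lo; hi[, nm] <- iv$hi
    domr[nm] <- row$max - row$min; dmin[nm] <- row$min
  }
  hier <- lapply(cat, function(nm) schema_hierarchy(schema, nm))
  names(hier) <- cat
  node <- matrix(0L, n, length(cat), dimnames = list(NULL, cat))
  for (nm in cat) node[, nm] <- .node_id(hier[[nm]], as.character(supers[[nm]]))
  s_vals <- policy$value
  M <- matrix(0, n, length(s_vals))
  effc <- matrix(0, n, length(s_vals))
  for (i in seq_len(n)) {
    d <- match(intersect(supers$sa[[i]], s_vals), s_vals)
    M[i, d] <- 1
    u <- ext_disease_union(e, supers$qsa[[i]])
    ext <- match(intersect(setdiff(u, supers$sa[[i]]), s_vals), s_vals)
    effc[i, d] <- 1
    if (length(ext) > 0L) effc[i, ext] <- 1 / length(u)
  }
  list(n = n, num = num, cat = cat, lo = lo, hi = hi, domr = domr,
       hier = hier, node = node, M = M, effc = effc, theta = policy$theta,
       case_id = supers$case_id)
}

.g_new <- function(prep, i) {
  list(idx = i, sz = 1L,
       lo = prep$lo[i, ], hi = prep$hi[i, ], cov = prep$node[i, ],
       sigma = prep$M[i, ], effsum = prep$effc[i, ])
}

.g_add <- function(st, prep, i) {
  st$idx <- c(st$idx, i); st$sz <- st$sz + 1L
  st$lo <- pmin(st$lo, prep$lo[i, ]); st$hi <- pmax(st$hi, prep$hi[i, ])
  for (j in seq_along(prep$cat)) {
    st$cov[j] <- prep$hier[[j]]$lca_id[st$cov[j], prep$node[i, j]]
  }
  st$sigma <- st$sigma + prep$M[i, ]
  st$effsum <- st$effsum + prep$effc[i, ]
  st
}

.g_terms <- function(st, prep) {
  t_num <- if (length(prep$num) > 0L) sum((st$hi - st$lo) / prep$domr) else 0
  t_cat <- 0
  for (j in seq_along(prep$cat)) {
    h <- prep$hier[[j]]
    t_cat <- t_cat + h$node_height[st$cov[j]] / h$height
  }
  t_num + t_cat
}

.g_il <- function(st, prep) st$sz * .g_terms(st, prep)

# delta-IL of adding each candidate (vectorized over candidate indices)
.g_dil_vec <- function(st, prep, cand) {
  t_num <- numeric(length(cand))
  for (nm in prep$num) {
    t_num <- t_num + (pmax(st$hi[nm], prep$hi[cand, nm]) -
                      pmin(st$lo[nm], prep$lo[cand, nm])) / prep$domr[nm]
  }
  t_cat <- numeric(length(cand))
  for (j in seq_along(prep$cat)) {
    h <- prep$hier[[j]]
    t_cat <- t_cat + h$lca_h[st$cov[j], prep$node[cand, j]] / h$height
  }
  (st$sz + 1L) * (t_num + t_cat) - .g_il(st, prep)
}

# privacy risk of adding each candidate
.g_pr_vec <- function(st, prep, cand, k) {
  cap <- floor(pmax(k, st$sz + 1L) * prep$theta + 1e-9)
  breach <- cap <= st$sigma
  prs <- ifelse(cap > st$sigma, st$sigma / (cap - st$sigma), 0)
  Mc <- prep$M[cand, , drop = FALSE]
  pr <- 1 + as.vector(Mc %*% ifelse(breach, 0, prs))
  pr[as.vector(Mc %*% breach) > 0] <- Inf
  pr
}

.g_compliant <- function(st, prep, k) {
  st$sz >= k && all(st$effsum / st$sz <= prep$theta + 1e-9)
}

#' Greedy clustering of super records into compliant QID-groups
#'
#' Stage 1 of the anonymizer. Each group starts from a seed record (see
#' [select_seed_record()]) and grows by repeatedly adding the candidate with
#' the least [delta_il_prime()] until it holds at least `k` distinct cases
#' and every protected value's effective confidence (direct or via external
#' linkage) is within threshold. Clustering stops when fewer than `k`
#' records remain or a group cannot be completed (e.g. the remaining records
#' all share an over-represented sensitive value); unassigned records are
#' left as residuals for [finalize_groups()].
#'
#' @param supers A super-record tibble from [combine_case_records()].
#' @param k Minimum distinct cases per group.
#' @param policy A `sensitive_policy`.
#' @param schema An [srs_schema()].
#' @param e Optional `ext_knowledge` table.
#' @param rng_seed Integer seed for the random first-group seed; all other
#'   steps are deterministic.
#' @return `supers` with an added integer `.group` column (`NA` marks
#'   residuals).
#' @export
build_groups <- function(supers, k, policy, schema, e = NULL, rng_seed = 0L) {
  out <- supers
  if (nrow(supers) == 0L) {
    out$.group <- integer(0)
    return(out)
  }
  prep <- .anon_prep(supers, schema, policy, e)
  set.seed(rng_seed)
  active <- rep(TRUE, prep$n)
  assign <- rep(NA_integer_, prep$n)
  gid <- 0L
  prev_seed <- NA_integer_
  while (sum(active) >= k) {
    cand <- which(active)
    if (is.na(prev_seed)) {
      seed_i <- cand[sample.int(length(cand), 1L)]
    } else {
      st0 <- .g_new(prep, prev_seed)
      pair <- .g_dil_vec(st0, prep, cand)
      seed_i <- cand[order(-pair, prep$case_id[cand])][1]
    }
    st <- .g_new(prep, seed_i)
    active[seed_i] <- FALSE
    completed <- FALSE
    repeat {
      if (.g_compliant(st, prep, k)) { completed <- TRUE; break }
      cand <- which(active)
      if (length(cand) == 0L) break
      dil <- .g_dil_vec(st, prep, cand)
      pr <- .g_pr_vec(st, prep, cand, k)
      dp <- dil * pr
      dp[is.infinite(pr)] <- Inf
      if (all(is.infinite(dp))) break
      pick <- cand[order(dp, dil, prep$case_id[cand])][1]
      st <- .g_add(st, prep, pick)
      active[pick] <- FALSE
    }
    if (completed) {
      gid <- gid + 1L
      assign[st$idx] <- gid
      prev_seed <- seed_i
    } else {
      # dissolve the stuck group; remaining records become residuals
      active[st$idx] <- TRUE
      break
    }
  }
  out$.group <- assign
  out
}

# rebuild engine states for already-assigned groups
.g_states <- function(prep, assign) {
  lapply(sort(unique(assign[!is.na(assign)])), function(g) {
    idx <- which(assign == g)
    st <- .g_new(prep, idx[1])
    for (i in idx[-1]) st <- .g_add(st, prep, i)
    st
  })
}

#' Residual placement, splitting, and QID generalization
#'
#' Stage 2 of the anonymizer. Each residual super record joins the existing
#' group with the least finite [delta_il_prime()]; when every group scores
#' infinite, the group with the least [delta_il()] is used and the placement
#' is recorded as forced. Any group left over threshold is then repaired by
#' merging it with the group giving the cheapest combined information loss
#' (merging dilutes confidence; in the limit the whole table is one group,
#' whose confidences equal the global frequencies). Finally super records
#' are split back into their original reports and every group's QID values
#' are generalized to a common signature.
#'
#' @param grouped Output of [build_groups()] (super records with `.group`).
#' @param data The report tibble the super records were built from.
#' @param k,policy,schema,e As in [build_groups()].
#' @return A list with `data` (the released report tibble, QID generalized,
#'   with `.group`), `forced` (residual case_ids whose placement was
#'   forced), and `merges` (number of repair merges).
#' @export
finalize_groups <- function(grouped, data, k, policy, schema, e = NULL) {
  residual_idx <- which(is.na(grouped$.group))
  if (length(residual_idx) > 0L && all(is.na(grouped$.group))) {
    stop("no compliant groups were formed; cannot place ",
         length(residual_idx), " residual records (k or theta* too strict ",
         "for this table)")
  }
  prep <- .anon_prep(grouped, schema, policy, e)
  assign <- grouped$.group
  states <- .g_states(prep, assign)
  forced <- character(0)
  residual_idx <- residual_idx[order(prep$case_id[residual_idx])]
  for (i in residual_idx) {
    dil <- vapply(states, function(st) .g_dil_vec(st, prep, i), numeric(1))
    pr <- vapply(states, function(st) .g_pr_vec(st, prep, i, k), numeric(1))
    dp <- dil * pr
    dp[is.infinite(pr)] <- Inf
    if (all(is.infinite(dp))) {
      g <- order(dil)[1]
      forced <- c(forced, prep$case_id[i])
    } else {
      g <- order(dp, dil)[1]
    }
    states[[g]] <- .g_add(states[[g]], prep, i)
    assign[i] <- g
  }
  # repair: merge any over-threshold group into its cheapest partner
  merges <- 0L
  repeat {
    bad <- which(!vapply(states, .g_compliant, NA, prep = prep, k = k))
    if (length(bad) == 0L || length(states) == 1L) break
    b <- bad[1]
    others <- setdiff(seq_along(states), b)
    cost <- vapply(others, function(o) {
      .merged_il(states[[b]], states[[o]], prep)
    }, numeric(1))
    o <- others[order(cost)[1]]
    states[[o]] <- .g_merge(states[[o]], states[[b]], prep)
    assign[assign == b] <- o
    states <- states[-b]
    assign <- match(assign, sort(unique(assign)))
    merges <- merges + 1L
  }
  if (merges > 0L) {
    message("finalize_groups: ", merges,
            " repair merge(s) were needed to restore compliance")
  }
  released <- .generalize_split(grouped, assign, states, data, schema, prep)
  list(data = released, forced = forced, merges = merges)
}

.g_merge <- function(a, b, prep) {
  for (i in b$idx) a <- .g_add(a, prep, i)
  a
}

.merged_il <- function(a, b, prep) {
  m <- a
  for (i in b$idx) m <- .g_add(m, prep, i)
  .g_il(m, prep)
}

.generalize_split <- function(grouped, assign, states, data, schema, prep) {
  case_group <- stats::setNames(assign, grouped$case_id)
  out <- data
  out$.group <- as.integer(case_group[data$case_id])
  for (g in seq_along(states)) {
    st <- states[[g]]
    rows <- which(out$.group == g)
    for (nm in prep$num) {
      if (!is.character(out[[nm]])) out[[nm]] <- .num_chr(out[[nm]])
      out[[nm]][rows] <- format_interval(st$lo[nm], st$hi[nm])
    }
    for (j in seq_along(prep$cat)) {
      nm <- prep$cat[j]
      out[[nm]][rows] <- prep$hier[[j]]$labels[st$cov[j]]
    }
  }
  out
}

#' Anonymize a report table to MS(k, theta*)-bounding
#'
#' Runs the full pipeline: [drop_missing_qid()], [combine_case_records()],
#' [build_groups()], [finalize_groups()]. The released table keeps every
#' surviving report (same ISR multiset), with QID values generalized per
#' group and a `.group` column.
#'
#' @param data A report tibble.
#' @param k Minimum distinct cases per QID-group.
#' @param policy A `sensitive_policy`.
#' @param schema An [srs_schema()].
#' @param e Optional `ext_knowledge` table.
#' @param rng_seed Integer seed; identical inputs and seed give identical
#'   output.
#' @return An object of class `ms_anon`: a list with `data` (the released
#'   tibble), `groups` (per-group summary tibble), `forced`, `merges`,
#'   `dropped` (reports removed for missing QID), `k`, `policy`, `schema`.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
anonymize <- function(data, k, policy, schema, e = NULL, rng_seed = 0L) {
  threshold_warnings <- validate_thresholds(data, policy)
  kept <- drop_missing_qid(data, schema)
  dropped <- nrow(data) - nrow(kept)
  if (nrow(kept) == 0L) {
    released <- kept
    released$.group <- integer(0)
    fin <- list(data = released, forced = character(0), merges = 0L)
  } else {
    supers <- combine_case_records(kept, schema)
    grouped <- build_groups(supers, k, policy, schema, e, rng_seed)
    fin <- finalize_groups(grouped, kept, k, policy, schema, e)
  }
  groups <- if (nrow(fin$data) == 0L) {
    tibble::tibble(group = integer(0), n_reports = integer(0),
                   n_cases = integer(0))
  } else {
    dplyr::summarise(fin$data, n_reports = dplyr::n(),
                     n_cases = dplyr::n_distinct(.data$case_id),
                     .by = ".group") |>
      dplyr::rename(group = ".group") |>
      dplyr::arrange(.data$group)
  }
  structure(
    list(data = fin$data, groups = groups, forced = fin$forced,
         merges = fin$merges, dropped = dropped,
         threshold_warnings = threshold_warnings,
         k = k, policy = policy, schema = schema, e = e,
         rng_seed = rng_seed),
    class = "ms_anon"
  )
}

#' @export
print.ms_anon <- function(x, ...) {
  cat("MS(k, theta*)-bounding anonymization\n")
  cat("  k =", x$k, " |S| =", nrow(x$policy), "\n")
  cat("  reports released:", nrow(x$data),
      " (dropped for missing QID:", x$dropped, ")\n")
  cat("  QID-groups:", nrow(x$groups),
      " forced placements:", length(x$forced),
      " repair merges:", x$merges, "\n")
  invisible(x)
}
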