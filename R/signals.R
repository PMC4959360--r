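# ADR disproportionality analysis on the 2x2 drug-reaction contingency
# table, and before/after-anonymization signal comparison.
#
#                 suspected ADR   without ADR
#  suspected drug       a              b
#  other drugs          c              d
#
# The counting unit defaults to distinct cases, so follow-up duplicates do
# not inflate counts.

#' Construct a 2x2 ADR contingency table
#'
#' @param a Cases with the suspected drug and the suspected reaction.
#' @param b Cases with the drug, without the reaction.
#' @param c Cases with the reaction, on other drugs.
#' @param d Cases with neither.
#' @return A one-row tibble of class `adr_contingency` with columns
#'   `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  out <- tibble::tibble(a = a, b = b, c = c, d = d, n = a + b + c + d)
  class(out) <- c("adr_contingency", class(out))
  out
}

#' Define an ADR rule
#'
#' A drug-reaction pair, optionally restricted to a demographic stratum via
#' a predicate over one QID attribute (e.g. age > 18, gender = Female).
#'
#' @param drug Drug name (matched against the `qsa` sets).
#' @param reaction Reaction term (matched against the `sa` sets).
#' @param condition Optional [qid_condition()].
#' @return An object of class `adr_rule`.
#' @export
adr_rule <- function(drug, reaction, condition = NULL) {
  if (!is.null(condition)) stopifnot(inherits(condition, "qid_condition"))
  structure(list(drug = drug, reaction = reaction, condition = condition),
            class = "adr_rule")
}

#' Demographic predicate over a QID attribute
#'
#' Supports numeric comparisons (`>`, `>=`, `<`, `<=`) and categorical
#' equality (`==`). On generalized values the matching mode matters: in
#' `"strict"` mode an interval satisfies a numeric predicate only when the
#' whole interval does (so `[20-30]` does not satisfy age > 25), and a
#' generalized label never matches an equality; in `"lenient"` mode overlap
#' suffices. Strict is the default because lenient matching inflates counts.
#'
#' @param attribute QID attribute name.
#' @param op One of `">"`, `">="`, `"<"`, `"<="`, `"=="`.
#' @param value Numeric threshold or categorical label.
#' @return An object of class `qid_condition`.
#' @export
qid_condition <- function(attribute, op, value) {
  op <- match.arg(op, c(">", ">=", "<", "<=", "=="))
  structure(list(attribute = attribute, op = op, value = value),
            class = "qid_condition")
}

format_condition <- function(cond) {
  if (is.null(cond)) return(NA_character_)
  paste(cond$attribute, cond$op, cond$value)
}

# logical vector: does each record satisfy the condition under `mode`?
.match_condition <- function(data, cond, mode) {
  if (is.null(cond)) return(rep(TRUE, nrow(data)))
  x <- data[[cond$attribute]]
  if (is.null(x)) stop("condition attribute not in data: ", cond$attribute)
  if (cond$op == "==") {
    lab <- as.character(x)
    hit <- !is.na(lab) & lab == as.character(cond$value)
    if (mode == "lenient") hit <- hit | (!is.na(lab) & lab == "ANY")
    return(hit)
  }
  iv <- parse_interval(x)
  v <- cond$value
  whole <- switch(cond$op,
    ">" = iv$lo > v, ">=" = iv$lo >= v, "<" = iv$hi < v, "<=" = iv$hi <= v)
  some <- switch(cond$op,
    ">" = iv$hi > v, ">=" = iv$hi >= v, "<" = iv$lo < v, "<=" = iv$lo <= v)
  out <- if (mode == "strict") whole else some
  out & !is.na(out)
}

#' Build the contingency table for an ADR rule
#'
#' Restricts the table to the rule's demographic stratum, then counts
#' distinct cases (default) or raw reports into the 2x2 cells. A case falls
#' in row "suspected drug" when any of its drugs equals the rule's drug, and
#' in column "suspected ADR" when any of its SA terms equals the rule's
#' reaction.
#'
#' @param data A report tibble (raw or released).
#' @param rule An [adr_rule()].
#' @param dedupe Count distinct cases (`TRUE`, default) or raw reports.
#' @param mode Interval matching mode for the demographic predicate,
#'   `"strict"` or `"lenient"` (see [qid_condition()]).
#' @return An `adr_contingency`.
#' @export
build_contingency <- function(data, rule, dedupe = TRUE,
                              mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  keep <- .match_condition(data, rule$condition, mode)
  sub <- data[keep, , drop = FALSE]
  units <- if (dedupe) collapse_cases(sub) else sub
  has_drug <- vapply(units$qsa, function(v) rule$drug %in% v, NA)
  has_reac <- vapply(units$sa, function(v) rule$reaction %in% v, NA)
  contingency_table(
    a = sum(has_drug & has_reac), b = sum(has_drug & !has_reac),
    c = sum(!has_drug & has_reac), d = sum(!has_drug & !has_reac)
  )
}

#' Proportional reporting ratio
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`. Returns `NA` when a denominator is zero
#' (undefined outcome, not an error); 0 when `a = 0` with valid
#' denominators.
#'
#' @param t An `adr_contingency`.
#' @return A non-negative number or `NA`.
#' @export
prr <- function(t) {
  if (t$a + t$b == 0 || t$c == 0) return(NA_real_)
  (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
}

#' Reporting odds ratio
#'
#' `ROR = (a/c) / (b/d) = ad/(bc)`. Returns `NA` when `b`, `c` or `d` is
#' zero; 0 when `a = 0` with valid denominators.
#'
#' @param t An `adr_contingency`.
#' @return A non-negative number or `NA`.
#' @export
ror <- function(t) {
  if (t$b == 0 || t$c == 0 || t$d == 0) return(NA_real_)
  (t$a * t$d) / (t$b * t$c)
}

#' Information component
#'
#' `IC = log2( a * N / ((a+b)(a+c)) )`. Returns `NA` when `a = 0`.
#'
#' @param t An `adr_contingency`.
#' @return A number or `NA`.
#' @export
ic <- function(t) {
  if (t$a == 0) return(NA_real_)
  log2(t$a * t$n / ((t$a + t$b) * (t$a + t$c)))
}

#' Yates-corrected chi-squared statistic of a contingency table
#'
#' The standard 2x2 chi-squared with continuity correction (the convention
#' of the MHRA signal criterion); set `correct = FALSE` for the uncorrected
#' statistic. Returns `NA` when a margin is zero.
#'
#' @param t An `adr_contingency`.
#' @param correct Apply Yates' continuity correction (default `TRUE`).
#' @return A non-negative number or `NA`.
#' @export
chisq_stat <- function(t, correct = TRUE) {
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
  unname(suppressWarnings(stats::chisq.test(m, correct = correct)$statistic))
}

#' Evaluate standard ADR signal criteria
#'
#' Four commonly used criteria: the PRR lower-confidence-bound test
#' (`exp(ln PRR - 1.96 SE) > 1`, with `SE(ln PRR) =
#' sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`), the MHRA triple criterion
#' (`PRR >= 2`, `a >= 3`, Yates chi-squared `>= 4`), the analogous ROR test
#' (`SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`), and an IC test
#' (`IC - 1.96 SE(IC) > 0`) using a normal approximation on the log2 scale
#' — a frequentist stand-in for the Bayesian shrinkage interval, flagged as
#' approximate. A criterion whose measure is undefined evaluates to `FALSE`
#' with a reason.
#'
#' @param t An `adr_contingency`.
#' @param correct Yates correction for the MHRA chi-squared.
#' @return A tibble with columns `criterion`, `signal`, `statistic`,
#'   `note`.
#' @export
signal_flags <- function(t, correct = TRUE) {
  p <- prr(t); r <- ror(t); i <- ic(t); x2 <- chisq_stat(t, correct)
  rows <- list()
  flag <- function(criterion, signal, statistic, note = NA_character_) {
    tibble::tibble(criterion = criterion, signal = signal,
                   statistic = statistic, note = note)
  }
  if (is.na(p) || p <= 0) {
    rows$prr <- flag("PRR-1.96SD>1", FALSE, NA_real_, "PRR undefined or zero")
  } else {
    se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
    lo <- exp(log(p) - 1.96 * se)
    rows$prr <- flag("PRR-1.96SD>1", lo > 1, lo)
  }
  rows$mhra <- flag("MHRA (PRR>=2, a>=3, chi2>=4)",
                    !is.na(p) && !is.na(x2) && p >= 2 && t$a >= 3 && x2 >= 4,
                    x2,
                    if (is.na(p) || is.na(x2)) "component undefined" else NA_character_)
  if (is.na(r) || r <= 0 || t$a == 0) {
    rows$ror <- flag("ROR-1.96SD>1", FALSE, NA_real_, "ROR undefined or zero")
  } else {
    se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
    lo <- exp(log(r) - 1.96 * se)
    rows$ror <- flag("ROR-1.96SD>1", lo > 1, lo)
  }
  if (is.na(i)) {
    rows$ic <- flag("IC-1.96SD>0 (approx.)", FALSE, NA_real_, "IC undefined")
  } else {
    se <- sqrt(1 / t$a + 1 / (t$a + t$b) + 1 / (t$a + t$c) + 1 / t$n) / log(2)
    lo <- i - 1.96 * se
    rows$ic <- flag("IC-1.96SD>0 (approx.)", lo > 0, lo,
                    "normal approximation")
  }
  dplyr::bind_rows(rows)
}

#' Compare ADR signals before and after anonymization
#'
#' For each rule, computes the event count `a`, PRR and ROR on both tables
#' and their differences. With no demographic predicate the counts are
#' identical by construction — anonymization touches only QID values — so
#' any difference can enter only through predicates on generalized
#' intervals.
#'
#' @param original,anonymized Report tibbles sharing drug/reaction
#'   vocabularies.
#' @param rules A list of [adr_rule()]s (a single rule is accepted).
#' @param dedupe,mode Passed to [build_contingency()].
#' @return A tibble of class `srs_signal_comparison`, one row per rule.
#' @export
compare_signals <- function(original, anonymized, rules, dedupe = TRUE,
                            mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (inherits(rules, "adr_rule")) rules <- list(rules)
  rows <- lapply(rules, function(rule) {
    t0 <- build_contingency(original, rule, dedupe, mode)
    t1 <- build_contingency(anonymized, rule, dedupe, mode)
    tibble::tibble(
      drug = rule$drug, reaction = rule$reaction,
      condition = format_condition(rule$condition),
      a_original = t0$a, a_anonymized = t1$a, delta_a = t1$a - t0$a,
      prr_original = prr(t0), prr_anonymized = prr(t1),
      delta_prr = prr(t1) - prr(t0),
      ror_original = ror(t0), ror_anonymized = ror(t1),
      delta_ror = ror(t1) - ror(t0)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("srs_signal_comparison", class(out))
  out
}
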