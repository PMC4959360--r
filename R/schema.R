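# Attribute schema: assigns each column of a report table one of the roles
# ID / QID / SA / QSA / NSA, and for QID attributes records whether it is
# numeric (with global domain bounds, used as the normalizing range in the
# information-loss metric) or categorical (with a generalization hierarchy).

#' Define the attribute schema of a report table
#'
#' Every report attribute is assigned a role: `QID` (quasi-identifier, the
#' columns that get generalized), `SA` (multi-valued sensitive attribute,
#' e.g. reaction and indication preferred terms), `QSA` (quasi-sensitive,
#' e.g. drug names, sensitive only through external linkage) or `NSA`
#' (carried through untouched). Report and case identifiers are handled
#' separately by [read_reports()].
#'
#' Numeric QID attributes need global domain bounds `c(min, max)` — the
#' denominators of the normalized range term in the information-loss metric.
#' Categorical QID attributes may carry a [hierarchy()]; one is required
#' for generalization and information loss, but not for compliance checking.
#'
#' @param qid_numeric Named list; each element is `c(min, max)` for a
#'   numeric QID attribute (units of that attribute, e.g. kg or years).
#' @param qid_categorical Named list; each element is a `gen_hierarchy`
#'   or `NULL` for a categorical QID attribute.
#' @param sa,qsa,nsa Character vectors of column names for the sensitive,
#'   quasi-sensitive and non-sensitive attributes.
#' @return A tibble of class `srs_schema` with columns `name`, `role`,
#'   `kind`, `min`, `max`, `hierarchy`.
#' @examples
#' srs_schema(
#'   qid_numeric = list(Age = c(0, 120), Weight = c(0, 250)),
#'   qid_categorical = list(Gender = gender_hierarchy()),
#'   sa = "Reactions", qsa = "Drugs"
#' )
#' @export
srs_schema <- function(qid_numeric = list(), qid_categorical = list(),
                       sa = character(), qsa = character(),
                       nsa = character()) {
  rows <- list()
  for (nm in names(qid_numeric)) {
    dom <- qid_numeric[[nm]]
    stopifnot(is.numeric(dom), length(dom) == 2L)
    if (!(dom[2] > dom[1])) {
      stop("numeric QID attribute '", nm, "' needs domain_max > domain_min")
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = nm, role = "QID", kind = "numeric",
      min = dom[1], max = dom[2], hierarchy = list(NULL))
  }
  for (nm in names(qid_categorical)) {
    h <- qid_categorical[[nm]]
    if (!is.null(h) && !inherits(h, "gen_hierarchy")) {
      stop("qid_categorical[['", nm, "']] must be a gen_hierarchy or NULL")
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = nm, role = "QID", kind = "categorical",
      min = NA_real_, max = NA_real_, hierarchy = list(h))
  }
  for (nm in sa) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = nm, role = "SA", kind = NA_character_,
      min = NA_real_, max = NA_real_, hierarchy = list(NULL))
  }
  for (nm in qsa) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = nm, role = "QSA", kind = NA_character_,
      min = NA_real_, max = NA_real_, hierarchy = list(NULL))
  }
  for (nm in nsa) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      name = nm, role = "NSA", kind = NA_character_,
      min = NA_real_, max = NA_real_, hierarchy = list(NULL))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("schema must declare at least one attribute")
  if (anyDuplicated(out$name)) {
    stop("duplicate attribute in schema: ", out$name[duplicated(out$name)][1])
  }
  class(out) <- c("srs_schema", class(out))
  out
}

qid_names <- function(schema) schema$name[schema$role == "QID"]
sa_names <- function(schema) schema$name[schema$role == "SA"]
qsa_names <- function(schema) schema$name[schema$role == "QSA"]

schema_row <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) stop("attribute not in schema: ", name)
  schema[i, ]
}

schema_hierarchy <- function(schema, name) {
  h <- schema_row(schema, name)$hierarchy[[1]]
  if (is.null(h)) {
    stop("categorical QID attribute '", name,
         "' has no generalization hierarchy in the schema")
  }
  h
}

# ---- numeric interval cells -------------------------------------------------
# Generalized numeric QID values are serialized as "[lo-hi]" (closed on both
# ends); an en dash on input is accepted, a hyphen is emitted. A degenerate
# interval is written as the plain number.

#' Parse numeric QID cells into interval bounds
#'
#' Report tables carry numeric quasi-identifiers either as plain numbers or,
#' once generalized, as closed intervals `"[lo-hi]"` (an en dash is also
#' accepted). This helper returns both bounds for each cell; a plain number
#' yields a degenerate interval.
#'
#' @param x Character or numeric vector of cells.
#' @return A tibble with numeric columns `lo` and `hi` (`NA` for missing
#'   cells).
#' @export
parse_interval <- function(x) {
  if (is.numeric(x)) return(tibble::tibble(lo = as.numeric(x), hi = as.numeric(x)))
  x <- as.character(x)
  x <- stringr::str_replace_all(x, "–", "-")
  lo <- hi <- rep(NA_real_, length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  m <- stringr::str_match(trimws(x), "^\\[\\s*(-?[0-9.]+)\\s*-\\s*(-?[0-9.]+)\\s*\\]$")
  is_int <- !is.na(m[, 1])
  lo[is_int] <- as.numeric(m[is_int, 2])
  hi[is_int] <- as.numeric(m[is_int, 3])
  plain <- !blank & !is_int
  if (any(plain)) {
    v <- suppressWarnings(as.numeric(x[plain]))
    if (anyNA(v)) {
      stop("cannot parse numeric QID cell(s): ",
           paste(utils::head(x[plain][is.na(v)], 3), collapse = ", "))
    }
    lo[plain] <- v; hi[plain] <- v
  }
  tibble::tibble(lo = lo, hi = hi)
}

format_interval <- function(lo, hi) {
  out <- ifelse(lo == hi, .num_chr(lo), paste0("[", .num_chr(lo), "-", .num_chr(hi), "]"))
  out[is.na(lo) | is.na(hi)] <- NA_character_
  out
}

.num_chr <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}
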