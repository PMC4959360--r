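# Reading and writing FAERS-style report tables.
#
# In-memory representation: a tibble with one row per report,
#   isr      report identifier (unique)
#   case_id  individual/event identifier (shared by follow-up reports)
#   <QID>    one column per quasi-identifier; numeric QIDs hold plain numbers
#            or, once generalized, "[lo-hi]" interval strings
#   sa       list-column: set of sensitive terms (reaction/indication PTs)
#   qsa      list-column: set of quasi-sensitive terms (drug names)
#   <NSA>    remaining columns, carried through untouched
#   .group   optional QID-group assignment (added by the anonymizer)

#' Read a report table
#'
#' Reads a delimited report file into the package's tidy representation.
#' All columns declared in the schema must be present; multi-valued SA/QSA
#' cells are split on `sep` and merged (set union) into the `sa` and `qsa`
#' list-columns. Rows retain file order.
#'
#' @param path Path to the file.
#' @param schema An [srs_schema()].
#' @param dialect `"csv"` (RFC-4180) or `"faers-dollar"` (the `$`-delimited
#'   FAERS ASCII layout).
#' @param sep Intra-cell separator for multi-valued SA/QSA cells.
#' @param isr_col,case_col Names of the report-ID and case-ID columns in the
#'   file.
#' @param na Strings treated as missing.
#' @return A tibble of reports (see the package overview for the layout).
#' @export
read_reports <- function(path, schema, dialect = c("csv", "faers-dollar"),
                         sep = ";", isr_col = "ISR", case_col = "CaseID",
                         na = c("", "NA")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "csv") "," else "$"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE,
    trim_ws = TRUE)
  for (col in c(isr_col, case_col, schema$name)) {
    if (!col %in% names(raw)) {
      stop("missing mandatory column in ", path, ": ", col)
    }
  }
  raw[] <- lapply(raw, function(x) replace(x, x %in% na, NA_character_))
  if (anyDuplicated(raw[[isr_col]])) {
    stop("duplicate ISR in ", path, ": ",
         raw[[isr_col]][duplicated(raw[[isr_col]])][1])
  }
  if (any(is.na(raw[[case_col]]))) {
    stop("missing case identifier (", case_col, ") in ", path)
  }
  out <- tibble::tibble(isr = raw[[isr_col]], case_id = raw[[case_col]])
  for (nm in qid_names(schema)) {
    x <- raw[[nm]]
    if (schema_row(schema, nm)$kind == "numeric") {
      iv <- parse_interval(x)
      if (any(iv$lo != iv$hi, na.rm = TRUE)) {
        x <- format_interval(iv$lo, iv$hi)      # normalized interval strings
      } else {
        x <- iv$lo
      }
    }
    out[[nm]] <- x
  }
  out$sa <- .merge_multivalued(raw, sa_names(schema), sep)
  out$qsa <- .merge_multivalued(raw, qsa_names(schema), sep)
  for (nm in schema$name[schema$role == "NSA"]) out[[nm]] <- raw[[nm]]
  if (".group" %in% names(raw)) out$.group <- raw$.group
  out
}

.merge_multivalued <- function(raw, cols, sep) {
  if (length(cols) == 0L) return(rep(list(character(0)), nrow(raw)))
  lapply(seq_len(nrow(raw)), function(i) {
    vals <- unlist(lapply(cols, function(cl) {
      cell <- raw[[cl]][i]
      if (is.na(cell)) return(character(0))
      trimws(strsplit(cell, sep, fixed = TRUE)[[1]])
    }))
    sort(unique(vals[nzchar(vals)]))
  })
}

#' Drop reports with missing quasi-identifier values
#'
#' Removes every report for which any QID attribute is missing; surviving
#' reports are untouched and keep their order. The number of dropped reports
#' is reported via `message()`.
#'
#' @param data A report tibble.
#' @param schema An [srs_schema()].
#' @return The filtered tibble.
#' @export
drop_missing_qid <- function(data, schema) {
  qids <- qid_names(schema)
  if (length(qids) == 0L || nrow(data) == 0L) return(data)
  miss <- Reduce(`|`, lapply(qids, function(nm) {
    x <- data[[nm]]
    is.na(x) | (is.character(x) & !nzchar(trimws(ifelse(is.na(x), "", x))))
  }))
  if (sum(miss) > 0L) {
    message("drop_missing_qid: discarded ", sum(miss), " of ", nrow(data),
            " reports with missing QID values")
  }
  data[!miss, , drop = FALSE]
}

#' Read an external drug-disease knowledge table
#'
#' A two-column delimited file (drug, disease), one pair per row, e.g.
#' scraped from a drug reference site. Diseases are aggregated per drug into
#' sets; duplicate pairs collapse.
#'
#' @param path Path to the file. An optional `drug,disease`-style header row
#'   is skipped.
#' @return A tibble of class `ext_knowledge` with columns `drug` and
#'   `diseases` (list-column of character sets).
#' @export
read_external_table <- function(path) {
  raw <- readr::read_csv(path, col_names = FALSE, col_types = "cc",
                         progress = FALSE, trim_ws = TRUE)
  if (nrow(raw) > 0L && tolower(raw[[1]][1]) %in% c("drug", "drugs")) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (any(is.na(raw[[2]]) | !nzchar(raw[[2]]))) {
    stop("empty disease field for drug: ",
         raw[[1]][is.na(raw[[2]]) | !nzchar(raw[[2]])][1])
  }
  external_table(raw[[1]], raw[[2]])
}

#' Construct an external knowledge table from drug-disease pairs
#'
#' @param drug,disease Character vectors of equal length; one treated
#'   disease per entry.
#' @return A tibble of class `ext_knowledge` with columns `drug` and
#'   `diseases` (list-column of character sets).
#' @export
external_table <- function(drug, disease) {
  stopifnot(length(drug) == length(disease))
  out <- tibble::tibble(drug = drug, disease = disease) |>
    dplyr::distinct() |>
    dplyr::summarise(diseases = list(sort(unique(.data$disease))),
                     .by = "drug")
  class(out) <- c("ext_knowledge", class(out))
  out
}

# union of disease sets over a drug vector; unknown drugs contribute nothing
ext_disease_union <- function(e, drugs, warn_missing = FALSE) {
  if (is.null(e) || length(drugs) == 0L) return(character(0))
  i <- match(drugs, e$drug)
  if (warn_missing && anyNA(i)) {
    warning("drug(s) absent from external table: ",
            paste(drugs[is.na(i)], collapse = ", "), call. = FALSE)
  }
  sort(unique(unlist(e$diseases[i[!is.na(i)]])))
}

#' Write a report table
#'
#' Serializes a report tibble back to a delimited file: columns `ISR`,
#' `CaseID`, the QID attributes (numeric intervals as `"[lo-hi]"`), `SA` and
#' `QSA` (multi-valued cells joined with `"; "`), any NSA columns, and
#' `.group` when present. Re-reading the file with the matching schema
#' reproduces the records.
#'
#' @param data A report tibble.
#' @param path Output path.
#' @param schema The [srs_schema()] the tibble conforms to.
#' @param dialect `"csv"` or `"faers-dollar"`.
#' @param sep Intra-cell separator for multi-valued cells.
#' @return `path`, invisibly.
#' @export
write_reports <- function(data, path, schema, dialect = c("csv", "faers-dollar"),
                          sep = ";") {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "csv") "," else "$"
  out <- tibble::tibble(ISR = data$isr, CaseID = data$case_id)
  for (nm in qid_names(schema)) {
    x <- data[[nm]]
    if (schema_row(schema, nm)$kind == "numeric") {
      iv <- parse_interval(x)
      x <- format_interval(iv$lo, iv$hi)
    }
    out[[nm]] <- x
  }
  join <- function(v) paste(v, collapse = paste0(sep, " "))
  out$SA <- vapply(data$sa, join, "")
  out$QSA <- vapply(data$qsa, join, "")
  for (nm in schema$name[schema$role == "NSA"]) out[[nm]] <- data[[nm]]
  if (".group" %in% names(data)) out$.group <- data$.group
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# schema describing the layout emitted by write_reports, derived from the
# original schema (SA/QSA collapsed into single columns)
written_schema <- function(schema) {
  qn <- schema[schema$role == "QID", ]
  num <- qn[qn$kind == "numeric", ]
  cat <- qn[qn$kind == "categorical", ]
  srs_schema(
    qid_numeric = stats::setNames(
      lapply(seq_len(nrow(num)), function(i) c(num$min[i], num$max[i])),
      num$name),
    qid_categorical = stats::setNames(cat$hierarchy, cat$name),
    sa = "SA", qsa = "QSA", nsa = schema$name[schema$role == "NSA"]
  )
}
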