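# YAML policy configuration for scripted/CLI use.

#' Read a sensitive-value policy from a YAML file
#'
#' The file names a `strategy` — `uniform`, `levelwise` or `frequency` —
#' with its parameters, and may add explicit per-value `overrides`:
#'
#' ```yaml
#' strategy: levelwise
#' theta_high: 0.2
#' theta_default: 0.4
#' high: [PT_0199, PT_0200]
#' nonsensitive: [PT_0001]
#' overrides:
#'   PT_0042: 0.3
#' ```
#'
#' The `uniform` strategy needs `theta` (and optionally `values`); the
#' `levelwise` and `frequency` strategies derive the value set from `data`.
#'
#' @param path Path to the YAML file.
#' @param data Report tibble; required unless a `uniform` policy lists its
#'   `values` explicitly.
#' @return A `sensitive_policy`.
#' @export
read_policy <- function(path, data = NULL) {
  cfg <- yaml::read_yaml(path)
  strategy <- match.arg(cfg$strategy, c("uniform", "levelwise", "frequency"))
  values_from_data <- function() {
    if (is.null(data)) stop("policy strategy '", strategy,
                            "' needs 'data' to derive the value set")
    sensitive_frequencies(data)$value
  }
  policy <- switch(strategy,
    uniform = build_uniform_policy(
      s_set = if (!is.null(cfg$values)) unlist(cfg$values) else values_from_data(),
      theta = cfg$theta %||% 0.4),
    levelwise = build_levelwise_policy(
      all_values = values_from_data(),
      high = unlist(cfg$high) %||% character(),
      nonsensitive = unlist(cfg$nonsensitive) %||% character(),
      theta_high = cfg$theta_high %||% 0.2,
      theta_default = cfg$theta_default %||% 0.4),
    frequency = build_frequency_policy(
      data = if (is.null(data)) stop("frequency policy needs 'data'") else data,
      top_frac = cfg$top_frac %||% 0.1,
      bottom_frac = cfg$bottom_frac %||% 0.1,
      theta_top = cfg$theta_top %||% 1,
      theta_mid = cfg$theta_mid %||% 0.4,
      theta_bottom = cfg$theta_bottom %||% 0.2)
  )
  for (nm in names(cfg$overrides)) {
    th <- cfg$overrides[[nm]]
    .check_theta(th)
    i <- match(nm, policy$value)
    if (is.na(i)) {
      policy <- dplyr::bind_rows(policy, tibble::tibble(value = nm, theta = th))
      class(policy) <- c("sensitive_policy", setdiff(class(policy),
                                                     "sensitive_policy"))
    } else {
      policy$theta[i] <- th
    }
  }
  policy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an attribute schema from a YAML file
#'
#' The file lists one entry per attribute:
#'
#' ```yaml
#' attributes:
#'   - {name: Age, role: QID, kind: numeric, min: 0, max: 100}
#'   - {name: Gender, role: QID, kind: categorical, hierarchy: gender.txt}
#'   - {name: PT, role: SA}
#'   - {name: Drugs, role: QSA}
#' ```
#'
#' Hierarchy paths are resolved relative to `hierarchy_dir`; the names
#' `age` and `gender` (no path) refer to the bundled trees.
#'
#' @param path Path to the YAML file.
#' @param hierarchy_dir Directory holding hierarchy files referenced by the
#'   schema.
#' @return An [srs_schema()].
#' @export
read_schema <- function(path, hierarchy_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$attributes)) stop("schema file needs an 'attributes' list")
  qn <- list(); qc <- list(); sa <- character(); qsa <- character()
  nsa <- character()
  for (at in cfg$attributes) {
    role <- toupper(at$role %||% "NSA")
    if (role == "QID" && identical(at$kind, "numeric")) {
      qn[[at$name]] <- c(at$min, at$max)
    } else if (role == "QID") {
      qc[[at$name]] <- .resolve_hierarchy(at$hierarchy, at$name, hierarchy_dir)
    } else if (role == "SA") {
      sa <- c(sa, at$name)
    } else if (role == "QSA") {
      qsa <- c(qsa, at$name)
    } else if (role == "NSA") {
      nsa <- c(nsa, at$name)
    } else if (role != "ID") {
      stop("unknown role '", at$role, "' for attribute ", at$name)
    }
  }
  srs_schema(qid_numeric = qn, qid_categorical = qc, sa = sa, qsa = qsa,
             nsa = nsa)
}

.resolve_hierarchy <- function(ref, attribute, hierarchy_dir) {
  if (is.null(ref)) return(NULL)
  if (ref %in% c("age", "gender")) {
    return(if (ref == "age") mesh_age_hierarchy() else gender_hierarchy())
  }
  p <- if (!is.null(hierarchy_dir)) file.path(hierarchy_dir, ref) else ref
  if (!file.exists(p)) stop("hierarchy file not found for ", attribute, ": ", p)
  parse_hierarchy(p, attribute = attribute)
}
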