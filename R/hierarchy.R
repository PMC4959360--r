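# Value generalization hierarchies for categorical quasi-identifiers.
#
# A hierarchy is a rooted tree whose leaves are raw data values and whose
# internal nodes are generalized values; the root is the fully suppressed
# value (conventionally "ANY"). Heights are measured bottom-up: a node's
# height is the tree height minus its depth, so leaves sit at height 0 and
# the root of a height-H tree at height H. This convention is what makes a
# QID-homogeneous group contribute 0 to information loss.

#' Construct a value generalization hierarchy
#'
#' Builds a rooted tree over categorical attribute values from parallel
#' parent/child label vectors. Leaves are raw data values; internal nodes are
#' generalized values; the single root (typically `"ANY"`) represents full
#' suppression.
#'
#' @param parent,child Character vectors of equal length; each pair is one
#'   edge of the tree.
#' @param attribute Optional attribute name the hierarchy generalizes.
#' @return An object of class `gen_hierarchy`.
#' @examples
#' h <- hierarchy(parent = c("ANY", "ANY"), child = c("Male", "Female"),
#'                attribute = "Gender")
#' hierarchy_height(h)
#' lca(h, c("Male", "Female"))
#' @export
hierarchy <- function(parent, child, attribute = NULL) {
  stopifnot(is.character(parent), is.character(child),
            length(parent) == length(child))
  if (length(parent) == 0L) {
    stop("hierarchy needs at least one edge (a single-leaf tree has height 0)")
  }
  if (anyDuplicated(child)) {
    stop("duplicate label in hierarchy: ", child[duplicated(child)][1])
  }
  roots <- setdiff(parent, child)
  if (length(unique(roots)) != 1L) {
    stop("hierarchy must have exactly one root; found: ",
         paste(unique(roots), collapse = ", "))
  }
  labels <- c(unique(roots), child)
  if (anyDuplicated(labels)) {
    stop("duplicate label in hierarchy: ", labels[duplicated(labels)][1])
  }
  parent_id <- integer(length(labels))
  parent_id[match(child, labels)] <- match(parent, labels)
  # depth by walking up; also detects cycles (cannot happen once the
  # single-root/unique-child checks pass, but guard against malformed input)
  n <- length(labels)
  depth <- rep.int(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (parent_id[j] != 0L) {
      j <- parent_id[j]; d <- d + 1L
      if (d > n) stop("cycle detected in hierarchy near label: ", labels[i])
    }
    depth[i] <- d
  }
  is_leaf <- !(seq_len(n) %in% parent_id)
  height <- max(depth[is_leaf])
  if (height < 1L) stop("hierarchy height must be at least 1")
  h <- structure(
    list(attribute = attribute, labels = labels, parent = parent_id,
         depth = depth, is_leaf = is_leaf, height = height,
         node_height = height - depth),
    class = "gen_hierarchy"
  )
  h$lca_id <- .pairwise_lca(h)
  h$lca_h <- matrix(h$node_height[h$lca_id], n, n)
  h
}

# root-to-node chain of node ids
.anc_chain <- function(h, id) {
  chain <- id
  while (h$parent[id] != 0L) {
    id <- h$parent[id]
    chain <- c(id, chain)
  }
  chain
}

.pairwise_lca <- function(h) {
  n <- length(h$labels)
  chains <- lapply(seq_len(n), function(i) .anc_chain(h, i))
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      a <- chains[[i]]; b <- chains[[j]]
      l <- min(length(a), length(b))
      common <- which(a[seq_len(l)] == b[seq_len(l)])
      id <- a[max(common)]
      m[i, j] <- id; m[j, i] <- id
    }
  }
  m
}

.node_id <- function(h, values) {
  id <- match(values, h$labels)
  if (anyNA(id)) {
    stop("label(s) not in hierarchy", if (!is.null(h$attribute))
      paste0(" for ", h$attribute), ": ",
      paste(unique(values[is.na(id)]), collapse = ", "))
  }
  id
}

#' Parse a value generalization hierarchy from a file
#'
#' Accepts two plain-text layouts: an indented outline (one label per line,
#' two spaces of indentation per level, the root unindented) or a two-column
#' `parent,child` CSV edge list (an optional `parent,child` header row is
#' skipped).
#'
#' @param path Path to the hierarchy file.
#' @param attribute Optional attribute name to record on the hierarchy.
#' @return A `gen_hierarchy`.
#' @export
parse_hierarchy <- function(path, attribute = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty hierarchy file: ", path)
  if (all(grepl(",", lines))) {
    .parse_hierarchy_edges(lines, attribute)
  } else {
    .parse_hierarchy_indent(lines, attribute)
  }
}

.parse_hierarchy_edges <- function(lines, attribute) {
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("edge-list line must be 'parent,child': ", lines[bad][1])
  parent <- trimws(vapply(parts, `[[`, "", 1L))
  child <- trimws(vapply(parts, `[[`, "", 2L))
  if (tolower(parent[1]) == "parent" && tolower(child[1]) == "child") {
    parent <- parent[-1]; child <- child[-1]
  }
  hierarchy(parent, child, attribute)
}

.parse_hierarchy_indent <- function(lines, attribute) {
  indent <- nchar(lines) - nchar(sub("^ *", "", lines))
  if (any(indent %% 2L != 0L)) {
    stop("indentation must be a multiple of two spaces: ",
         trimws(lines[indent %% 2L != 0L][1]))
  }
  level <- indent %/% 2L
  label <- trimws(lines)
  if (sum(level == 0L) != 1L || level[1] != 0L) {
    stop("hierarchy must have exactly one root (one unindented line, first)")
  }
  parent <- character(0); child <- character(0)
  stack <- character(max(level) + 1L)
  stack[1] <- label[1]
  for (i in seq_along(label)[-1]) {
    if (level[i] < 1L || level[i] > max(which(nzchar(stack)))) {
      stop("bad indentation jump at: ", label[i])
    }
    parent <- c(parent, stack[level[i]])
    child <- c(child, label[i])
    stack[level[i] + 1L] <- label[i]
    if (level[i] + 2L <= length(stack)) {
      stack[(level[i] + 2L):length(stack)] <- ""
    }
  }
  hierarchy(parent, child, attribute)
}

#' Lowest common ancestor of a set of values
#'
#' Returns the deepest node that is an ancestor-or-self of every given value.
#' Values may be leaves or internal (already generalized) labels.
#'
#' @param h A `gen_hierarchy`.
#' @param values Character vector of labels occurring in the tree.
#' @return The label of the lowest common ancestor.
#' @export
lca <- function(h, values) {
  stopifnot(inherits(h, "gen_hierarchy"), length(values) >= 1L)
  id <- .node_id(h, unique(values))
  h$labels[Reduce(function(a, b) h$lca_id[a, b], id)]
}

#' Height of the lowest common ancestor
#'
#' The bottom-up height of `lca(h, values)`: 0 for a leaf (so 0 for any set
#' of identical leaf values), up to `hierarchy_height(h)` for the root.
#'
#' @inheritParams lca
#' @return A non-negative integer.
#' @export
lca_height <- function(h, values) {
  stopifnot(inherits(h, "gen_hierarchy"), length(values) >= 1L)
  id <- .node_id(h, unique(values))
  h$node_height[Reduce(function(a, b) h$lca_id[a, b], id)]
}

#' Height of a generalization hierarchy
#'
#' @param h A `gen_hierarchy`.
#' @return The tree height (root height above the leaf level), an integer
#'   of at least 1.
#' @export
hierarchy_height <- function(h) {
  stopifnot(inherits(h, "gen_hierarchy"))
  h$height
}

#' @export
print.gen_hierarchy <- function(x, ...) {
  cat("<gen_hierarchy", if (!is.null(x$attribute)) paste0(" ", x$attribute),
      ">: ", sum(x$is_leaf), " leaves, height ", x$height,
      ", root '", x$labels[x$parent == 0L], "'\n", sep = "")
  invisible(x)
}

#' Bundled age-group generalization hierarchy
#'
#' A MeSH-inspired age-group tree of height 2: the root `ANY` covers `Minor`
#' (Infant, Child, Adolescent) and `Adult Group` (Young Adult, Adult,
#' Middle Aged, Aged). Intended for categorical age attributes coded as
#' MeSH-style age groups; users with other codings should supply their own
#' tree via [parse_hierarchy()].
#'
#' @return A `gen_hierarchy` for attribute `"Age"`.
#' @export
mesh_age_hierarchy <- function() {
  parse_hierarchy(
    system.file("extdata", "hierarchies", "age.txt", package = "srsanon"),
    attribute = "Age"
  )
}

#' Bundled gender generalization hierarchy
#'
#' A height-1 tree: `ANY` over `Male` and `Female`.
#'
#' @return A `gen_hierarchy` for attribute `"Gender"`.
#' @export
gender_hierarchy <- function() {
  parse_hierarchy(
    system.file("extdata", "hierarchies", "gender.txt", package = "srsanon"),
    attribute = "Gender"
  )
}
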