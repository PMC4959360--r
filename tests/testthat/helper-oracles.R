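# Independent brute-force oracles used by property tests. These deliberately
# avoid the package's precomputed LCA tables and vectorized engine.

# random rooted tree as a gen_hierarchy; node i > 1 hangs under a random
# earlier node, so trees are ragged
random_tree <- function(n_nodes, labels = sprintf("L%02d", seq_len(n_nodes))) {
  parent_idx <- c(NA, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 1L))
  hierarchy(parent = labels[parent_idx[-1]], child = labels[-1])
}

# ancestor-or-self label set of a node, by walking raw parent pointers
bf_ancestors <- function(h, label) {
  i <- match(label, h$labels)
  out <- i
  while (h$parent[i] != 0L) {
    i <- h$parent[i]
    out <- c(out, i)
  }
  h$labels[out]
}

# brute-force LCA: deepest label ancestral to every value
bf_lca <- function(h, values) {
  common <- Reduce(intersect, lapply(values, function(v) bf_ancestors(h, v)))
  common[which.max(h$depth[match(common, h$labels)])]
}

bf_lca_height <- function(h, values) {
  h$height - h$depth[match(bf_lca(h, values), h$labels)]
}

# all set partitions of 1..n (n small)
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# does a partition of the super records into MS(k, theta*)-compliant groups
# exist? Direct-confidence check (no external table), distinct case ids.
bf_feasible <- function(sa_sets, k, policy) {
  n <- length(sa_sets)
  for (p in set_partitions(n)) {
    ok <- all(vapply(p, function(block) {
      if (length(block) < k) return(FALSE)
      confs <- vapply(policy$value, function(s) {
        mean(vapply(sa_sets[block], function(v) s %in% v, NA))
      }, numeric(1))
      all(confs <= policy$theta + 1e-9)
    }, NA))
    if (ok) return(TRUE)
  }
  FALSE
}

# small raw (ungeneralized) report table in Example-1 style: numeric ages,
# gender/country labels, drugs as QSA
raw_example1_style <- function() {
  tibble::tibble(
    isr = sprintf("%03d", 1:6),
    case_id = c("001", "001", "002", "002", "003", "004"),
    Age = c(25, 25, 28, 28, 33, 38),
    Gender = c(rep("M", 4), rep("F", 2)),
    Country = c(rep("USA", 4), rep("UK", 2)),
    sa = rep(list(character(0)), 6),
    qsa = list("Paracetamol", "Paracetamol",
               c("Antacid", "Intron A"), c("Antacid", "Intron A"),
               "Paracetamol", "Antacid")
  )
}
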