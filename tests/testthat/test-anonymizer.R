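simple_schema <- function() {
  srs_schema(
    qid_numeric = list(Age = c(0, 100)),
    qid_categorical = list(Gender = gender_hierarchy()),
    sa = "SA", qsa = "QSA"
  )
}

random_supers <- function(n, n_sym = 3, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    isr = sprintf("i%02d", seq_len(n)),
    case_id = sprintf("c%02d", seq_len(n)),
    member_isrs = as.list(sprintf("i%02d", seq_len(n))),
    Age = as.character(sample(20:80, n, replace = TRUE)),
    Gender = sample(c("Male", "Female"), n, replace = TRUE),
    sa = lapply(seq_len(n), function(i)
      sort(sample(paste0("S", seq_len(n_sym)), sample(1:2, 1)))),
    qsa = rep(list(character(0)), n)
  )
}

test_that("follow-up reports merge into one super record per case", {
  fx <- fixture_example1()
  sup <- combine_case_records(fx$data, fx$schema)
  expect_equal(nrow(sup), 4)
  expect_equal(sup$member_isrs[[1]], c("001", "002"))
  expect_equal(sup$Age[1], "[20-30]")      # identical members: QID unchanged
  expect_equal(sup$qsa[[2]], c("Antacid", "Intron A"))
  # differing ages widen to the covering interval
  d <- tibble::tibble(
    isr = c("a", "b"), case_id = c("x", "x"), Age = c(25, 27),
    Gender = c("Male", "Male"), sa = list("s1", "s2"),
    qsa = list(character(0), character(0)))
  sup2 <- combine_case_records(d, simple_schema())
  expect_equal(sup2$Age, "[25-27]")
  expect_equal(sup2$sa[[1]], c("s1", "s2"))
  # differing categorical values rise to the LCA
  d$Gender <- c("Male", "Female")
  expect_equal(combine_case_records(d, simple_schema())$Gender, "ANY")
})

test_that("information loss reproduces the worked example and its invariants", {
  fx <- fixture_example2()
  g <- fx$group; cand <- fx$candidates; sc <- fx$schema
  expect_equal(information_loss(g, sc), 1)
  expect_equal(information_loss(dplyr::bind_rows(g, cand[1, ]), sc), 6.25)
  expect_equal(information_loss(dplyr::bind_rows(g, cand[2, ]), sc), 9.25)
  # a singleton with point values loses nothing
  expect_equal(information_loss(cand[1, ], sc), 0)
  expect_equal(delta_il(g, cand[1, ], sc), 5.25)
  expect_equal(delta_il(g, cand[2, ], sc), 8.25)
  # a record matching the group cover costs exactly the replication share
  clone <- dplyr::mutate(g[4, ], case_id = "r9", isr = "r9")
  expect_equal(delta_il(g, clone, sc), information_loss(g, sc) / nrow(g))
  expect_error(
    information_loss(dplyr::mutate(g, Weight = "[50-170]"), sc),
    "outside declared domain")
})

test_that("breach capacity eta follows floor(max(k, n) * theta)", {
  expect_equal(eta(5, 5, 0.6), 3)
  expect_equal(eta(10, 5, 0.4), 4)
  expect_equal(eta(3, 5, 1), 5)
  expect_equal(eta(10, 5, 1), 10)
  expect_equal(eta(fixture_example2()$group, 5, 0.6), 3)  # 4 cases, k wins
})

test_that("privacy risk reproduces the worked example and its bounds", {
  fx <- fixture_example2()
  g <- fx$group; cand <- fx$candidates
  expect_equal(privacy_risk(g, cand[1, ], fx$k, fx$policy), 1.5)
  expect_equal(privacy_risk(g, cand[2, ], fx$k, fx$policy), 3.5)
  expect_equal(privacy_risk(g, cand[3, ], fx$k, fx$policy), Inf)
  # all-new sensitive values cost exactly the unit increment
  fresh <- dplyr::mutate(cand[1, ], sa = list("I9"),
                         case_id = "r9", isr = "r9")
  pol9 <- build_uniform_policy(paste0("I", c(1:4, 9)), 0.6)
  expect_equal(privacy_risk(g, fresh, fx$k, pol9), 1)
})

test_that("the combined metric picks r5 in the worked example", {
  fx <- fixture_example2()
  g <- fx$group; cand <- fx$candidates
  expect_equal(delta_il_prime(g, cand[1, ], fx$k, fx$policy, fx$schema),
               5.25 * 1.5)
  expect_equal(delta_il_prime(g, cand[3, ], fx$k, fx$policy, fx$schema), Inf)
  best <- select_best_record(g, cand, fx$k, fx$policy, fx$schema)
  expect_equal(best$case_id, "r5")
  expect_equal(select_best_record(g, cand[2, ], fx$k, fx$policy,
                                  fx$schema)$case_id, "r6")
  # every candidate breaching: the distinguished none-outcome
  tight <- build_uniform_policy(paste0("I", 1:4), 0.25)
  expect_null(select_best_record(g, cand, fx$k, tight, fx$schema))
})

test_that("seed selection is reproducible and maximizes QID dissimilarity", {
  sc <- simple_schema()
  cand <- tibble::tibble(
    isr = c("a", "b"), case_id = c("a", "b"), Age = c("26", "80"),
    Gender = "Male", sa = list("s", "s"), qsa = list(character(0), character(0)))
  prev <- tibble::tibble(isr = "p", case_id = "p", Age = "25", Gender = "Male",
                         sa = list("s"), qsa = list(character(0)))
  expect_equal(select_seed_record(prev, cand, sc)$case_id, "b")
  expect_equal(select_seed_record(prev, cand[1, ], sc)$case_id, "a")
  set.seed(0); first1 <- select_seed_record(NULL, cand, sc)
  set.seed(0); first2 <- select_seed_record(NULL, cand, sc)
  expect_identical(first1, first2)
})

test_that("greedy clustering forms compliant groups and leaves honest residuals", {
  sc <- simple_schema()
  # 10 distinct cases, all-distinct symptoms, theta = 1: two groups of five
  sup <- random_supers(10, n_sym = 10, seed = 3)
  sup$sa <- as.list(paste0("S", 1:10))
  pol1 <- build_uniform_policy(paste0("S", 1:10), 1)
  g <- build_groups(sup, k = 5, pol1, sc, rng_seed = 0)
  expect_equal(sort(as.integer(table(g$.group))), c(5L, 5L))
  expect_equal(sum(is.na(g$.group)), 0)
  # fewer than k records: nothing can form
  g2 <- build_groups(sup[1:4, ], k = 5, pol1, sc, rng_seed = 0)
  expect_true(all(is.na(g2$.group)))
  expect_error(finalize_groups(g2, sup[1:4, ], 5, pol1, sc),
               "no compliant groups")
  # 9 of 10 records share s with theta_s = 0.5: capacity 2 per group of 5,
  # so at most 4 carriers can ever be grouped
  sup3 <- random_supers(10, seed = 4)
  sup3$sa <- c(rep(list("s"), 9), list("t"))
  pol3 <- build_uniform_policy(c("s", "t"), 0.5)
  g3 <- build_groups(sup3, k = 5, pol3, sc, rng_seed = 0)
  expect_gt(sum(is.na(g3$.group)), 0)
  # every formed group is compliant under the tibble-level checker
  formed <- g3[!is.na(g3$.group), ]
  if (nrow(formed) > 0) {
    expect_true(is_satisfied(check_ms_bounding(formed, 5, pol3)))
  }
})

test_that("greedy compliance matches brute-force feasibility at micro scale", {
  sc <- simple_schema()
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    sup <- random_supers(n, n_sym = 3, seed = 100 + rep)
    theta <- sample(c(0.4, 0.6, 1), 1)
    pol <- build_uniform_policy(paste0("S", 1:3), theta)
    g <- build_groups(sup, k = 2, pol, sc, rng_seed = rep)
    formed <- g[!is.na(g$.group), ]
    # greedy may be suboptimal but never non-compliant
    if (nrow(formed) > 0) {
      expect_true(is_satisfied(check_ms_bounding(formed, 2, pol)))
    }
    # a full greedy grouping certifies feasibility; infeasibility forces residuals
    feasible <- bf_feasible(sup$sa, 2, pol)
    if (sum(is.na(g$.group)) == 0) expect_true(feasible)
    if (!feasible) expect_gt(sum(is.na(g$.group)), 0)
  }
})

test_that("finalize places residuals by least cost and preserves every report", {
  sc <- simple_schema()
  sup <- random_supers(11, n_sym = 11, seed = 5)
  sup$sa <- as.list(paste0("S", 1:11))
  pol <- build_uniform_policy(paste0("S", 1:11), 1)
  data <- dplyr::mutate(sup[, c("isr", "case_id", "Age", "Gender", "sa", "qsa")])
  g <- build_groups(sup, k = 5, pol, sc, rng_seed = 0)
  expect_equal(sum(is.na(g$.group)), 1)
  fin <- finalize_groups(g, data, 5, pol, sc)
  expect_equal(sort(fin$data$isr), sort(data$isr))
  expect_equal(length(fin$forced), 0)
  expect_equal(dplyr::n_distinct(fin$data$.group), 2)
  # all rows of one group share one generalized QID signature
  sig <- dplyr::distinct(fin$data[, c(".group", "Age", "Gender")])
  expect_equal(nrow(sig), 2)
})

test_that("the full pipeline yields a compliant table and is deterministic", {
  raw <- raw_example1_style()
  fx <- fixture_example1()
  pol <- build_uniform_policy(sort(unique(unlist(fx$external$diseases))), 0.4)
  res <- anonymize(raw, 2, pol, fx$schema, fx$external, rng_seed = 0)
  expect_s3_class(res, "ms_anon")
  expect_equal(nrow(res$data), 6)
  expect_equal(dplyr::n_distinct(res$data$case_id), 4)
  expect_true(is_satisfied(
    check_ms_bounding(res$data, 2, pol, fx$external, fx$schema)))
  res2 <- anonymize(raw, 2, pol, fx$schema, fx$external, rng_seed = 0)
  expect_identical(res$data, res2$data)
  g <- glance(res)
  expect_equal(g$dr, 0)
  expect_equal(g$n_reports, 6)
  # empty input passes through
  res0 <- anonymize(raw[0, ], 2, pol, fx$schema, fx$external)
  expect_equal(nrow(res0$data), 0)
})

test_that("information loss and privacy risk obey their structural bounds", {
  fx <- fixture_example2()
  sc <- simple_schema()
  set.seed(21)
  for (rep in 1:10) {
    sup <- random_supers(8, n_sym = 4, seed = 200 + rep)
    g <- sup[1:5, ]; r <- sup[6, , drop = FALSE]
    il <- information_loss(g, sc)
    expect_gte(il, 0)
    # adding a record replicates the (possibly wider) cover across |g|+1 rows
    expect_gte(information_loss(dplyr::bind_rows(g, r), sc) + 1e-12,
               il * (nrow(g) + 1) / nrow(g))
    pol <- build_uniform_policy(paste0("S", 1:4), 0.5)
    pr <- privacy_risk(g, r, 3, pol)
    expect_true(pr >= 1)
    shared <- length(intersect(unlist(r$sa), unlist(g$sa))) > 0
    if (!shared) expect_equal(pr, 1)
    if (is.finite(pr) && pr == 1) expect_false(shared)
  }
})
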