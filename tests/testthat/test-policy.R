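# one case per symptom gives uniform frequencies, so bucket arithmetic and
# lexicographic tie-breaking are fully predictable
uniform_freq_data <- function(m) {
  tibble::tibble(
    isr = sprintf("r%03d", seq_len(m)),
    case_id = sprintf("c%03d", seq_len(m)),
    sa = as.list(sprintf("S%03d", seq_len(m))),
    qsa = rep(list(character(0)), m)
  )
}

test_that("uniform policy assigns one threshold to every value, range-checked", {
  p <- build_uniform_policy(paste0("I", 1:4), 0.6)
  expect_equal(p$theta, rep(0.6, 4))
  expect_equal(build_uniform_policy("X", 1)$theta, 1)
  expect_error(build_uniform_policy("X", 0), "probability in \\(0, 1\\]")
  expect_error(build_uniform_policy("X", 1.2), "probability in \\(0, 1\\]")
  expect_error(build_uniform_policy(character(0), 0.5), "non-empty")
})

test_that("level-wise policy maps high/non-sensitive/default tiers", {
  vals <- paste0("S", 1:6)
  p <- build_levelwise_policy(vals, high = c("S1", "S2"), nonsensitive = "S6")
  expect_equal(p$theta[match(c("S1", "S2"), p$value)], c(0.2, 0.2))
  expect_equal(p$theta[match("S6", p$value)], 1)
  expect_equal(p$theta[match(c("S3", "S4", "S5"), p$value)], rep(0.4, 3))
  # degenerate to uniform
  expect_equal(build_levelwise_policy(vals)$theta, rep(0.4, 6))
  expect_error(build_levelwise_policy(vals, high = "S1", nonsensitive = "S1"),
               "both 'high' and 'nonsensitive'")
})

test_that("frequency policy bucket sizes follow the ceiling arithmetic", {
  p10 <- build_frequency_policy(uniform_freq_data(10))
  expect_equal(as.integer(table(p10$theta)[c("0.2", "0.4", "1")]), c(1L, 8L, 1L))
  p20 <- build_frequency_policy(uniform_freq_data(20))
  expect_equal(as.integer(table(p20$theta)[c("0.2", "0.4", "1")]), c(2L, 16L, 2L))
  # single symptom: the top bucket wins
  expect_equal(build_frequency_policy(uniform_freq_data(1))$theta, 1)
  # ties broken lexicographically: first names land in the top bucket
  expect_equal(p20$value[p20$theta == 1], sprintf("S%03d", 1:2))
  expect_equal(p20$value[p20$theta == 0.2], sprintf("S%03d", 19:20))
})

test_that("confidence counts distinct cases, not reports", {
  fx <- fixture_example2()
  expect_equal(conf(fx$group, "I2"), 0.75)
  expect_equal(conf(fx$group, "absent"), 0)
  expect_equal(conf(fx$group[2, ], "I3"), 1)
  # a follow-up duplicate must not dilute the confidence
  dup <- dplyr::bind_rows(fx$group, dplyr::mutate(fx$group[1, ], isr = "r1b"))
  expect_equal(conf(dup, "I2"), 0.75)
})

test_that("external-linked confidence spreads belief uniformly over candidate diseases", {
  fx <- fixture_example1()
  uk <- fx$data[fx$data$Country == "UK", ]
  usa <- fx$data[fx$data$Country == "USA", ]
  # case 003 takes Paracetamol -> {Headache, Fever}: contributes 1/2;
  # case 004 takes Antacid -> {Stomachache, GERD}: contributes 0
  expect_equal(conf_external(uk, "Headache", fx$external), 0.25)
  expect_equal(conf_external(usa, "Headache", fx$external), 0.25)
  expect_equal(conf_external(uk, "Leukemia", fx$external), 0)
  # no knowledge table: only direct SA containment counts
  expect_equal(conf_external(uk, "Headache", NULL), 0)
  direct <- dplyr::mutate(uk[1, ], sa = list("Headache"))
  expect_equal(conf_external(direct, "Headache", NULL), 1)
  # unknown drug contributes nothing, with a warning
  odd <- dplyr::mutate(uk[1, ], qsa = list("Unobtainium"))
  expect_warning(v <- conf_external(odd, "Headache", fx$external),
                 "absent from external table")
  expect_equal(v, 0)
})

test_that("MS(k, theta*) compliance checks group size and linked confidence", {
  fx <- fixture_example1()
  pol <- build_uniform_policy(sort(unique(unlist(fx$external$diseases))), 0.4)
  ok <- check_ms_bounding(fx$data, 2, pol, fx$external, fx$schema)
  expect_true(is_satisfied(ok))
  expect_equal(nrow(ok), 0)
  # both groups hold two distinct cases, so k = 3 breaks both
  bad <- check_ms_bounding(fx$data, 3, pol, fx$external, fx$schema)
  expect_false(is_satisfied(bad))
  expect_equal(sum(bad$type == "group_size"), 2)
  expect_equal(glance(bad)$n_size_violations, 2)
  # 3 of 5 cases share s against theta 0.5 -> confidence violation at 0.6
  g5 <- tibble::tibble(
    isr = paste0("i", 1:5), case_id = paste0("c", 1:5),
    Age = "[20-30]", Gender = "M", Country = "USA",
    sa = list("s", "s", "s", "t", "t"), qsa = rep(list(character(0)), 5)
  )
  v <- check_ms_bounding(g5, 5, build_uniform_policy(c("s", "t"), 0.5),
                         NULL, fx$schema)
  expect_equal(v$value[v$type == "confidence"], "s")
  expect_equal(unname(v$confidence[v$type == "confidence"]), 0.6)
})

test_that("thresholds below a value's global frequency are flagged as unattainable", {
  d <- uniform_freq_data(5)
  d$sa[1:2] <- list(c("S001"), c("S001"))   # S001 in 2/5 cases
  pol <- build_uniform_policy(c("S001", "S003"), 0.39)
  expect_warning(w <- validate_thresholds(d, pol), "S001")
  expect_equal(w$value, "S001")
  expect_equal(w$frequency, 0.4)
  expect_equal(nrow(suppressWarnings(
    validate_thresholds(d, build_uniform_policy("S001", 0.4)))), 0)
  expect_equal(nrow(validate_thresholds(d, build_uniform_policy("S001", 1))), 0)
})
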