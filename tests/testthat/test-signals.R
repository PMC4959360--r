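# a table realizing the 2x2 counts (a, b, c, d) as distinct cases
cases_for_counts <- function(a, b, c, d, drug = "X", reaction = "Y") {
  n <- a + b + c + d
  tibble::tibble(
    isr = sprintf("i%03d", seq_len(n)),
    case_id = sprintf("c%03d", seq_len(n)),
    Age = "50", Gender = "Male",
    qsa = c(rep(list(drug), a + b), rep(list("other"), c + d)),
    sa = c(rep(list(reaction), a), rep(list("z"), b),
           rep(list(reaction), c), rep(list("z"), d))
  )
}

test_that("contingency construction counts distinct cases within the stratum", {
  d <- cases_for_counts(3, 7, 10, 80)
  t <- build_contingency(d, adr_rule("X", "Y"))
  expect_equal(c(t$a, t$b, t$c, t$d), c(3, 7, 10, 80))
  expect_equal(t$n, 100)
  # duplicate reports of one case count once
  dup <- dplyr::bind_rows(d, dplyr::mutate(d[1, ], isr = "extra"))
  t2 <- build_contingency(dup, adr_rule("X", "Y"))
  expect_equal(t2$a, 3)
  expect_equal(build_contingency(dup, adr_rule("X", "Y"), dedupe = FALSE)$a, 4)
  # empty table
  t0 <- build_contingency(d[0, ], adr_rule("X", "Y"))
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0, 0, 0, 0))
})

test_that("PRR, ROR and IC match direct arithmetic and handle degeneracies", {
  t <- contingency_table(3, 7, 10, 80)
  expect_equal(prr(t), 2.7)
  expect_equal(ror(t), 240 / 70)
  expect_equal(ic(t), log2(300 / 130))
  expect_equal(prr(contingency_table(0, 7, 10, 80)), 0)
  expect_equal(ror(contingency_table(0, 7, 10, 80)), 0)
  expect_true(is.na(ic(contingency_table(0, 7, 10, 80))))
  expect_true(is.na(prr(contingency_table(3, 7, 0, 80))))
  expect_true(is.na(ror(contingency_table(3, 0, 10, 80))))
  # independence: equal proportions give PRR = ROR = 1, IC = 0
  ind <- contingency_table(5, 45, 10, 90)
  expect_equal(prr(ind), 1)
  expect_equal(ror(ind), 1)
  expect_equal(ic(contingency_table(1, 0, 0, 0)), 0)
})

test_that("measures agree with brute-force recomputation on random tables", {
  set.seed(99)
  for (rep in 1:100) {
    x <- sample(0:50, 4, replace = TRUE)
    t <- contingency_table(x[1], x[2], x[3], x[4])
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]; n <- sum(x)
    if (a + b > 0 && c > 0) {
      expect_equal(prr(t), (a / (a + b)) / (c / (c + d)), tolerance = 1e-12)
    } else expect_true(is.na(prr(t)))
    if (b > 0 && c > 0 && d > 0) {
      expect_equal(ror(t), (a * d) / (b * c), tolerance = 1e-12)
    } else expect_true(is.na(ror(t)))
    if (a > 0) {
      expect_equal(ic(t), log2(a * n / ((a + b) * (a + c))), tolerance = 1e-12)
    } else expect_true(is.na(ic(t)))
    # standard 2x2 inequality: ROR >= PRR on positive-signal tables
    if (a > 0 && b > 0 && c > 0 && d > 0 && prr(t) >= 1) {
      expect_gte(ror(t), prr(t) - 1e-12)
    }
  }
})

test_that("contingency counts agree with a brute-force recount on a random dataset", {
  set.seed(5)
  n <- 400
  d <- tibble::tibble(
    isr = sprintf("i%04d", 1:n),
    case_id = sprintf("c%04d", sample(1:300, n, replace = TRUE)),
    Age = as.character(sample(10:90, n, replace = TRUE)),
    Gender = "Male",
    qsa = lapply(1:n, function(i) sample(c("X", "W", "V"), sample(1:2, 1))),
    sa = lapply(1:n, function(i) sample(c("Y", "U"), sample(1:2, 1)))
  )
  t <- build_contingency(d, adr_rule("X", "Y"))
  ids <- unique(d$case_id)
  has <- function(col, v) vapply(ids, function(cid)
    v %in% unlist(d[[col]][d$case_id == cid]), NA)
  hd <- has("qsa", "X"); hr <- has("sa", "Y")
  expect_equal(c(t$a, t$b, t$c, t$d),
               c(sum(hd & hr), sum(hd & !hr), sum(!hd & hr), sum(!hd & !hr)))
})

test_that("signal criteria evaluate their published formulas", {
  t <- contingency_table(3, 7, 10, 80)
  fl <- signal_flags(t)
  expect_equal(nrow(fl), 4)
  # Yates chi-squared by hand
  x2 <- (abs(3 * 80 - 7 * 10) - 100 / 2)^2 * 100 / (10 * 90 * 13 * 87)
  expect_equal(chisq_stat(t), x2)
  mhra <- fl[grepl("MHRA", fl$criterion), ]
  expect_equal(mhra$signal, prr(t) >= 2 && t$a >= 3 && x2 >= 4)
  prr_lo <- exp(log(prr(t)) - 1.96 * sqrt(1/3 - 1/10 + 1/10 - 1/90))
  expect_equal(fl$statistic[fl$criterion == "PRR-1.96SD>1"], prr_lo)
  expect_equal(fl$signal[fl$criterion == "PRR-1.96SD>1"], prr_lo > 1)
  # a strong disproportionality triggers all criteria
  strong <- signal_flags(contingency_table(30, 20, 10, 940))
  expect_true(all(strong$signal))
  # an empty signal triggers none
  expect_false(any(signal_flags(contingency_table(0, 10, 10, 80))$signal))
})

test_that("demographic predicates respect strict vs lenient interval matching", {
  d <- tibble::tibble(
    isr = c("1", "2", "3"), case_id = c("1", "2", "3"),
    Age = c("[20-30]", "[40-50]", "28"), Gender = c("M", "ANY", "F"),
    qsa = list("X", "X", "X"), sa = list("Y", "Y", "Y")
  )
  over25 <- adr_rule("X", "Y", qid_condition("Age", ">", 25))
  # strict: [40-50] and the point value 28; lenient additionally [20-30]
  expect_equal(build_contingency(d, over25, mode = "strict")$a, 2)
  expect_equal(build_contingency(d, over25, mode = "lenient")$a, 3)
  gender_f <- adr_rule("X", "Y", qid_condition("Gender", "==", "M"))
  expect_equal(build_contingency(d, gender_f, mode = "strict")$a, 1)
  expect_equal(build_contingency(d, gender_f, mode = "lenient")$a, 2)  # ANY overlaps
})

test_that("signal comparison is exact without predicates and reports deltas with them", {
  d <- cases_for_counts(3, 7, 10, 80)
  cmp <- compare_signals(d, d, adr_rule("X", "Y"))
  expect_equal(cmp$delta_prr, 0)
  expect_equal(cmp$delta_a, 0)
  # anonymization does not touch drugs or reactions: unconditional counts equal
  cfg <- synth_config(n_cases = 60, n_symptoms = 20, missing_rate = 0,
                      rng_seed = 8)
  syn <- synth_reports(cfg)
  pol <- build_uniform_policy(sensitive_frequencies(syn$data)$value, 1)
  res <- anonymize(syn$data, 3, pol, syn$schema, syn$external, rng_seed = 8)
  drug <- syn$data$qsa[[1]][1]; reac <- syn$data$sa[[1]][1]
  cmp2 <- compare_signals(syn$data, res$data, adr_rule(drug, reac))
  expect_equal(cmp2$delta_a, 0)
  expect_equal(cmp2$delta_prr, 0)
  # a predicate no interval strictly satisfies zeroes the stratum
  none <- adr_rule(drug, reac, qid_condition("Age", ">", 99.5))
  t_none <- build_contingency(res$data, none, mode = "strict")
  expect_equal(t_none$n, dplyr::n_distinct(
    res$data$case_id[parse_interval(res$data$Age)$lo > 99.5]))
})
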