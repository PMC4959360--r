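# Synthetic FAERS-like report generator.
#
# Emulates the structural features of spontaneous reporting data that the
# privacy model is designed around: follow-up reports duplicating a case,
# multi-valued SA with Zipf-skewed symptom frequencies (so a handful of
# symptoms are common and the tail is rare), multi-valued drug sets linked
# to an external drug-disease table, missing QID values, and plantable
# drug-reaction associations of known target strength.

#' Configuration for the synthetic report generator
#'
#' Defaults model a small FAERS-like extract: a skewed symptom vocabulary
#' whose most frequent term appears in roughly a fifth to a third of cases
#' (the regime where uniform low thresholds become unattainable), a modest
#' follow-up rate, and 5% missing QID cells.
#'
#' @param n_cases Number of distinct cases.
#' @param followup_rate Probability that a case has follow-up reports.
#' @param followup_count_max Maximum follow-ups per case.
#' @param age_range,weight_range Numeric QID domains (years, kg).
#' @param gender_probs Named probabilities for the Gender categories.
#' @param n_symptoms Symptom vocabulary size.
#' @param symptom_skew Zipf exponent for symptom frequencies.
#' @param symptoms_per_case Mean extra symptoms per case (count is
#'   `1 + Poisson(symptoms_per_case)`).
#' @param n_drugs Drug vocabulary size.
#' @param drugs_per_case Mean extra drugs per case (count is
#'   `1 + Poisson(drugs_per_case)`).
#' @param diseases_per_drug Range `c(min, max)` of diseases each drug treats
#'   in the external table (drawn uniformly from the symptom vocabulary).
#' @param indication_rate Probability that a case's SA also records an
#'   indication drawn from its drugs' treated diseases (drug-disease
#'   co-occurrence).
#' @param missing_rate Per-QID-cell missing probability.
#' @param followup_perturb Perturb follow-up ages by one year with
#'   probability 0.2 (exercises super-record interval generalization);
#'   off by default.
#' @param planted_rules Optional tibble with columns `drug`, `reaction`,
#'   `n_exposed`, `target_prr` (and optionally `age_min`, `age_max` for a
#'   stratum) describing drug-reaction associations to plant.
#' @param rng_seed Integer seed; generation is fully deterministic given
#'   the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 500, followup_rate = 0.2,
                         followup_count_max = 2,
                         age_range = c(0, 100), weight_range = c(0, 150),
                         gender_probs = c(Male = 0.5, Female = 0.5),
                         n_symptoms = 200, symptom_skew = 1,
                         symptoms_per_case = 1,
                         n_drugs = 40, drugs_per_case = 0.5,
                         diseases_per_drug = c(2, 4),
                         indication_rate = 0.3,
                         missing_rate = 0.05,
                         followup_perturb = FALSE,
                         planted_rules = NULL,
                         rng_seed = 0L) {
  stopifnot(n_cases >= 1, followup_rate >= 0, followup_rate <= 1,
            followup_count_max >= 1, missing_rate >= 0, missing_rate <= 1,
            indication_rate >= 0, indication_rate <= 1,
            n_symptoms >= 1, symptom_skew >= 0, n_drugs >= 1,
            age_range[2] > age_range[1], weight_range[2] > weight_range[1])
  if (!is.null(planted_rules)) {
    stopifnot(all(c("drug", "reaction", "n_exposed", "target_prr") %in%
                    names(planted_rules)),
              all(planted_rules$target_prr > 0))
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Schema matching the synthetic generator's output
#'
#' @param cfg A [synth_config()].
#' @return An [srs_schema()] with numeric `Age` and `Weight`, categorical
#'   `Gender` (bundled hierarchy), and `SA`/`QSA` I/O columns.
#' @export
synth_schema <- function(cfg) {
  srs_schema(
    qid_numeric = list(Age = cfg$age_range, Weight = cfg$weight_range),
    qid_categorical = list(Gender = gender_hierarchy()),
    sa = "SA", qsa = "QSA"
  )
}

#' Generate a synthetic FAERS-like report table
#'
#' Produces a report tibble in the package's canonical layout, the matching
#' external drug-disease knowledge table, and a ground-truth tibble for any
#' planted drug-reaction rules (their realized 2x2 counts and PRR).
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `data`, `external`, `truth`, `schema`.
#' @export
synth_reports <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_cases
  symptoms <- sprintf("PT_%04d", seq_len(cfg$n_symptoms))
  drugs <- sprintf("DRUG_%03d", seq_len(cfg$n_drugs))
  zipf_w <- seq_len(cfg$n_symptoms)^(-cfg$symptom_skew)

  # external knowledge table: each drug treats a few diseases, drawn
  # uniformly from the symptom vocabulary (treatments cover the catalogue
  # broadly, not proportionally to reporting frequency)
  n_dis <- sample(cfg$diseases_per_drug[1]:cfg$diseases_per_drug[2],
                  cfg$n_drugs, replace = TRUE)
  treats <- lapply(n_dis, function(m) sort(sample(symptoms, m)))
  external <- external_table(rep(drugs, lengths(treats)), unlist(treats))

  case_id <- sprintf("C%05d", seq_len(n))
  age <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]))
  weight <- round(stats::runif(n, cfg$weight_range[1], cfg$weight_range[2]))
  gender <- sample(names(cfg$gender_probs), n, replace = TRUE,
                   prob = cfg$gender_probs)
  case_drugs <- lapply(seq_len(n), function(i) {
    sort(sample(drugs, min(cfg$n_drugs, 1 + stats::rpois(1, cfg$drugs_per_case))))
  })
  case_sa <- lapply(seq_len(n), function(i) {
    m <- min(cfg$n_symptoms, 1 + stats::rpois(1, cfg$symptoms_per_case))
    sa <- sample(symptoms, m, prob = zipf_w)
    if (stats::runif(1) < cfg$indication_rate) {
      indi <- unlist(external$diseases[match(case_drugs[[i]], external$drug)])
      if (length(indi) > 0L) sa <- c(sa, sample(indi, 1))
    }
    sort(unique(sa))
  })

  # plant drug-reaction associations of known target strength
  truth <- NULL
  if (!is.null(cfg$planted_rules)) {
    truth_rows <- list()
    for (ri in seq_len(nrow(cfg$planted_rules))) {
      rule <- cfg$planted_rules[ri, ]
      in_stratum <- rep(TRUE, n)
      if ("age_min" %in% names(rule) && !is.na(rule[["age_min"]])) {
        in_stratum <- in_stratum & age >= rule[["age_min"]]
      }
      if ("age_max" %in% names(rule) && !is.na(rule[["age_max"]])) {
        in_stratum <- in_stratum & age <= rule[["age_max"]]
      }
      pool <- which(in_stratum)
      if (length(pool) < rule$n_exposed) {
        stop("planted rule ", rule$drug, ": stratum holds only ",
             length(pool), " cases, need ", rule$n_exposed)
      }
      exposed <- sample(pool, rule$n_exposed)
      unexposed <- setdiff(seq_len(n), exposed)
      p0 <- mean(vapply(case_sa[unexposed],
                        function(v) rule$reaction %in% v, NA))
      if (p0 <= 0) {
        stop("planted rule ", rule$drug, ": background rate of ",
             rule$reaction, " is zero; pick a more frequent reaction")
      }
      p1 <- rule$target_prr * p0
      if (p1 > 1) {
        stop("planted rule ", rule$drug, ": target PRR ", rule$target_prr,
             " infeasible; background rate ", signif(p0, 3),
             " caps PRR at ", signif(1 / p0, 3))
      }
      for (i in exposed) {
        case_drugs[[i]] <- sort(unique(c(case_drugs[[i]], rule$drug)))
        has <- stats::runif(1) < p1
        sa <- setdiff(case_sa[[i]], rule$reaction)
        if (has) sa <- c(sa, rule$reaction)
        case_sa[[i]] <- sort(unique(sa))
      }
      truth_rows[[ri]] <- tibble::tibble(
        drug = rule$drug, reaction = rule$reaction,
        n_exposed = rule$n_exposed, target_prr = rule$target_prr,
        background_rate = p0)
    }
    truth <- dplyr::bind_rows(truth_rows)
  }

  # expand cases into reports (base + follow-ups)
  n_fu <- ifelse(stats::runif(n) < cfg$followup_rate,
                 sample.int(cfg$followup_count_max, n, replace = TRUE), 0L)
  rows <- rep(seq_len(n), 1L + n_fu)
  data <- tibble::tibble(
    isr = sprintf("R%06d", seq_along(rows)),
    case_id = case_id[rows],
    Age = as.numeric(age[rows]),
    Weight = as.numeric(weight[rows]),
    Gender = gender[rows],
    sa = case_sa[rows],
    qsa = case_drugs[rows]
  )
  if (cfg$followup_perturb) {
    fu <- duplicated(data$case_id)
    bump <- fu & stats::runif(nrow(data)) < 0.2
    data$Age[bump] <- pmin(cfg$age_range[2], pmax(cfg$age_range[1],
      data$Age[bump] + sample(c(-1, 1), sum(bump), replace = TRUE)))
  }
  if (cfg$missing_rate > 0) {
    for (nm in c("Age", "Weight", "Gender")) {
      data[[nm]][stats::runif(nrow(data)) < cfg$missing_rate] <- NA
    }
  }

  if (!is.null(truth)) {
    realized <- lapply(seq_len(nrow(truth)), function(ri) {
      t <- build_contingency(data, adr_rule(truth$drug[ri], truth$reaction[ri]))
      tibble::tibble(a = t$a, b = t$b, c = t$c, d = t$d, realized_prr = prr(t))
    })
    truth <- dplyr::bind_cols(truth, dplyr::bind_rows(realized))
  }

  list(data = data, external = external, truth = truth,
       schema = synth_schema(cfg))
}

# ---- worked-example fixtures ------------------------------------------------

#' Six-report sample table with its external knowledge table
#'
#' A small anonymized FAERS-style table of six reports over four cases in
#' two QID-groups (`[20-30]`/M/USA and `[30-40]`/F/UK), together with a
#' four-drug external drug-disease table. The table satisfies
#' MS(2, 0.4)-bounding: both groups hold two distinct cases and no disease
#' is inferable with confidence above 0.4 even via drug linkage.
#'
#' @return A list with `data`, `external`, `schema`.
#' @export
fixture_example1 <- function() {
  data <- tibble::tibble(
    isr = sprintf("%03d", 1:6),
    case_id = c("001", "001", "002", "002", "003", "004"),
    Age = c(rep("[20-30]", 4), rep("[30-40]", 2)),
    Gender = c(rep("M", 4), rep("F", 2)),
    Country = c(rep("USA", 4), rep("UK", 2)),
    sa = rep(list(character(0)), 6),
    qsa = list("Paracetamol", "Paracetamol",
               c("Antacid", "Intron A"), c("Antacid", "Intron A"),
               "Paracetamol", "Antacid")
  )
  external <- external_table(
    drug = c(rep("Aspirin", 3), rep("Intron A", 4), rep("Paracetamol", 2),
             rep("Antacid", 2)),
    disease = c("Flu", "Headache", "Fever",
                "Hepatitis B", "Hepatitis C", "Leukemia", "Melanoma",
                "Headache", "Fever",
                "Stomachache", "GERD")
  )
  schema <- srs_schema(
    qid_numeric = list(Age = c(0, 100)),
    qid_categorical = list(
      Gender = hierarchy(c("ANY", "ANY"), c("M", "F"), "Gender"),
      Country = hierarchy(c("ANY", "ANY"), c("USA", "UK"), "Country")
    ),
    sa = "Reactions", qsa = "Drugs"
  )
  list(data = data, external = external, schema = schema)
}

#' Known-group / isolated-records fixture for the selection metrics
#'
#' A QID-group of four cases, homogeneous in Gender (Male) and Age (Young
#' Adult) with weight interval `[50-75]`, plus three isolated candidate
#' records, under QID = \{Gender, Age, Weight\} with weight domain
#' \[0, 100\], the height-1 gender tree and the height-2 age-group tree.
#' Under `k = 5` and uniform threshold 0.6 the candidates score
#' `PR = 1.5, 3.5, Inf`, and the greedy metric picks `r5`.
#'
#' @return A list with `group`, `candidates`, `schema`, `k`, `policy`.
#' @export
fixture_example2 <- function() {
  group <- tibble::tibble(
    isr = paste0("r", 1:4), case_id = paste0("r", 1:4),
    Gender = "Male", Age = "Young Adult", Weight = "[50-75]",
    sa = list("I1", c("I2", "I3", "I4"), c("I2", "I3"), "I2"),
    qsa = rep(list(character(0)), 4)
  )
  candidates <- tibble::tibble(
    isr = paste0("r", 5:7), case_id = paste0("r", 5:7),
    Gender = c("Male", "Female", "Male"),
    Age = c("Adolescent", "Adult", "Young Adult"),
    Weight = c("50", "40", "80"),
    sa = list("I1", c("I3", "I4"), c("I2", "I3")),
    qsa = rep(list(character(0)), 3)
  )
  schema <- srs_schema(
    qid_numeric = list(Weight = c(0, 100)),
    qid_categorical = list(Gender = gender_hierarchy(),
                           Age = mesh_age_hierarchy()),
    sa = "Indications"
  )
  list(group = group, candidates = candidates, schema = schema,
       k = 5, policy = build_uniform_policy(paste0("I", 1:4), 0.6))
}
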