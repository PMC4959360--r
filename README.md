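# srsanon

Privacy-preserving anonymization of spontaneous adverse-drug-event (ADE)
reports, with built-in checks that the sanitized data still supports
pharmacovigilance signal detection.

## The problem

Spontaneous reporting systems (SRS) such as FAERS collect voluntarily
submitted ADE reports. Before such tables can be published they must be
sanitized: quasi-identifiers (age, gender, weight, ...) could be linked with
outside information to re-identify patients, and the reported reactions,
indications and drugs reveal sensitive health facts. SRS tables defeat the
classic microdata models (k-anonymity, l-diversity) on three counts:

* **rare events** — new ADRs occur a handful of times, and suppressing rare
  records is exactly what destroys the signals of interest;
* **multiple records per individual** — follow-up reports share a `CaseID`,
  so a "group of k records" may really contain far fewer than k people;
* **multi-valued sensitive and quasi-sensitive attributes** — each report
  carries sets of reaction/indication terms, and drug names become sensitive
  once linked to an external drug–disease knowledge table (knowing a patient
  takes an antiretroviral combination is knowing the diagnosis).

## The model

`srsanon` implements **MS(k, θ\*)-bounding**. A released table D\* satisfies
MS(k, θ\*)-bounding iff

1. every QID-group contains at least *k* **distinct cases**, and
2. for every protected sensitive value *s*ᵢ with threshold *θ*ᵢ, the
   confidence of inferring *s*ᵢ for a group *q* — with or without the
   external table *E* — is bounded: conf(q → *s*ᵢ, E) ≤ *θ*ᵢ.

Thresholds can differ per value (uniform, level-wise, or frequency-based
strategies), encoding that a rare AIDS-related term deserves a tighter bound
than a cough.

The anonymizer is a two-stage greedy clustering. Reports sharing a case are
first merged into *super records*. Groups then grow from a seed record by
repeatedly adding the candidate *r* minimizing

ΔIL′(g, r) = ΔIL(g, r) × PR(g, r),

where ΔIL is the increase in information loss

IL(g) = |g| · ( Σᵢ (max(Nᵢ,g) − min(Nᵢ,g)) / (max(Nᵢ) − min(Nᵢ))
              + Σⱼ h(Cⱼ,g) / h(Cⱼ) )

(numeric QIDs generalize to covering intervals, categorical QIDs to their
lowest common ancestor in a value hierarchy), and PR is the privacy risk
PR(g, r) = 1 + Σ_{s∈Sᵣ} σₛ(g) / (ηₛ(g∪{r}) − σₛ(g)), with
ηₛ = ⌊max{k, |g|} · θₛ⌋ the number of s-carriers a group can tolerate; PR is
infinite when a threshold would be breached. Residual records are then
placed at least cost, super records are split back into their original
reports, and each group receives one generalized QID signature.

Quality is measured by **NIL** (normalized information loss, utility) and
**DR** (dangerous ratio: the fraction of groups containing an
over-threshold value), and signal impact by **PRR / ROR / IC**
disproportionality on the 2×2 drug–reaction contingency table, with the
standard MHRA and confidence-bound criteria.

## Worked example

```r
library(srsanon)

cfg    <- synth_config(n_cases = 500, rng_seed = 0)   # FAERS-like synthetic extract
syn    <- synth_reports(cfg)
policy <- build_frequency_policy(syn$data)            # top 10% free, bottom 10% at 0.2, rest 0.4
res    <- anonymize(syn$data, k = 5, policy, syn$schema, syn$external, rng_seed = 0)
res
#> MS(k, theta*)-bounding anonymization
#>   k = 5  |S| = 170
#>   reports released: 563  (dropped for missing QID: 95 )
#>   QID-groups: 87  forced placements: 0  repair merges: 0
glance(res)
#> # A tibble: 1 × 8
#>   n_groups n_reports n_cases   nil    dr n_forced n_merges n_dropped
#>      <int>     <int>   <int> <dbl> <dbl>    <int>    <int>     <int>
#> 1       87       563     438 0.505     0        0        0        95
head(res$data[, c("isr", "case_id", "Age", "Weight", "Gender", ".group")], 3)
#> # A tibble: 3 × 6
#>   isr     case_id Age     Weight    Gender .group
#>   <chr>   <chr>   <chr>   <chr>     <chr>   <int>
#> 1 R000001 C00001  [55-66] [124-146] Female     32
#> 2 R000002 C00001  [55-66] [124-146] Female     32
#> 3 R000003 C00002  [60-71] [4-24]    Male       45
```

Every released group holds ≥ 5 distinct cases; `dr = 0` says no sensitive
value anywhere exceeds its disclosure threshold, even via drug–disease
linkage; `nil ≈ 0.5` quantifies the generalization paid for it (0 would be
no distortion). `tidy(res)` gives the per-group detail, `autoplot(res)` the
group-size chart, and `compare_signals()` the before/after PRR/ROR per ADR
rule.

A shell front end wrapping the same functions ships in
`inst/scripts/srs-anon` (subcommands `convert`, `check`, `anonymize`,
`evaluate`, `signals`, `synth`).

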