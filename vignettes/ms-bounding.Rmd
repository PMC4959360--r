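---
title: "Anonymizing spontaneous ADE reports with MS(k, theta*)-bounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing spontaneous ADE reports with MS(k, theta*)-bounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsanon)
library(dplyr)
```

## The privacy model

A spontaneous-reporting table is viewed as four disjoint attribute sets:
quasi-identifiers (QID: here Age, Weight, Gender), multi-valued sensitive
attributes (SA: reaction and indication preferred terms, merged by set
union into one per-report set), quasi-sensitive attributes (QSA: drug
names), and everything else (NSA, carried through). Each report has a
unique report identifier (`isr`) and a case identifier (`case_id`) shared
by follow-up reports of the same event.

A released table satisfies **MS(k, θ\*)-bounding** when every QID-group
(the rows sharing one generalized QID signature) contains at least `k`
*distinct cases*, and for every protected sensitive value `s` the
attacker's confidence is bounded by its threshold: both the direct
confidence `conf(q → s)` — the fraction of the group's distinct cases whose
SA set contains `s` — and the confidence after linking an external
drug–disease table `E`. Counting *cases* rather than *reports* is what
distinguishes the model from record-oriented ones: a group of `k` reports
may describe a single patient.

Two modelling choices deserve emphasis, because the model's definitions fix
only their values, not their form:

* **External-linkage confidence.** For a case whose SA does not contain
  `s`, let `U` be the union of the disease sets of the case's drugs. The
  case contributes `1/|U|` when `s ∈ U` and 0 otherwise — the attacker's
  belief is spread uniformly over the candidate diseases; a case whose SA
  contains `s` directly contributes 1. The group confidence is the mean
  contribution over distinct cases. This uniform-over-union rule is the
  simplest distribution consistent with the model's worked linkage value
  (0.25 for a two-disease drug held by one of two cases); it is isolated
  behind `conf_external()` so an alternative (e.g. a joint multi-label
  model over drug combinations) can be swapped in without touching
  compliance checking. The effective confidence used everywhere is
  `max(conf, conf_external)`, since the bound must hold with or without
  external knowledge.
* **Attainability.** Generalization can only average a value's prevalence
  across groups, never reduce it below the dataset-wide case frequency
  `P(s)`; a threshold `θ_s < P(s)` is unattainable by generalization alone.
  `validate_thresholds()` warns about such values up front, and
  `anonymize()` proceeds with the warning on record rather than failing —
  the honest outcome is then a nonzero dangerous ratio.

## Threshold strategies

`θ*` is a vector, one threshold per protected value, built three ways:

* **uniform** (`build_uniform_policy()`): one bound for everything. 0.4 is
  a workable default for data whose most frequent symptom sits near 20–30%
  of cases; 0.2 typically collides with the attainability constraint on
  real extracts, where single terms can exceed 20%.
* **level-wise** (`build_levelwise_policy()`): a curated "high sensitive"
  set at 0.2, a "non-sensitive" set at 1 (unprotected), the remainder at
  0.4. Mirrors practice where only specific term groups (e.g.
  AIDS-related) are truly sensitive.
* **frequency-based** (`build_frequency_policy()`): "the more frequent, the
  less sensitive" — rank symptoms by case frequency; the top
  `⌈0.1·m⌉` get 1, the bottom `⌈0.1·m⌉` get 0.2, the rest 0.4. This
  strategy is self-calibrating: frequent values land in the unprotected
  bucket, so the attainability constraint is satisfied by construction.
  Ties are broken lexicographically, and the top bucket wins overlaps, so
  the policy is deterministic.

## The metrics driving the greedy clustering

For a group `g`, with numeric QID attributes `N_i` (global domain ranges
from the schema) and categorical attributes `C_j` (each with a
generalization hierarchy of height `h(C_j)`):

`IL(g) = |g| × ( Σ_i (max(N_i,g) − min(N_i,g)) / (max(N_i) − min(N_i)) + Σ_j h(C_j,g) / h(C_j) )`

`h(C_j, g)` is the height of the lowest common ancestor of the group's
values, measured **bottom-up**: leaves at height 0, the root of a height-H
tree at H. The convention matters — it makes homogeneous groups lose
nothing and the fully suppressed value cost the full unit, and it is the
only convention consistent with the bundled worked example
(`fixture_example2()`), whose three age terms must evaluate to 2/2, 1/2 and
0/2. `|g|` counts whatever rows the group holds at the stage being
evaluated: super records during clustering, original reports in the
released table.

The privacy risk of adding record `r` (sensitive set `S_r`) to `g`:

* capacity `η_s = ⌊max{k, |g∪{r}|} × θ_s⌋` — the most `s`-carriers the
  post-inclusion group may hold. The capacity is evaluated on the
  *post-inclusion* size; that is the reading under which the worked
  example's printed denominators (3−1, 3−2) come out.
* `PR_s = σ_s(g) / (η_s − σ_s(g))` when `η_s > σ_s(g)`, else `∞`, where
  `σ_s(g)` counts the group's super records (distinct cases) carrying `s`
  directly.
* `PR(g, r) = 1 + Σ_{s∈S_r∩S} PR_s`, with `∞` absorbing. The leading 1
  keeps the product metric `ΔIL′ = ΔIL × PR` sensitive to information loss
  when all of `r`'s values are new to the group (`PR = 1`).

The bundled worked example pins these numbers down: the four-record group
has `IL = 1`; adding its three candidates gives `IL = 6.25`, `9.25`, `1.5`
and `PR = 1.5`, `3.5`, `∞`; the greedy metric selects the first candidate.

```{r worked-example}
fx <- fixture_example2()
information_loss(fx$group, fx$schema)
privacy_risk(fx$group, fx$candidates[2, ], fx$k, fx$policy)
select_best_record(fx$group, fx$candidates, fx$k, fx$policy, fx$schema)$case_id
```

## The two-stage algorithm

**Stage 1 — greedy clustering** (`build_groups()`):

1. merge reports by `case_id` into super records (numeric QIDs to covering
   intervals, categorical QIDs to the LCA, SA/QSA unioned) so follow-ups
   can never be split across groups or shrink a group's effective size;
2. seed the first group with a uniformly random super record (under
   `rng_seed`); grow the group by the candidate with least `ΔIL′`,
   breaking ties by smaller `ΔIL`, then `case_id` order, until the group
   holds ≥ k cases *and* every protected value's effective confidence is
   within threshold;
3. seed each later group with the candidate most distinguished from the
   previous seed (largest pairwise information loss), and repeat;
4. stop when fewer than `k` records remain, or when a group in progress
   finds no candidate with finite `ΔIL′` (typically: the remaining records
   all share an over-represented value). The members of such a stuck group
   are returned to the residual pool — by then the residual pool is
   dominated by records that no group can absorb, so clustering ends
   rather than re-attempting seeds that would stall the same way.

**Stage 2 — finalization** (`finalize_groups()`):

1. each residual joins the existing group with least finite `ΔIL′`; when
   every group scores `∞` it joins the group with least `ΔIL`, and the
   placement is recorded as *forced*;
2. forced placements are re-verified: any group left over threshold is
   repaired by merging it with the partner giving the cheapest combined
   information loss, repeated until compliant. Merging can only dilute an
   over-represented value toward its global frequency, so when every
   threshold is attainable the repair terminates with a compliant
   partition — this is what makes the released table's dangerous ratio
   exactly zero by construction, not just usually zero. Merges are counted
   and reported;
3. super records are split back into their original reports (group
   membership retained, the ISR multiset is preserved exactly), and each
   group's QID values are generalized to one signature — numeric
   `[min-max]` over the group, categorical LCA label.

## Numerical and degenerate-input choices

* Threshold comparisons use a `1e-9` slack, and the capacity floor is
  computed as `⌊x + 1e-9⌋` (bucket ceilings as `⌈x − 1e-9⌉`): products
  like `5 × 0.6` must count as 3, not 2.999…
* `ΔIL = 0` with `PR = ∞` is `∞` (a breaching record is never admissible,
  however cheap); `ΔIL = 0` with finite `PR` is 0.
* All randomness flows through one integer seed; identical inputs and seed
  give byte-identical output. Everything after the first-group seed is
  deterministic via the documented tie-breaks.
* Intervals are closed, serialized `[lo-hi]` (en dash accepted on input),
  degenerate intervals as the plain number. Records with any missing QID
  value are discarded before clustering, with the count reported —
  imputation is out of scope.
* The NIL normalization `Σ IL(g) / (n_g × |QID|)` can exceed 1 when groups
  are large (its group term scales with group size); the raw value is
  reported with a message rather than clamped.

## What the synthetic generator does and does not emulate

`synth_reports()` exists so that every pipeline stage is testable without
access to a real SRS extract. It reproduces the structural features the
model is designed around: distinct cases with follow-up duplicates (20% of
cases, up to 2 extra reports), Zipf-skewed symptom frequencies over a
200-term vocabulary (exponent 1, putting the top term near 20–30% of cases
— the regime where uniform θ = 0.2 becomes unattainable, as on real
quarterly extracts), multi-valued drug sets, an external drug–disease
table whose diseases are drawn uniformly from the symptom vocabulary (with
optional indication co-occurrence in the SA sets), 5% missing QID cells,
and plantable drug–reaction associations calibrated to a target PRR via
the background reaction rate (with an explicit feasibility bound). The
acceptance-scale runs use 500 cases for the compliance conditions and
2,000 cases for signal preservation; both sizes keep the full suite in the
tens of seconds while leaving every group-formation phenomenon (residuals,
forced placements, repair merges) reachable.

It does **not** emulate real FAERS marginals: no MedDRA term structure, no
correlated demographics, no drug co-prescription patterns, no
reporting-over-time dynamics, and ages/weights are uniform rather than
realistic. Passing tests on synthetic data therefore demonstrate the
algorithm's contracts (compliance, conservation, determinism, signal
invariance) — not utility figures transferable to a specific real extract.

## Scope and limitations

* Generalization is the only operator: no suppression, no counterfeit
  records, no perturbation. Values whose frequency exceeds their threshold
  therefore stay unattainable (flagged, not silently fixed).
* QSA values (drug names) are never generalized; they enter only through
  the linkage confidence. Hierarchies are strict trees — multi-parent
  taxonomies are out of scope.
* The greedy clustering is heuristic: it guarantees compliance, not
  IL-optimality, and a brute-force enumeration at micro scale (see the
  test suite) confirms exactly that trade-off.
* "Most distinguished" seed selection measures distance to the previous
  *seed*, not to the previous group; the choice is isolated in
  `select_seed_record()`.
* The IC signal criterion uses a frequentist normal approximation on the
  log2 scale, not the Bayesian shrinkage interval; it is labelled
  approximate in `signal_flags()` output.

## End-to-end run

```{r pipeline, eval = FALSE}
syn <- synth_reports(synth_config(n_cases = 500, rng_seed = 0))
policy <- build_frequency_policy(syn$data)
res <- anonymize(syn$data, k = 5, policy, syn$schema, syn$external, rng_seed = 0)
glance(res)          # n_groups, NIL, DR (0 by construction), drops
tidy(res)            # per-group IL and worst confidence
autoplot(res)        # group sizes against k
compare_signals(drop_missing_qid(syn$data, syn$schema), res$data,
                adr_rule("DRUG_001", "PT_0001"))
```
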