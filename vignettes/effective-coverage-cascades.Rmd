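---
title: "Estimating effective coverage cascades for antenatal care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effective coverage cascades for antenatal care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effcascade)
```

## The problem

Service *contact* coverage — the share of pregnant women who attended
antenatal care (ANC) at least once — is high in many low- and middle-income
countries, yet maternal outcomes have not improved in proportion. Contact
alone says nothing about whether the facility a woman attended had the inputs
to deliver care (readiness), whether she received the key clinical
interventions, or whether the care process met clinical standards
(provision/experience of care). An *effective coverage cascade* decomposes
coverage into ordered steps, each bounded above by the previous one in
expectation:

1. **Target population** — women 15–49 with a live birth in the last two
   years; fixed at 100% by definition.
2. **Service contact** — at least *k* ANC visits (k = 1, 4, 8) from a
   qualified provider.
3. **Readiness-adjusted coverage** — the contact indicator scaled by the
   readiness score of the place(s) of care.
4. **Intervention coverage** — the average share of key interventions
   (tetanus toxoid, SP for malaria where relevant, iron–folic acid, blood
   pressure, urine and blood tests, deworming) each woman reports receiving.
5. **Quality-adjusted coverage** — the contact indicator scaled by the
   provision/experience-of-care score of the place(s) of care.

User-adherence- and outcome-adjusted steps exist conceptually but are not
estimable from household surveys and facility assessments, so this package
never emits them. Cascades are computed separately for the full ANC service
and for the maternal-nutrition (MN) subset of items and interventions.

The two data sources cannot be linked at the individual level: household
surveys do not record which facility a woman attended, only its *type* (and
her region or district of residence). The method therefore links
*ecologically*: each woman receives the average score of the stratum —
geographic domain crossed with facility category — matching each source of
care she reported.

## Scores

Readiness and quality are additive indices on [0, 1]. A facility's readiness
score is the unweighted mean of its collected index items: binary
availability indicators (equipment, medicines, diagnostics, guidelines) and
training proportions in [0, 1] (the share of ANC providers trained in a
topic; an assessment that only asks "at least one staff trained?" yields a
degenerate 0/1 proportion). Items a country's instrument never collected are
removed via the index's *country mask*; an item missing incidentally for one
facility drops out of that facility's denominator only. No domain weighting
is applied — items are roughly balanced across domains, and additive ANC
indices have been found robust to adding or removing a few items.

A client's quality score is the analogous mean over items observed during an
ANC first visit (history taking, examination, investigations, counselling,
client experience); only first-visit items are eligible, because the correct
content of later visits depends on earlier ones, which a cross-sectional
assessment cannot see.

Stratum readiness is the facility-weight-weighted mean of facility scores.
Stratum quality *pools all client observations in the stratum* with client
weights — deliberately not a mean of per-facility means — so high-caseload
facilities count more and the mean represents the average client rather than
the average facility. Where a stratum contains no surveyed units, the
national mean for that facility category substitutes (we weight national
means by facility weights for consistency with the stratum means; the
alternative unweighted convention differs negligibly and is not offered).

## Linking rules

- Each distinct reported source maps, via a country-specific provider
  mapping, to a facility category, to `UNQUALIFIED`, or — for qualified
  non-facility providers such as community health workers with no usable
  facility proxy — to a fixed score in [0, 1].
- Women reporting several qualified sources get the unweighted mean of the
  resolved scores; care from unqualified sources is ignored when a qualified
  source exists. (Alternatives — taking the best or worst source — bound the
  client experience rather than describe it, and are not implemented.)
- Women whose only care was unqualified, or who had no ANC, score zero; they
  also contribute zero contact.
- A mapping that targets a category with no surveyed facility anywhere is an
  error rather than a silent zero: zero means "no readiness", not "no data".

Contact at threshold *k* requires reported ANC, at least one qualified
source, and a visit count of at least *k*; women unsure of their count are
imputed one visit, so they count for ANC1 only. Intervention coverage
averages each woman's received share over her non-missing masked receipt
responses (missing answers are not imputed; women with all responses missing
drop out of numerator and denominator) and does not depend on *k* — hence it
can exceed readiness-adjusted coverage in the 4+/8+ cascades.

## Uncertainty

Contact and intervention coverage involve the household survey alone; their
variance is the standard Taylor linearisation of a weighted ratio mean under
stratified cluster sampling (with-replacement PSU approximation). Strata
holding a single cluster are collapsed into the neighbouring stratum, a
common certainty-unit treatment; a design in which *every* stratum has one
cluster is refused.

Readiness- and quality-adjusted coverage inherit uncertainty from both
surveys. Their variance is a two-survey delete-one-group jackknife:

- **Component A** — withhold each household cluster in turn (remaining
  weights unchanged) and re-estimate; `var_A = (G−1)/G · Σ (θ̂₍₋g₎ − θ̄)²`.
- **Component B** — withhold each facility together with its client
  observations, rebuild the stratum score table from scratch, re-link every
  woman, re-estimate; scaled analogously.

The total is `var_A + var_B`. No published formula combines the two
components; additivity is our design choice, justified by the independence
of the household and facility samples (the cross-term it ignores is the
product of the two components' relative variances, second-order small). If
deleting a facility empties a national fallback category the replicate is
excluded with a warning; generator defaults keep at least two facilities per
category so this cannot occur in shipped validation runs. 95% intervals are
`estimate ± 1.96·SE`, truncated to [0, 1].

## The synthetic generator and its closed-form truth

Restricted-access microdata cannot ship with a package, so validation rests
on a generator that emulates the structure of the real inputs:

- women in `n_clusters` clusters (round-robin across `n_domains` domains,
  design stratum = domain), log-normal weights, care-seeking drawn over
  configured *source sets* (including "none" and unqualified-only),
  zero-truncated negative-binomial visit counts with a small probability of
  an "unsure" response, and Bernoulli intervention receipts whose
  probability depends on qualified contact, with equal-rate missingness;
- facilities per category per domain with independent Bernoulli item
  indicators and Beta-distributed training proportions;
- one-plus-Poisson client observations per facility with independent
  Bernoulli care items.

Because item indicators are independent given the category and weights are
independent of outcomes, the expectation of every cascade step is available
in closed form (`closed_form_truth()`), and every pipeline estimator is
exactly unbiased for it. The defaults describe a plausible country: ANC1
contact ≈ 0.89 (national surveys in this setting report 80–99%), a steep
ANC1 ≫ ANC4 ≫ ANC8 gradient (visit model mean 3.8, dispersion 3),
unqualified-only care 3% (under the ≤6% seen in survey data), readiness
means ≈ 0.55–0.80 declining from hospitals to primary facilities, quality
means ≈ 0.55–0.65 with counselling weakest, and intervention receipt
probabilities averaging ≈ 0.67 given contact. These are structural
emulations, not fits to any country's microdata.

What the generator deliberately omits: item–item correlation within
facilities (a correlation knob would break the closed-form truth and is left
unimplemented), facility random effects in client quality, preferential
care-seeking toward better facilities (the known bias risk of ecological
linking), and recall error. Passing recovery tests therefore demonstrates
correctness of the estimators under the model's assumptions, not robustness
of ecological linking on real data.

## Validation choices and problem sizes

- **Oracle equivalence**: on bundles of ≤ 50 women and 10 facilities, every
  estimator — stratum means, linked scores, contact, intervention, adjusted
  coverage, Taylor and jackknife variances — must match an independently
  coded plain-loop implementation to 1e-10.
- **Parameter recovery** runs at 200 clusters × 25 women and 200 facilities
  (8 domains × 25 facilities), with Monte-Carlo SEs taken from 200 replicate
  seeds at the same scale; the designated run must sit within 3 MC SEs of
  the closed-form truth on every step, and the replicate mean within
  4 SE/√200.
- **Jackknife calibration** compares the mean estimated variance over 500
  replicate surveys against the empirical variance of the estimator pooled
  over 2000 replicates (so the reference's own Monte-Carlo error, about 3%,
  is small against the 20% acceptance band), at 40 clusters × 10 women and
  50 facilities (5/15/5 per category per domain). Sizes were chosen to keep
  every stratum at ≥ 5 facilities: the delete-one jackknife of ratio-type
  stratum means is conservative (upward-biased) by O(1/n) in the per-stratum
  unit count, visibly so below ~4 units, which is a property of the method,
  not of its implementation. At the calibration size the jackknife runs a
  few percent conservative, as expected.

## Numerical conventions

- Estimates are proportions internally; reports render integer percentages
  with half-up rounding (`52 pp (55%)`), CSV outputs keep full precision.
- `NOT_COLLECTED` is an empty CSV cell, never 0; an unsure visit count is an
  empty `n_visits` with `any_anc = TRUE`.
- Ties and degenerate inputs: a facility (or observation) with *no*
  collected masked item is an error, not a zero score; an all-zero weight
  total is an error; `relative_change(a, b)` with `a = 0` returns `NA`.
- Estimation is deterministic throughout — randomness exists only in the
  generator, which takes a mandatory seed and restores the global RNG state.

## A worked example

```{r example}
params <- params_small()
bundle <- generate_bundle(params, seed = 42)
bundle

results <- run_cascades(bundle, services = "anc", ks = 1, variance = "full")
results[, c("step", "estimate", "se", "ci_low", "ci_high")]

closed_form_truth(params) |> subset(service == "ANC" & k == 1)
```

The readiness-adjusted estimate sits below contact by the average readiness
of the facilities women actually use; the jackknife SE of the adjusted steps
exceeds the Taylor SE of contact because it also carries the facility
survey's sampling noise.

## Limitations

Ecological linking assigns a stratum average, not the woman's own facility;
with strong preferential care-seeking or high within-stratum variability the
adjusted steps can be biased in real data. Countries whose facility
assessment lacks direct observation of care (no client observations) end
their cascade at intervention coverage. Index content is configuration, not
a standard: estimates are comparable over time within a country far more
safely than across countries.
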