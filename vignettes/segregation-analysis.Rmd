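---
title: "Segregation analysis of a late-onset disease in closed pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segregation analysis of a late-onset disease in closed pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedseg)
```

## The problem

Osteosarcoma is the most common cancer of Scottish Deerhounds: breed-survey
lifetime incidences are about 9% in males and 11% in bitches, with onset
typically between 4 and 12 years of age. Because the disease arrives late in
life, a classical segregation analysis of breeder pedigrees faces a
censoring problem: a young disease-free dog tells you nothing, and a dog
that died at, say, six years of age without a tumor cannot be scored at all.
`pedseg` implements the whole chain of such an analysis — phenotype
assignment under an age cutoff, rule-based single-locus genotype inference,
observed-versus-expected segregation statistics, and a gene-drop simulator
that makes every stage testable without any external data.

## Phenotype assignment and censoring

A dog is **affected** if osteosarcoma was ever diagnosed, **unaffected**
only if it is disease-free *and* at least `cutoff_age` years old (default
8.5 years), and **unevaluable** otherwise. Unevaluable offspring are removed
before analysis (`filter_evaluable()`); unevaluable dogs that are parents
are kept as structural nodes because their litters still carry information.

The cutoff trades sample size against label quality. From the packaged
survey onset table, 67% of eventually affected males and 60% of affected
females are diagnosed by 8.5 years; the complements (33% and 40%) times the
lifetime incidences (9%, 11%) give mislabel probabilities of about 3% and 4%
per unaffected call:

```{r}
tab <- survey_onset_table()
percent(misclassification_prob(tab, "male",   8.5, 0.09))
percent(misclassification_prob(tab, "female", 8.5, 0.11))
```

All onset queries are bin-granular: an age interior to a bin resolves to the
bin's upper edge rather than interpolating, because the survey data are
binned and interpolation would invent precision. Arithmetic is full
precision throughout; `percent()` applies half-away-from-zero rounding at
the display layer only (so 62.5% prints as 63%). Mean onset age is
deliberately *not* computed from the binned table: bin midpoints do not
recover the published sex-specific means (the female mean in particular
lands visibly high), so any such estimate would be spurious.

## Two single-locus hypotheses

The analysis asks, separately for each family, how well the data fit

* a **recessive** risk factor `t` at **full penetrance**: affected ⟺
  genotype `t/t`; and
* a **dominant** risk factor `C` at **high but incomplete penetrance**:
  affected ⟹ at least one `C`, but an unaffected dog may be a silent
  carrier.

Internally genotypes are `risk_hom`, `het`, `norm_hom`, and each dog carries
the *set* of genotypes still possible. Recessive inference
(`infer_recessive()`) initializes sets from phenotype (affected →
`{risk_hom}`, unaffected → `{het, norm_hom}`) and then applies full
Mendelian closure per family to a fixpoint: a parental genotype pair is
feasible only if every pup's current set contains a genotype the pair can
produce, and each dog's set is intersected with what the feasible pairs
allow. This subsumes the classical textbook rules (an unaffected parent of
an affected pup is an obligate carrier; so is an unaffected pup of an
affected parent) and additionally detects hard contradictions such as an
unaffected pup of two affected parents. Because propagation only removes
possibilities, the fixpoint is identical under any processing order — a
property the test suite checks by shuffling input rows.

Contradictions do not abort the run: the offending family is recorded and
frozen (its members' sets are treated as uninformative afterwards) so that a
whole-hypothesis verdict can still be reported. Unaffected dogs whose set
collapses to `{het}` are the **obligate carriers**; a *male* obligate
carrier additionally witnesses that the locus is autosomal, since males are
hemizygous for the X.

Dominant inference is deliberately weaker, because incomplete penetrance
breaks the phenotype-to-genotype link: affected dogs lose `norm_hom`,
unaffected dogs keep all three genotypes, and the only structural deduction
retained is the pair-level flag "this unaffected-by-unaffected litter
produced an affected pup, so at least one parent is a silent carrier". The
disjunction is never resolved to a particular parent, and no
penetrance-based elimination is performed.

Where deduction stops (a parent that died young with informative litters),
`parent_genotype_likelihood_ratio()` compares two candidate genotypes by the
binomial likelihood of the observed affected/unaffected pup split at full
penetrance. These ratios are advisory and are never fed back into
propagation, keeping deduction and plausibility separate.

## Segregation statistics and verdicts

`observed_segregation()` pools affected/unaffected counts over the litters
of a cross class (affected-by-unaffected, unaffected-by-unaffected, ...).
`expected_affected_fraction()` gives the Mendelian expectation for any
parental genotype pair — or mixture; the affected-dam-by-unaffected-sire
expectation under the dominant model uses the sire fixed `norm_hom` (the
overwhelmingly likely genotype for an unaffected dog when carriers are
rare) and the dam an equal mixture of `het` and `risk_hom`, giving 75% at
full penetrance.

No specific significance test is canonical for litter pools this small; the
package adopts the two-sided exact binomial test by the point-probability
method (`stats::binom.test`) at a configurable `alpha`, default 0.05, as
the smallest-assumption formalization of "close to the expected ratio".
Pooling treats pups as independent Bernoulli draws, as classical
segregation analysis implicitly does; a per-litter exact multinomial
variant is out of scope.

`hypothesis_report()` then renders the verdicts:

* **recessive** — pools only the affected-by-unaffected litters whose
  unaffected parent is a *proven* obligate carrier (crosses expected to
  segregate 1-to-1) and rejects when the exact test rejects or when
  propagation found a Mendelian contradiction;
* **dominant** — reports all affected-by-unaffected litters against the
  75% expectation and the 0.5 floor (dam merely heterozygous). Only a
  significant *deficit* below the floor is flagged, and it is labelled
  `low_penetrance_or_alternative` rather than rejected outright, because
  incomplete penetrance can absorb a deficit; the report carries an
  explicit `cannot_rule_out` flag for this hedge.

On the bundled cohorts this yields the two contrasting stories: family K's
carrier crosses segregate 8:10 (`0.8-to-1`, p = 0.81, consistent with
recessive) while family T's segregate 18:5 (p = 0.011, rejected against
1-to-1 but sitting at the 75% dominant expectation). Ratios are displayed
in the field's `x-to-1` form at two significant digits.

## The bundled cohorts

The fixtures encode the evaluable dogs of the two families as recoverable
from their litter summaries: every printed per-litter composition, every
named dog, and the structurally required unevaluable parents. Dogs never
named get role ids (`K2S` = sire of litter K2); their ages are placeholders
consistent with their phenotypes, and no statistic depends on them. Three
reconstruction choices were genuinely open and are documented in
`inst/extdata/README.md`: litter K5's sire is encoded as OAN (the minimal
repeated-sire reading that makes the published litter selection emerge from
inference), VIK is the repeated parent among the five unaffected parents of
litters T1/T2/T8, and litter T4 — whose composition was never published —
carries synthetic pups that belong to no pooled cross class. The original
families also contained young censored dogs that were never enumerated, so
the fixtures are smaller than the raw cohorts were; the censoring
*mechanism* is exercised through the simulator instead.

## What the simulator emulates

`simulate_pedigree()` gene-drops a single autosomal locus through a closed
pedigree: founders at Hardy–Weinberg proportions for the configured risk
allele frequency, random pairing within each generation, one allele from
each parent per pup. Disease strikes at-risk genotypes with probability
`penetrance` and others with `baseline_risk`; diseased dogs draw an onset
age (by default from the packaged survey table, uniform within the
diagnosed bin and one year wide above the last edge) and every dog draws a
lifespan; a dog is diagnosed only if onset precedes death.
`censor_to_observed()` then strips the truth columns, reproducing exactly
the observable CSV fields — and with them the late-onset mislabeling
mechanism, since an at-risk dog that dies before onset but after the cutoff
is labeled unaffected.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `risk_allele_freq` | 0.3 | enriched-family frequency; under recessive expression ~9% of founders are at risk, matching breed-level incidence, while the pedigree concentrates risk further |
| `penetrance` | 1 | the recessive analysis premise; lower values model the dominant hedge |
| `baseline_risk` | 0.05 | the background risk of a dog without the factor |
| `n_founders`, `n_generations`, `n_matings`, `litter_size_mean` | 10, 3, 4, 6 | cohort-scale output: ~80 dogs, ~50–70 evaluable, litter sizes 1 + Poisson(5) (no published litter-size distribution exists; this is a stand-in) |
| `lifespan_mean`, `lifespan_sd`, `lifespan_min` | 9.5, 1.8, 1 (normal, floored) | calibrated so evaluability loss at the 8.5-year cutoff is of the same order as real late-onset cohorts lose; a calibration choice, not a measured value |

The simulator does **not** attempt the real families' breeding structure:
no inbreeding-targeted mate choice, no two-locus modifier, no attempt to
match real kinship. Passing tests therefore demonstrate correctness of the
*method* under the stated single-locus model, not that real Deerhound data
satisfy that model.

## The mode-recovery experiment

`mode_recovery_experiment()` closes the loop: simulate under a known mode,
censor, run the full pipeline, and record how often the recessive
hypothesis is rejected. Under recessive truth the rejection rate sits
modestly above `alpha` (phenocopies at `baseline_risk` and censoring
occasionally fabricate contradictions); under dominant truth it is several
times higher, driven mostly by affected-by-affected matings that produce
unaffected pups — impossible under recessive expression at full penetrance.
`analysis/05_mode_recovery.R` runs this at 40 replicates per mode with a
fixed seed and writes the rates with binomial confidence bounds;
the acceptance suite re-runs it and asserts the separation. The replicate
counts (40 for the experiment, 1000 small pedigrees for the soundness
property, a 65-run pool for the Mendelian-ratio check) were chosen to give
stable assertions at comfortable desk-scale runtimes.

## Numerical and edge-case choices

* Display rounding is half-away-from-zero to whole percent, applied only at
  the display layer; JSON reports carry full precision.
* The exact binomial test inherits `binom.test`'s relative tolerance
  (1 + 1e-7) for ties in the point-probability comparison; the test suite
  verifies equality against an independent pmf summation for every
  `n ≤ 25` and expectation in {0.25, 0.5, 0.75}.
* An empty genotype set marks a contradiction; the family is frozen rather
  than cascading empties through the pedigree.
* Empty pedigrees, classes with no litters, and parents with no scored pups
  all yield `not_applicable`/`NA` results rather than errors.
* LINKAGE PED export drops ages by design (the format cannot carry
  censoring); on import, declared-unaffected dogs are assigned the cutoff
  age so their declared phenotype survives, and affection-0 dogs stay
  unevaluable.
* A bred generation that comes out single-sex ends breeding early; only a
  founder set with no opposite-sex pair is an error.

## Known limitations

* No ascertainment correction: litters entered the data because families
  with affected dogs were studied, and the expected ratios are not adjusted
  for that (the observed-versus-expected comparisons inherit this bias from
  the study design).
* Pooling across litters ignores litter-level random effects.
* The dominant model is tested only against its floor and its mixture
  expectation; no likelihood model of partial penetrance is fit.
* X-linkage is assessed only through the male-obligate-carrier witness, not
  through a transmission model.
* Kinship and inbreeding coefficients are out of scope.
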