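# pedseg

Classical pedigree segregation analysis for a late-onset Mendelian disease,
built around osteosarcoma in Scottish Deerhounds — a breed in which bone
cancer is the leading neoplasm (lifetime incidence ≈ 9% in males, 11% in
bitches) and arrives so late (median onset 7–8 years) that scoring a dog
"unaffected" is itself a statistical decision.

The package is for geneticists and breed-health researchers doing
mode-of-inheritance work on breeder-supplied pedigrees. It implements:

* **Censoring-aware phenotyping.** A dog is affected if ever diagnosed,
  unaffected only if disease-free at or past a cutoff age *c* (default
  8.5 y), else unevaluable. The mislabel risk of an unaffected call is
  `P(onset > c | affected) × P(affected)` — about 3% (males) and 4%
  (bitches) at the defaults, computed from a bundled survey onset table.
* **Set-valued genotype inference.** Under a recessive hypothesis at full
  penetrance each dog carries a subset of {t/t, T/t, T/T}; constraint
  propagation with full Mendelian closure shrinks the sets to a fixpoint,
  yields obligate carriers (unaffected dogs pinned to T/t), witnesses for
  autosomal inheritance (male obligate carriers), and records hard
  contradictions. A dominant hypothesis with incomplete penetrance pins far
  less and instead flags parent pairs that must contain a silent carrier.
* **Segregation statistics.** Observed affected:unaffected pools per cross
  class against Mendelian expectations (affected × carrier → 1:1 under
  recessive; affected dam × unaffected sire → 75% affected under dominant
  with the dam equally C/c or C/C), tested with the two-sided exact
  binomial test (point-probability method) at α = 0.05.
* **A gene-drop simulator** (founders at Hardy–Weinberg, configurable mode,
  penetrance, allele frequency, onset and lifespan censoring) plus a
  mode-recovery experiment that checks the pipeline can tell the two modes
  apart at cohort scale.

Two reconstructed example families ship as plain-text fixtures: cohort K
(12 litters) and cohort T (8 litters).

## Worked example

```r
library(pedseg)

rep_t <- run_cohort_analysis(cohort_pedigree("T"))
rep_t
#> <cohort_report> 62 dogs (61 evaluable), 8 litters; cutoff 8.5 y
#>   risk given an affected parent: 78%
#> <hypothesis_report> alpha = 0.05
#>   recessive: 18 affected / 5 unaffected in carrier crosses (3.6-to-1), p = 0.0106 -> inconsistent
#>   dominant: 18 affected / 5 unaffected in AFFxUNAFF crosses (3.6-to-1), expected 75%, -> consistent

writeLines(render_tables(rep_t, "AFFxUNAFF"))
#> Litter    Affected  Unaffected Affected% Unaffected%
#> T3               7           2       78%         22%
#> T6               7           3       70%         30%
#> T7               4           0      100%          0%
#> Totals          18           5       78%         22%
```

Reading: in family T, a pup with an affected parent has a 78% risk of
osteosarcoma. The affected-by-carrier litters segregate 18:5 — the exact
test rejects the 1:1 ratio a recessive factor predicts (p ≈ 0.011), but
the pool sits at the 75% a highly penetrant dominant factor predicts.
Family K gives the mirror image: its carrier crosses segregate 8:10
(`0.8-to-1`, p ≈ 0.81), consistent with a recessive factor, with the
dominant reading not excludable (`cannot_rule_out` flag). The inference
result also names the deduced carriers, e.g. the five unaffected parents
of litters T1/T2/T8 — including the males ABE and VIK, which places the
locus on an autosome.

The numbered scripts under `analysis/` run the full story — cohort loading,
censoring arithmetic, inference, segregation verdicts, and the simulation
power check — and write their tables under `results/`:

```sh
Rscript analysis/01_cohorts.R
Rscript analysis/02_onset_censoring.R
Rscript analysis/03_inference.R
Rscript analysis/04_segregation.R
Rscript analysis/05_mode_recovery.R
```

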