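# Bundled fixtures

## cohort_K.csv / cohort_T.csv

Two Scottish Deerhound family cohorts ("K" and "T") segregating
osteosarcoma, encoded in the package CSV dialect. They record the evaluable
dogs and parental structure recoverable from the cohorts' litter summaries
and named-dog accounts; they are reconstructions, not raw breeder exports,
and carry these synthetic elements:

* Dogs never identified by name have role ids built from litter and role:
  `K2S` = sire of litter K2, `K2D` = its dam, `T5S`/`T5D` = the unaffected
  parents of litter T5, and pups are numbered `K3M1` (male) / `K3F2`
  (female) within each litter. Named dogs keep their codes (three letters =
  male, four letters = female).
* Ages are only known for the named dogs (e.g. TAL 10 y, LANG 12 y, SON and
  AMP 6 y, KELL and MYCK 9.5 y, PEN 12 y, LIUM 10 y, SPIG 13 y). All other
  ages are synthetic placeholders chosen to be consistent with the recorded
  phenotype: affected dogs get onset-plausible ages, unaffected dogs ages at
  or above the 8.5-year cutoff. No analysis in the package depends on the
  placeholder values, only on the phenotype they imply.
* The original cohorts also contained dogs that died osteosarcoma-free
  before the cutoff age; apart from the structurally required parents SON,
  AMP and the dam of litter T4, those unevaluable dogs were never
  enumerated and are not encoded, so the fixtures are smaller than the raw
  cohorts were.
* Litter K5's sire was reported only as an already-deduced carrier; he is
  encoded as OAN (also sire of K4), the minimal repeated-sire reading.
* Litter T4's composition was never published beyond its sire RIF; its
  three pups here are synthetic and belong to no pooled cross class used by
  any statistic.
* Two additional unaffected pups of PEN were mentioned but never
  identified; they are omitted.
* Five unaffected dogs (ABE, LAVE, COCA, VIK, DENA) parent the three
  litters T1/T2/T8, so one of them parents two litters; which one was never
  stated, and VIK is encoded as the repeated parent (T2 and T8).

## onset_survey_2011.csv

Age-at-diagnosis counts by sex from a 2011 breed health survey of 588
Scottish Deerhounds (24 affected males of 273; 35 affected females of 315),
in half-open one-year bins; the last bin is open-ended above 11.5 years.
Load with `survey_onset_table()`.
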