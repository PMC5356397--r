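#' Bundled example cohorts
#'
#' Two Scottish Deerhound family cohorts segregating osteosarcoma, "K" and
#' "T", as pedigree fixtures. They encode the evaluable dogs and litter
#' structure recoverable from the cohorts' litter summaries; dogs never
#' identified by name carry synthetic role ids (e.g. `K2S`, sire of litter
#' K2) and synthetic ages consistent with their recorded phenotypes. See the
#' fixture notes in `system.file("extdata", "README.md", package =
#' "pedseg")` for every reconstruction choice.
#'
#' @param cohort `"K"` or `"T"`.
#' @param cutoff_age cutoff age for the returned pedigree (default 8.5).
#' @return a [pedigree()].
#' @examples
#' ped <- cohort_pedigree("K")
#' summary(ped)
#' @export
cohort_pedigree <- function(cohort = c("K", "T"), cutoff_age = 8.5) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", paste0("cohort_", cohort, ".csv"),
                      package = "pedseg", mustWork = TRUE)
  read_pedigree(path, format = "csv", cutoff_age = cutoff_age)
}

#' Breed-survey age-of-onset table
#'
#' Age-at-diagnosis counts by sex from a 2011 health survey of 588 Scottish
#' Deerhounds (24 affected males, 35 affected females), in half-open
#' one-year bins from 3.5 years with an open-ended bin above 11.5 years.
#'
#' @return an [onset_table()].
#' @examples
#' tab <- survey_onset_table()
#' percent(cumulative_onset_fraction(tab, "male", 8.5))  # 67
#' @export
survey_onset_table <- function() {
  path <- system.file("extdata", "onset_survey_2011.csv",
                      package = "pedseg", mustWork = TRUE)
  read_onset_table(path)
}
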