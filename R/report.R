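#' End-to-end cohort analysis
#'
#' Strings the pipeline together for one cohort: phenotype assignment under
#' the cutoff, evaluability filtering, cross classification, genotype
#' inference and segregation verdicts under both hypotheses, the conditional
#' offspring risk, and the censoring-induced misclassification probabilities
#' from the onset table. All numbers in the report are full precision;
#' [render_tables()] applies the whole-percent display convention.
#'
#' @param ped a [pedigree()] or a path readable by [read_pedigree()].
#' @param onset an [onset_table()] for the misclassification arithmetic.
#' @param cutoff_age cutoff age in years (default 8.5).
#' @param alpha test size for verdicts (default 0.05).
#' @param incidence named lifetime incidences by sex (defaults
#'   `c(male = 0.09, female = 0.11)`).
#' @return object of class `cohort_report`; serialize with
#'   [write_cohort_report()].
#' @export
run_cohort_analysis <- function(ped, onset = survey_onset_table(),
                                cutoff_age = 8.5, alpha = 0.05,
                                incidence = c(male = 0.09, female = 0.11)) {
  if (is.character(ped)) ped <- read_pedigree(ped, cutoff_age = cutoff_age)
  stopifnot(inherits(ped, "pedigree"))
  ped$cutoff_age <- cutoff_age
  phen_full <- assign_phenotypes(ped, cutoff = cutoff_age)
  evaluable <- filter_evaluable(ped, phen_full)
  phen <- assign_phenotypes(evaluable, cutoff = cutoff_age)
  classes <- classify_crosses(evaluable, phen)
  report <- hypothesis_report(evaluable, phen, alpha = alpha)

  misclass <- vapply(names(incidence), function(sx) {
    if (!sx %in% names(onset$counts_by_sex)) return(NA_real_)
    misclassification_prob(onset, sx, cutoff_age, incidence[[sx]])
  }, numeric(1))

  seg <- lapply(stats::setNames(nm = c("AFFxAFF", "AFFxUNAFF", "UNAFFxUNAFF",
                                       "PARENT_UNKNOWN")),
                function(cl) observed_segregation(evaluable, phen, cl))

  structure(list(
    cutoff_age = cutoff_age,
    alpha = alpha,
    evaluability = list(
      n_total = nrow(ped$dogs),
      n_evaluable = sum(phen_full != "unevaluable"),
      n_retained = nrow(evaluable$dogs),
      n_litters = nrow(litters(evaluable))
    ),
    phenotypes = phen,
    cross_classes = classes,
    segregation = seg,
    conditional_risk = conditional_offspring_risk(evaluable, phen),
    misclassification = misclass,
    hypothesis = report
  ), class = "cohort_report")
}

#' Serialize a cohort report to JSON
#'
#' Full precision, schema-stable (no timestamps), so identical inputs give
#' byte-identical files.
#'
#' @param report a [run_cohort_analysis()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  hy <- report$hypothesis
  json <- list(
    cutoff_age = report$cutoff_age,
    alpha = report$alpha,
    evaluability = report$evaluability,
    phenotypes = as.list(report$phenotypes),
    cross_classes = as.list(report$cross_classes),
    conditional_risk = report$conditional_risk,
    misclassification = as.list(report$misclassification),
    recessive = list(
      obligate_carriers = hy$recessive$inference$obligate_carriers,
      autosomal_consistent = hy$recessive$inference$autosomal_consistent,
      witnesses = hy$recessive$inference$witnesses,
      carrier_cross_litters = hy$recessive$carrier_cross_litters,
      affected = hy$recessive$counts$affected,
      unaffected = hy$recessive$counts$unaffected,
      expected_fraction = hy$recessive$expected_fraction,
      p_value = hy$recessive$p_value,
      ratio = hy$recessive$ratio,
      n_contradictions = hy$recessive$n_contradictions,
      verdict = hy$recessive$verdict
    ),
    dominant = list(
      flagged_litters = hy$dominant$inference$silent_carrier_flags$litter_id,
      affected = hy$dominant$counts$affected,
      unaffected = hy$dominant$counts$unaffected,
      expected_fraction = hy$dominant$expected_fraction,
      floor_fraction = hy$dominant$floor_fraction,
      p_value_floor = hy$dominant$p_value_floor,
      ratio = hy$dominant$ratio,
      flagged_ratio = hy$dominant$flagged_ratio,
      verdict = hy$dominant$verdict,
      cannot_rule_out = hy$dominant$cannot_rule_out
    )
  )
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Render litter tables in the survey display convention
#'
#' Per-litter affected/unaffected counts with relative phenotypes as whole
#' percents (half-away-from-zero), plus a totals row, for one cross class.
#'
#' @param report a [run_cohort_analysis()] result.
#' @param cross_class which class to render (default `"AFFxUNAFF"`).
#' @return character vector of text lines (header only when the class is
#'   empty); printed with a trailing newline per line by [writeLines()].
#' @export
render_tables <- function(report, cross_class = "AFFxUNAFF") {
  stopifnot(inherits(report, "cohort_report"))
  counts <- report$segregation[[cross_class]]
  per <- counts$per_litter
  fmt <- "%-8s %9s %11s %9s %11s"
  lines <- sprintf(fmt, "Litter", "Affected", "Unaffected",
                   "Affected%", "Unaffected%")
  row_line <- function(label, a, u) {
    n <- a + u
    pa <- if (n == 0) "-" else paste0(percent(a / n), "%")
    pu <- if (n == 0) "-" else paste0(percent(u / n), "%")
    sprintf(fmt, label, a, u, pa, pu)
  }
  for (i in seq_len(nrow(per))) {
    lines <- c(lines, row_line(per$litter_id[i], per$affected[i],
                               per$unaffected[i]))
  }
  if (nrow(per) > 0L) {
    lines <- c(lines, row_line("Totals", counts$affected, counts$unaffected))
  }
  lines
}

#' @export
print.cohort_report <- function(x, ...) {
  ev <- x$evaluability
  cat(sprintf("<cohort_report> %d dogs (%d evaluable), %d litters; cutoff %.1f y\n",
              ev$n_total, ev$n_evaluable, ev$n_litters, x$cutoff_age))
  cr <- x$conditional_risk
  cat(sprintf("  risk given an affected parent: %s\n",
              if (is.na(cr)) "n/a" else paste0(percent(cr), "%")))
  print(x$hypothesis)
  invisible(x)
}
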