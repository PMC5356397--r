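#' Observed segregation counts for a cross class
#'
#' Counts evaluable affected and unaffected pups, per litter and pooled, over
#' all litters whose parental phenotypes match the requested class.
#'
#' @param ped a [pedigree()].
#' @param phenotypes output of [assign_phenotypes()].
#' @param cross_class one of `"AFFxAFF"`, `"AFFxUNAFF"`, `"UNAFFxUNAFF"`,
#'   `"PARENT_UNKNOWN"`.
#' @param litter_ids optional subset of litters to count (intersected with
#'   the class).
#' @return object of class `cross_counts`: list with `cross_class`,
#'   `per_litter` (data.frame `litter_id`, `affected`, `unaffected`) and
#'   pooled `affected`, `unaffected`. A class with no litters yields counts
#'   (0, 0).
#' @export
observed_segregation <- function(ped, phenotypes = assign_phenotypes(ped),
                                 cross_class, litter_ids = NULL) {
  stopifnot(inherits(ped, "pedigree"),
            cross_class %in% c("AFFxAFF", "AFFxUNAFF", "UNAFFxUNAFF",
                               "PARENT_UNKNOWN"))
  lit <- litters(ped)
  classes <- classify_crosses(ped, phenotypes)
  pick <- lit$litter_id[classes[lit$litter_id] == cross_class]
  if (!is.null(litter_ids)) pick <- intersect(pick, litter_ids)
  per <- data.frame(litter_id = pick,
                    affected = integer(length(pick)),
                    unaffected = integer(length(pick)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(pick)) {
    pups <- lit$pups[[which(lit$litter_id == pick[i])]]
    pp <- phenotypes[pups]
    per$affected[i] <- sum(pp == "affected")
    per$unaffected[i] <- sum(pp == "unaffected")
  }
  structure(list(cross_class = cross_class, per_litter = per,
                 affected = sum(per$affected),
                 unaffected = sum(per$unaffected)),
            class = "cross_counts")
}

#' Expected affected-pup fraction for a cross
#'
#' Mendelian affected-offspring probability for a parental pair, times
#' penetrance, averaged over mixture weights when a parent's genotype is
#' uncertain. Genotypes are `"risk_hom"`, `"het"`, `"norm_hom"`; a mixture is
#' a named numeric vector of weights summing to 1 (e.g. an affected dam under
#' the dominant model equally likely heterozygous or homozygous:
#' `c(het = 0.5, risk_hom = 0.5)`).
#'
#' @param mode `"recessive"` or `"dominant"`.
#' @param sire_genotype,dam_genotype single genotype name or named weight
#'   vector.
#' @param penetrance probability that an at-risk genotype expresses disease,
#'   in `[0, 1]`; default 1.
#' @return fraction in `[0, 1]`.
#' @export
expected_affected_fraction <- function(mode = c("recessive", "dominant"),
                                       sire_genotype, dam_genotype,
                                       penetrance = 1) {
  mode <- match.arg(mode)
  stopifnot(penetrance >= 0, penetrance <= 1)
  as_mixture <- function(g) {
    if (is.character(g)) {
      stopifnot(length(g) == 1L, g %in% .GENOTYPES)
      return(stats::setNames(1, g))
    }
    stopifnot(is.numeric(g), !is.null(names(g)), all(names(g) %in% .GENOTYPES),
              abs(sum(g) - 1) < 1e-8)
    g
  }
  ms <- as_mixture(sire_genotype)
  md <- as_mixture(dam_genotype)
  total <- 0
  for (gs in names(ms)) {
    for (gd in names(md)) {
      total <- total + ms[[gs]] * md[[gd]] *
        .affected_prob(mode, gs, gd, penetrance)
    }
  }
  total
}

#' Two-sided exact binomial segregation test
#'
#' Point-probability method: the p-value is the sum of probabilities of all
#' outcomes no more probable than the observed affected count, under the
#' hypothesized affected fraction. This is the smallest-assumption
#' formalization of judging whether a litter pool is "close to" its expected
#' Mendelian ratio on counts this small.
#'
#' @param counts a `cross_counts` object, or a numeric vector
#'   `c(affected, unaffected)`.
#' @param expected_fraction hypothesized affected fraction in (0, 1).
#' @return two-sided p-value, or `NA_real_` when no pups were counted.
#' @export
binomial_segregation_test <- function(counts, expected_fraction) {
  stopifnot(expected_fraction > 0, expected_fraction < 1)
  if (inherits(counts, "cross_counts")) {
    k <- counts$affected
    n <- counts$affected + counts$unaffected
  } else {
    stopifnot(is.numeric(counts), length(counts) == 2L, all(counts >= 0))
    k <- counts[[1L]]
    n <- sum(counts)
  }
  if (n == 0) return(NA_real_)
  stats::binom.test(k, n, p = expected_fraction)$p.value
}

#' Offspring risk conditional on having an affected parent
#'
#' Fraction affected among evaluable pups with at least one affected parent.
#'
#' @inheritParams observed_segregation
#' @return fraction, or `NA_real_` if no qualifying pups exist.
#' @export
conditional_offspring_risk <- function(ped,
                                       phenotypes = assign_phenotypes(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  dogs <- ped$dogs
  parent_aff <- function(id) !is.na(id) && phenotypes[[id]] == "affected"
  has_aff_parent <- vapply(seq_len(nrow(dogs)), function(i) {
    parent_aff(dogs$sire[i]) || parent_aff(dogs$dam[i])
  }, logical(1))
  pp <- phenotypes[dogs$id[has_aff_parent]]
  k <- sum(pp == "affected")
  u <- sum(pp == "unaffected")
  if (k + u == 0) return(NA_real_)
  k / (k + u)
}

#' Display a segregation ratio in "x-to-1" form
#'
#' @param affected,unaffected pooled counts.
#' @param digits significant digits (default 2, the convention for quoting
#'   ratios like 0.62-to-1).
#' @return character scalar, e.g. `"0.8-to-1"`; `NA` when `unaffected` is 0.
#' @export
ratio_to_one <- function(affected, unaffected, digits = 2) {
  if (unaffected == 0) return(NA_character_)
  paste0(format(signif(affected / unaffected, digits)), "-to-1")
}

# expected fraction for an affected-dam x unaffected-sire cross under the
# dominant model: sire homozygous normal (the high-likelihood case), dam
# equally likely het or risk-homozygous
.dominant_affdam_expectation <- function(dam_mixture = c(het = 0.5,
                                                         risk_hom = 0.5),
                                         penetrance = 1) {
  expected_affected_fraction("dominant", "norm_hom", dam_mixture, penetrance)
}

#' Cohort-level mode-of-inheritance report
#'
#' Runs genotype inference under both hypotheses and confronts each with the
#' segregation counts it predicts:
#'
#' * Recessive: pools the affected-by-unaffected litters whose unaffected
#'   parent is an inferred obligate carrier (the cross predicted to segregate
#'   1-to-1) and tests the pooled counts against an expected affected
#'   fraction of 0.5. The verdict is `"inconsistent"` when propagation hit a
#'   Mendelian contradiction or the exact test rejects at `alpha`;
#'   `"not_applicable"` when no informative cross exists.
#' * Dominant: pools all affected-by-unaffected litters and reports them
#'   against the high-likelihood expectation (sire homozygous normal, dam
#'   equally het or risk-homozygous: 75% affected at full penetrance) and
#'   against the 0.5 floor (the lowest expected ratio, dam heterozygous). A
#'   significant deficit of affected pups below the floor is reported as
#'   `"low_penetrance_or_alternative"` rather than a hard rejection, because
#'   incomplete penetrance can absorb it; `cannot_rule_out` is then `TRUE`.
#'   Unaffected-by-unaffected litters containing affected pups are summarized
#'   with their silent-carrier flags.
#'
#' Pooling treats pups as independent Bernoulli draws, as classical
#' segregation analysis does.
#'
#' @inheritParams observed_segregation
#' @param alpha test size for the verdicts (default 0.05).
#' @return object of class `hypothesis_report`.
#' @export
hypothesis_report <- function(ped, phenotypes = assign_phenotypes(ped),
                              alpha = 0.05) {
  stopifnot(inherits(ped, "pedigree"), alpha > 0, alpha < 1)
  lit <- litters(ped)
  classes <- classify_crosses(ped, phenotypes)

  rec <- infer_recessive(ped, phenotypes)
  dom <- infer_dominant(ped, phenotypes)

  # recessive: affected x obligate-carrier litters
  carrier_litters <- character(0)
  if (nrow(lit) > 0L) {
    for (i in seq_len(nrow(lit))) {
      l <- lit$litter_id[i]
      if (classes[[l]] != "AFFxUNAFF") next
      parents <- c(lit$sire[i], lit$dam[i])
      unaff_parent <- parents[!is.na(parents) &
                                phenotypes[parents] == "unaffected"]
      if (length(unaff_parent) == 1L &&
          unaff_parent %in% rec$obligate_carriers) {
        carrier_litters <- c(carrier_litters, l)
      }
    }
  }
  rec_counts <- observed_segregation(ped, phenotypes, "AFFxUNAFF",
                                     litter_ids = carrier_litters)
  rec_n <- rec_counts$affected + rec_counts$unaffected
  rec_p <- binomial_segregation_test(rec_counts, 0.5)
  rec_verdict <- if (length(rec$contradictions) > 0L) {
    "inconsistent"
  } else if (rec_n == 0L) {
    "not_applicable"
  } else if (rec_p < alpha) {
    "inconsistent"
  } else {
    "consistent"
  }

  # dominant: all affected x unaffected litters vs the D6 expectation
  dom_counts <- observed_segregation(ped, phenotypes, "AFFxUNAFF")
  dom_n <- dom_counts$affected + dom_counts$unaffected
  dom_expect <- .dominant_affdam_expectation()
  dom_floor <- 0.5
  dom_p_floor <- binomial_segregation_test(dom_counts, dom_floor)
  dom_deficit <- dom_n > 0L &&
    dom_counts$affected / dom_n < dom_floor &&
    !is.na(dom_p_floor) && dom_p_floor < alpha
  dom_verdict <- if (dom_n == 0L) {
    "not_applicable"
  } else if (dom_deficit) {
    "low_penetrance_or_alternative"
  } else {
    "consistent"
  }

  uu_counts <- observed_segregation(ped, phenotypes, "UNAFFxUNAFF",
                                    litter_ids = dom$silent_carrier_flags$litter_id)

  structure(list(
    alpha = alpha,
    recessive = list(
      inference = rec,
      carrier_cross_litters = carrier_litters,
      counts = rec_counts,
      expected_fraction = 0.5,
      p_value = rec_p,
      ratio = ratio_to_one(rec_counts$affected, rec_counts$unaffected),
      verdict = rec_verdict,
      n_contradictions = length(rec$contradictions)
    ),
    dominant = list(
      inference = dom,
      counts = dom_counts,
      expected_fraction = dom_expect,
      floor_fraction = dom_floor,
      p_value_floor = dom_p_floor,
      ratio = ratio_to_one(dom_counts$affected, dom_counts$unaffected),
      flagged_unaff_counts = uu_counts,
      flagged_ratio = ratio_to_one(uu_counts$affected, uu_counts$unaffected),
      verdict = dom_verdict,
      cannot_rule_out = dom_verdict != "not_applicable"
    )
  ), class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat(sprintf("<hypothesis_report> alpha = %g\n", x$alpha))
  r <- x$recessive
  cat(sprintf("  recessive: %d affected / %d unaffected in carrier crosses (%s), p = %s -> %s\n",
              r$counts$affected, r$counts$unaffected,
              ifelse(is.na(r$ratio), "-", r$ratio),
              format(signif(r$p_value, 3)), r$verdict))
  if (r$n_contradictions > 0L) {
    cat(sprintf("    %d Mendelian contradiction(s)\n", r$n_contradictions))
  }
  d <- x$dominant
  cat(sprintf("  dominant: %d affected / %d unaffected in AFFxUNAFF crosses (%s), expected %.0f%%, -> %s\n",
              d$counts$affected, d$counts$unaffected,
              ifelse(is.na(d$ratio), "-", d$ratio),
              100 * d$expected_fraction, d$verdict))
  invisible(x)
}
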