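#' Assign phenotypes under an age cutoff
#'
#' A late-onset disease forces a censoring rule: a diagnosed dog is affected
#' at any age, an undiagnosed dog is unaffected only once it has reached the
#' cutoff age without disease, and an undiagnosed dog younger than the cutoff
#' (or of unknown age) cannot be scored and is unevaluable. The default
#' cutoff of 8.5 years is the pedigree's `cutoff_age`.
#'
#' @param ped a [pedigree()].
#' @param cutoff cutoff age in years (> 0); defaults to `ped$cutoff_age`.
#' @param strict if `TRUE`, only deceased dogs can be called unaffected;
#'   living dogs at or past the cutoff remain unevaluable. Default `FALSE`:
#'   a living dog past the cutoff counts as unaffected.
#' @return named character vector over all dog ids with values `"affected"`,
#'   `"unaffected"` or `"unevaluable"`.
#' @export
assign_phenotypes <- function(ped, cutoff = ped$cutoff_age, strict = FALSE) {
  stopifnot(inherits(ped, "pedigree"), is.numeric(cutoff), cutoff > 0)
  dogs <- ped$dogs
  old_enough <- !is.na(dogs$age_years) & dogs$age_years >= cutoff
  if (strict) old_enough <- old_enough & !dogs$alive
  phen <- ifelse(dogs$diagnosed, "affected",
                 ifelse(old_enough, "unaffected", "unevaluable"))
  stats::setNames(phen, dogs$id)
}

#' Drop unevaluable offspring, keep structural parents
#'
#' Unevaluable dogs contribute no phenotype information as offspring and are
#' removed from their litters; litters left without evaluable pups are
#' dropped. An unevaluable dog that is itself a parent is retained as a
#' structural node with unknown phenotype (it anchors its litters), but loses
#' its own litter membership. The operation is idempotent.
#'
#' @param ped a [pedigree()].
#' @param phenotypes output of [assign_phenotypes()] covering every dog;
#'   recomputed at `ped$cutoff_age` if omitted.
#' @return a reduced [pedigree()].
#' @export
filter_evaluable <- function(ped, phenotypes = assign_phenotypes(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  dogs <- ped$dogs
  if (!all(dogs$id %in% names(phenotypes))) {
    stop("phenotypes must cover every dog in the pedigree")
  }
  phen <- phenotypes[dogs$id]
  is_parent <- dogs$id %in% c(dogs$sire, dogs$dam)
  uneval <- phen == "unevaluable"
  keep <- !uneval | is_parent
  dogs <- dogs[keep, , drop = FALSE]
  # a retained unevaluable parent is a structural node, not an offspring
  dogs$litter_id[phen[keep] == "unevaluable"] <- NA_character_
  # parents of dropped-only litters may now dangle; pedigree() re-validates
  rownames(dogs) <- NULL
  pedigree(dogs, cutoff_age = ped$cutoff_age)
}

#' Classify litters by parental phenotype
#'
#' @param ped a [pedigree()].
#' @param phenotypes output of [assign_phenotypes()].
#' @return named character vector over litter ids with values `"AFFxAFF"`,
#'   `"AFFxUNAFF"`, `"UNAFFxUNAFF"` or `"PARENT_UNKNOWN"` (any unevaluable or
#'   unrecorded parent). The class depends only on the two parental
#'   phenotypes, never on the pups.
#' @export
classify_crosses <- function(ped, phenotypes = assign_phenotypes(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  lit <- litters(ped)
  if (nrow(lit) == 0L) return(stats::setNames(character(0), character(0)))
  cls <- function(sire, dam) {
    ps <- if (is.na(sire)) "unevaluable" else phenotypes[[sire]]
    pd <- if (is.na(dam)) "unevaluable" else phenotypes[[dam]]
    if (ps == "unevaluable" || pd == "unevaluable") return("PARENT_UNKNOWN")
    n_aff <- (ps == "affected") + (pd == "affected")
    c("UNAFFxUNAFF", "AFFxUNAFF", "AFFxAFF")[n_aff + 1L]
  }
  stats::setNames(mapply(cls, lit$sire, lit$dam), lit$litter_id)
}
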