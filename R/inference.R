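# Single-locus genotypes are set-valued: each dog carries the subset of
# {risk_hom, het, norm_hom} still possible under a hypothesis. Propagation
# only ever removes possibilities, so the fixpoint is order-independent.

.GENOTYPES <- c("risk_hom", "het", "norm_hom")

# P(transmit the risk allele) per genotype
.risk_transmission <- c(risk_hom = 1, het = 0.5, norm_hom = 0)

# Offspring genotype distribution for a pure parental pair.
.offspring_dist <- function(sire_geno, dam_geno) {
  ps <- .risk_transmission[[sire_geno]]
  pd <- .risk_transmission[[dam_geno]]
  c(risk_hom = ps * pd,
    het = ps * (1 - pd) + (1 - ps) * pd,
    norm_hom = (1 - ps) * (1 - pd))
}

.offspring_support <- function(sire_geno, dam_geno) {
  d <- .offspring_dist(sire_geno, dam_geno)
  names(d)[d > 0]
}

# Probability that a pup of a pure parental pair is affected, given the mode
# and penetrance (phenocopies excluded: this is the Mendelian expectation).
.affected_prob <- function(mode, sire_geno, dam_geno, penetrance = 1) {
  d <- .offspring_dist(sire_geno, dam_geno)
  at_risk <- if (mode == "recessive") c("risk_hom") else c("risk_hom", "het")
  sum(d[at_risk]) * penetrance
}

.initial_sets <- function(ids, phen, mode) {
  sets <- lapply(phen[ids], function(p) {
    if (mode == "recessive") {
      switch(p,
             affected = "risk_hom",
             unaffected = c("het", "norm_hom"),
             .GENOTYPES)
    } else {
      switch(p,
             affected = c("risk_hom", "het"),
             .GENOTYPES)
    }
  })
  stats::setNames(sets, ids)
}

# Family groups: one per (sire, dam) pair over dogs with a known parent.
# Litter identity is irrelevant to Mendelian constraints, so repeat litters
# of the same pair are pooled.
.family_groups <- function(dogs) {
  has_parent <- !is.na(dogs$sire) | !is.na(dogs$dam)
  kids <- dogs[has_parent, , drop = FALSE]
  if (nrow(kids) == 0L) return(list())
  key <- paste(ifelse(is.na(kids$sire), "", kids$sire),
               ifelse(is.na(kids$dam), "", kids$dam), sep = "\r")
  lapply(split(seq_len(nrow(kids)), key), function(i) {
    list(sire = kids$sire[i[1L]], dam = kids$dam[i[1L]], pups = kids$id[i])
  })
}

#' Infer single-locus genotypes under the recessive hypothesis
#'
#' Rule-based constraint propagation at full penetrance: an affected dog is
#' homozygous for the risk allele; an unaffected dog carries at most one
#' copy; and every family must satisfy Mendelian transmission, i.e. for some
#' still-possible pair of parental genotypes every pup's set contains a
#' producible genotype. The Mendelian closure subsumes the classical
#' obligate-carrier rules (an unaffected parent of an affected pup, or an
#' unaffected pup of an affected parent, must be a heterozygous silent
#' carrier) and is applied to a fixpoint, which is identical under any rule
#' application order.
#'
#' A genotype set that empties signals a contradiction with the hypothesis
#' (for example an unaffected pup of two affected parents). Contradictions
#' are recorded, the offending set is left empty and treated as
#' uninformative thereafter, and inference continues so a whole-hypothesis
#' verdict can still be reported.
#'
#' @param ped a [pedigree()].
#' @param phenotypes output of [assign_phenotypes()] covering every dog.
#' @return an object of class `inference_result`: list with `mode`,
#'   `genotypes` (named list of possible-genotype character vectors over
#'   `"risk_hom"`, `"het"`, `"norm_hom"`), `obligate_carriers` (unaffected
#'   dogs whose set collapsed to `"het"`), `silent_carrier_flags` (empty here;
#'   see [infer_dominant()]), `autosomal_consistent`, `witnesses` (male
#'   obligate carriers), and `contradictions` (list of `rule`/`ids` records).
#' @export
infer_recessive <- function(ped, phenotypes = assign_phenotypes(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  dogs <- ped$dogs
  if (!all(dogs$id %in% names(phenotypes))) {
    stop("phenotypes must cover every dog in the pedigree")
  }
  sets <- .initial_sets(dogs$id, phenotypes, "recessive")
  families <- .family_groups(dogs)
  contradictions <- list()
  contradicted <- logical(length(families))  # frozen families
  broken <- character(0)  # members of contradicted families; uninformative

  get_set <- function(id) {
    if (is.na(id) || id %in% broken) .GENOTYPES else sets[[id]]
  }

  repeat {
    changed <- FALSE
    for (fi in seq_along(families)) {
      if (contradicted[fi]) next
      fam <- families[[fi]]
      s_set <- get_set(fam$sire)
      d_set <- get_set(fam$dam)
      pup_sets <- lapply(fam$pups, get_set)
      feas_s <- character(0)
      feas_d <- character(0)
      pup_union <- stats::setNames(vector("list", length(fam$pups)), fam$pups)
      for (gs in s_set) {
        for (gd in d_set) {
          support <- .offspring_support(gs, gd)
          ok <- all(vapply(pup_sets, function(ps) any(ps %in% support),
                           logical(1)))
          if (ok) {
            feas_s <- union(feas_s, gs)
            feas_d <- union(feas_d, gd)
            for (p in fam$pups) pup_union[[p]] <- union(pup_union[[p]], support)
          }
        }
      }
      if (length(feas_s) == 0L) {
        # no parental genotype pair can produce these pups: the hypothesis
        # fails for this family; freeze it and move on
        members <- unique(stats::na.omit(c(fam$sire, fam$dam, fam$pups)))
        contradictions[[length(contradictions) + 1L]] <-
          list(rule = "mendelian", ids = members)
        for (m in intersect(members, fam$pups)) sets[[m]] <- character(0)
        contradicted[fi] <- TRUE
        broken <- union(broken, members)
        changed <- TRUE
        next
      }
      update <- function(id, new_set) {
        if (is.na(id) || id %in% broken) return(invisible(NULL))
        if (length(new_set) < length(sets[[id]])) {
          sets[[id]] <<- new_set
          changed <<- TRUE
        }
      }
      update(fam$sire, intersect(s_set, feas_s))
      update(fam$dam, intersect(d_set, feas_d))
      for (p in fam$pups) {
        update(p, intersect(get_set(p), pup_union[[p]]))
      }
    }
    if (!changed) break
  }

  unaffected <- names(phenotypes)[phenotypes == "unaffected"]
  obligate <- names(sets)[vapply(sets, function(s) identical(s, "het"),
                                 logical(1))]
  obligate <- setdiff(intersect(obligate, unaffected), broken)
  res <- structure(list(
    mode = "recessive",
    genotypes = sets,
    obligate_carriers = obligate,
    silent_carrier_flags = data.frame(litter_id = character(),
                                      sire = character(), dam = character(),
                                      stringsAsFactors = FALSE),
    autosomal_consistent = NA,
    witnesses = character(0),
    contradictions = contradictions
  ), class = "inference_result")
  aut <- check_autosomal_consistency(res, ped)
  res$autosomal_consistent <- aut$consistent
  res$witnesses <- aut$witnesses
  res
}

#' Infer genotype constraints under the dominant hypothesis
#'
#' With dominant expression at high but incomplete penetrance, phenotype pins
#' far less: an affected dog carries at least one risk allele, while an
#' unaffected dog can be any genotype (it may be a silent carrier that failed
#' to express). No penetrance-based elimination is performed. The one
#' structural deduction retained is the silent-carrier flag: a cross between
#' two unaffected dogs that produced an affected pup must have had at least
#' one silent-carrier parent. The disjunction ("one or both") is kept at the
#' pair level, never resolved to a particular parent.
#'
#' @inheritParams infer_recessive
#' @return an `inference_result`; `silent_carrier_flags` is a data.frame with
#'   one row per flagged litter (`litter_id`, `sire`, `dam`). Dominant
#'   premises cannot produce hard contradictions, so `contradictions` is
#'   always empty.
#' @export
infer_dominant <- function(ped, phenotypes = assign_phenotypes(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  dogs <- ped$dogs
  if (!all(dogs$id %in% names(phenotypes))) {
    stop("phenotypes must cover every dog in the pedigree")
  }
  sets <- .initial_sets(dogs$id, phenotypes, "dominant")
  lit <- litters(ped)
  cross <- classify_crosses(ped, phenotypes)
  flagged <- vapply(seq_len(nrow(lit)), function(i) {
    l <- lit$litter_id[i]
    if (cross[[l]] != "UNAFFxUNAFF") return(FALSE)
    any(phenotypes[lit$pups[[i]]] == "affected")
  }, logical(1))
  flags <- data.frame(litter_id = lit$litter_id[flagged],
                      sire = lit$sire[flagged], dam = lit$dam[flagged],
                      stringsAsFactors = FALSE)
  structure(list(
    mode = "dominant",
    genotypes = sets,
    obligate_carriers = character(0),
    silent_carrier_flags = flags,
    autosomal_consistent = NA,
    witnesses = character(0),
    contradictions = list()
  ), class = "inference_result")
}

#' Autosomal-versus-X-linkage witness test
#'
#' A recessive X-linked risk factor admits no male heterozygous carriers
#' (males are hemizygous), so the existence of even one male obligate carrier
#' places the locus on an autosome.
#'
#' @param result an `inference_result` from [infer_recessive()].
#' @param ped the pedigree it was computed on.
#' @return list with `consistent` (TRUE iff a male obligate carrier exists)
#'   and `witnesses` (ids of male obligate carriers).
#' @export
check_autosomal_consistency <- function(result, ped) {
  stopifnot(inherits(result, "inference_result"), inherits(ped, "pedigree"))
  sex_of <- stats::setNames(ped$dogs$sex, ped$dogs$id)
  witnesses <- result$obligate_carriers[
    sex_of[result$obligate_carriers] == "male"]
  list(consistent = length(witnesses) > 0L, witnesses = unname(witnesses))
}

#' Likelihood ratio for two hypothesized parent genotypes
#'
#' Formalizes "suggests but does not prove" reasoning about a parent whose
#' genotype deduction is ambiguous: given a fixed mate genotype and the
#' observed affected/unaffected split among evaluable pups, compare the
#' binomial likelihoods of the data under two candidate genotypes for the
#' parent (full penetrance; the binomial coefficient cancels). Values above 1
#' favor the first hypothesis. The result is advisory and is never fed back
#' into constraint propagation.
#'
#' @inheritParams infer_recessive
#' @param parent_id the parent whose genotype is in question.
#' @param mode `"recessive"` or `"dominant"`.
#' @param mate_genotype the mate's (single) genotype.
#' @param hypotheses character vector of two candidate genotypes for the
#'   parent.
#' @param mate_id restrict to litters with this mate; default: all litters in
#'   which `parent_id` is a parent.
#' @return list with `ratio` (`Inf` or `0` when one hypothesis has zero
#'   likelihood and pups of the impossible class were observed; `NaN` when
#'   both do), `affected`, `unaffected`, and the per-hypothesis affected-pup
#'   probabilities `p_affected`.
#' @export
parent_genotype_likelihood_ratio <- function(ped,
                                             phenotypes = assign_phenotypes(ped),
                                             parent_id,
                                             mode = c("recessive", "dominant"),
                                             mate_genotype, hypotheses,
                                             mate_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ped, "pedigree"), length(hypotheses) == 2L,
            all(hypotheses %in% .GENOTYPES), mate_genotype %in% .GENOTYPES)
  if (!parent_id %in% ped$dogs$id) stop("unknown parent id: ", parent_id)
  dogs <- ped$dogs
  is_pup <- (!is.na(dogs$sire) & dogs$sire == parent_id) |
    (!is.na(dogs$dam) & dogs$dam == parent_id)
  if (!is.null(mate_id)) {
    is_pup <- is_pup & ((!is.na(dogs$sire) & dogs$sire == mate_id) |
                          (!is.na(dogs$dam) & dogs$dam == mate_id))
  }
  pup_phen <- phenotypes[dogs$id[is_pup]]
  k <- sum(pup_phen == "affected")
  u <- sum(pup_phen == "unaffected")
  n <- k + u
  lik <- vapply(hypotheses, function(h) {
    p <- if (dogs$sex[dogs$id == parent_id] == "male") {
      .affected_prob(mode, h, mate_genotype)
    } else {
      .affected_prob(mode, mate_genotype, h)
    }
    p^k * (1 - p)^(n - k)
  }, numeric(1))
  ratio <- if (n == 0L) 1 else lik[[1L]] / lik[[2L]]
  list(ratio = unname(ratio), affected = k, unaffected = u,
       p_affected = stats::setNames(
         vapply(hypotheses, function(h) {
           if (dogs$sex[dogs$id == parent_id] == "male") {
             .affected_prob(mode, h, mate_genotype)
           } else {
             .affected_prob(mode, mate_genotype, h)
           }
         }, numeric(1)), hypotheses))
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> mode=%s\n", x$mode))
  cat(sprintf("  obligate carriers: %s\n",
              if (length(x$obligate_carriers) == 0L) "none"
              else paste(x$obligate_carriers, collapse = ", ")))
  if (x$mode == "recessive") {
    cat(sprintf("  autosomal-consistent: %s (witnesses: %s)\n",
                x$autosomal_consistent,
                if (length(x$witnesses) == 0L) "none"
                else paste(x$witnesses, collapse = ", ")))
  }
  if (nrow(x$silent_carrier_flags) > 0L) {
    cat(sprintf("  silent-carrier pairs flagged: %s\n",
                paste(x$silent_carrier_flags$litter_id, collapse = ", ")))
  }
  cat(sprintf("  contradictions: %d\n", length(x$contradictions)))
  invisible(x)
}
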