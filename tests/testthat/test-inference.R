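test_that("recessive propagation recovers the cohort T carrier deductions", {
  t <- cohort_pedigree("T")
  phen <- assign_phenotypes(t)
  res <- infer_recessive(t, phen)

  # affected dogs are risk homozygotes, always
  aff <- names(phen)[phen == "affected"]
  for (id in aff) expect_equal(res$genotypes[[id]], "risk_hom")

  # the five unaffected parents of the UNAFFxUNAFF litters with affected pups
  expect_true(all(c("ABE", "LAVE", "COCA", "VIK", "DENA") %in%
                    res$obligate_carriers))
  # the sires of the affected-dam litters
  expect_true(all(c("SAM", "T3S", "T7S") %in% res$obligate_carriers))
  # the unaffected pups of litters T3 and T6 (RIF among them)
  t3t6_unaff <- c("RIF", "T3F4", "T6F4", "T6M5", "T6F5")
  expect_setequal(intersect(res$obligate_carriers, t3t6_unaff), t3t6_unaff)
  # pups of two carrier parents are NOT obligate carriers
  expect_false(any(c("T8F2", "T8M2", "T1F1") %in% res$obligate_carriers))
  expect_length(res$contradictions, 0L)
})

test_that("recessive propagation recovers the cohort K deductions", {
  k <- cohort_pedigree("K")
  phen <- assign_phenotypes(k)
  res <- infer_recessive(k, phen)

  # sires of affected-dam litters that produced affected pups
  expect_true(all(c("OAN", "CRY", "ART") %in% res$obligate_carriers))
  # dams of litters with affected pups and an unevaluable mate
  expect_true(all(c("KELL", "MYCK") %in% res$obligate_carriers))
  # both unaffected parents of litter K1
  expect_true(all(c("TAL", "LANG") %in% res$obligate_carriers))
  # the 13 unaffected pups of the affected-dam litters are all carriers
  pups13 <- c("K3F2", "K4M2", "K4F2", "K5M1", "K6M1", "K6M2", "K6F2",
              "K9M2", "K9F2", "K9M3", "K10F1", "K10M1", "K10F2")
  expect_true(all(pups13 %in% res$obligate_carriers))
  # SON and AMP remain ambiguous: carrier or risk-homozygote, never resolved
  expect_setequal(res$genotypes[["SON"]], c("risk_hom", "het"))
  expect_setequal(res$genotypes[["AMP"]], c("risk_hom", "het"))
  # PEN was never proven a carrier
  expect_setequal(res$genotypes[["PEN"]], c("het", "norm_hom"))
  expect_false("PEN" %in% res$obligate_carriers)
  expect_length(res$contradictions, 0L)
})

test_that("the fixpoint is order-independent and only shrinks sets", {
  t <- cohort_pedigree("T")
  ref <- infer_recessive(t)$genotypes
  for (s in 1:5) {
    set.seed(s)
    shuf <- t
    shuf$dogs <- shuf$dogs[sample.int(nrow(shuf$dogs)), ]
    rownames(shuf$dogs) <- NULL
    got <- infer_recessive(shuf)$genotypes
    for (id in names(ref)) expect_setequal(got[[id]], ref[[id]])
  }
  # monotone: the fixpoint is a subset of the phenotype-only initial sets
  phen <- assign_phenotypes(t)
  for (id in names(ref)) {
    init <- switch(phen[[id]],
                   affected = "risk_hom",
                   unaffected = c("het", "norm_hom"),
                   c("risk_hom", "het", "norm_hom"))
    expect_true(all(ref[[id]] %in% init))
  }
})

test_that("Mendelian contradictions are recorded without aborting", {
  # two affected parents cannot produce an unaffected pup under recessive
  # expression at full penetrance
  ped <- make_ped(
    dog_row("SIR", diagnosed = TRUE, age = 7),
    dog_row("DAMM", sex = "female", diagnosed = TRUE, age = 8),
    dog_row("BAD", "SIR", "DAMM", age = 10, litter = "L1"),
    dog_row("OK1", "SIR", "DAMM", diagnosed = TRUE, age = 6, litter = "L1")
  )
  res <- infer_recessive(ped)
  expect_gte(length(res$contradictions), 1L)
  expect_true("BAD" %in% res$contradictions[[1]]$ids)
  expect_length(res$genotypes[["BAD"]], 0L)
  # and the cohort verdict machinery reports the hypothesis inconsistent
  rep <- hypothesis_report(ped)
  expect_equal(rep$recessive$verdict, "inconsistent")
})

test_that("dominant inference flags silent-carrier pairs only where forced", {
  k <- cohort_pedigree("K")
  dk <- infer_dominant(k)
  expect_equal(dk$silent_carrier_flags$litter_id, "K1")
  expect_setequal(unlist(dk$silent_carrier_flags[1, c("sire", "dam")]),
                  c("TAL", "LANG"))

  t <- cohort_pedigree("T")
  dt <- infer_dominant(t)
  expect_setequal(dt$silent_carrier_flags$litter_id, c("T1", "T2", "T8"))
  expect_false("T5" %in% dt$silent_carrier_flags$litter_id)

  # affected dogs carry at least one risk allele; unaffected dogs anything
  phen <- assign_phenotypes(t)
  for (id in names(phen)[phen == "affected"]) {
    expect_setequal(dt$genotypes[[id]], c("risk_hom", "het"))
  }
  expect_length(dt$genotypes[["ABE"]], 3L)
  expect_length(dt$contradictions, 0L)
})

test_that("likelihood ratios quantify ambiguous parent genotypes", {
  k <- cohort_pedigree("K")
  phen <- assign_phenotypes(k)
  # SON x KELL (carrier mate): 5 affected / 4 unaffected pups; homozygous
  # risk vs carrier for SON
  lr_son <- parent_genotype_likelihood_ratio(
    k, phen, "SON", "recessive", mate_genotype = "het",
    hypotheses = c("risk_hom", "het"))
  expect_equal(lr_son$affected, 5L)
  expect_equal(lr_son$unaffected, 4L)
  expect_equal(lr_son$ratio, (0.5^5 * 0.5^4) / (0.25^5 * 0.75^4))
  expect_gt(lr_son$ratio, 1)  # favors homozygous risk

  # PEN x LIUM (affected mate): 0 affected / 3 unaffected; homozygous normal
  # vs carrier for PEN
  lr_pen <- parent_genotype_likelihood_ratio(
    k, phen, "PEN", "recessive", mate_genotype = "risk_hom",
    hypotheses = c("norm_hom", "het"))
  expect_equal(lr_pen$ratio, 1 / 0.5^3)

  # no pups -> uninformative ratio of 1
  lr_none <- parent_genotype_likelihood_ratio(
    make_ped(dog_row("LON")), parent_id = "LON", mode = "recessive",
    mate_genotype = "het", hypotheses = c("risk_hom", "het"))
  expect_equal(lr_none$ratio, 1)

  # affected pups under a zero-probability hypothesis -> infinite ratio
  lr_inf <- parent_genotype_likelihood_ratio(
    k, phen, "SON", "recessive", mate_genotype = "het",
    hypotheses = c("risk_hom", "norm_hom"))
  expect_identical(lr_inf$ratio, Inf)
})

test_that("male obligate carriers witness autosomal inheritance", {
  k <- cohort_pedigree("K")
  rk <- infer_recessive(k)
  expect_true(rk$autosomal_consistent)
  expect_true("TAL" %in% rk$witnesses)

  t <- cohort_pedigree("T")
  rt <- infer_recessive(t)
  expect_true(rt$autosomal_consistent)
  expect_true(all(c("ABE", "VIK") %in% rt$witnesses))

  # all deduced carriers female -> no witness, X-linkage not excluded
  ped <- make_ped(
    dog_row("SIR", diagnosed = TRUE, age = 7),
    dog_row("DAMM", sex = "female", age = 10),
    dog_row("P1", "SIR", "DAMM", diagnosed = TRUE, age = 6, litter = "L1"),
    dog_row("P2", "SIR", "DAMM", sex = "female", age = 3, litter = "L1")
  )
  res <- infer_recessive(ped)
  expect_false(res$autosomal_consistent)
  expect_length(res$witnesses, 0L)
})

test_that("inference is sound on simulated recessive pedigrees", {
  # full penetrance, no phenocopies: the true genotype must always survive
  # propagation, and every obligate-carrier call must be correct
  violations <- 0L
  for (r in 1:150) {
    # lifespans beyond the onset range: no censoring-induced mislabels
    cfg <- sim_config(mode = "recessive", penetrance = 1, baseline_risk = 0,
                      n_founders = 8, n_generations = 2, n_matings = 3,
                      litter_size_mean = 4, lifespan_mean = 20,
                      lifespan_sd = 1, seed = 5000 + r)
    sim <- simulate_pedigree(cfg)
    obs <- censor_to_observed(sim)
    res <- infer_recessive(obs)
    truth <- stats::setNames(sim$dogs$true_genotype, sim$dogs$id)
    for (id in names(truth)) {
      if (!truth[[id]] %in% res$genotypes[[id]]) violations <- violations + 1L
    }
    if (!all(truth[res$obligate_carriers] == "het")) {
      violations <- violations + 1L
    }
    expect_length(res$contradictions, 0L)
  }
  expect_equal(violations, 0L)
})
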