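test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_pedigree(sim_config(seed = 123))
  b <- simulate_pedigree(sim_config(seed = 123))
  expect_equal(a$dogs, b$dogs)
  c <- simulate_pedigree(sim_config(seed = 124))
  expect_false(identical(a$dogs, c$dogs))
})

test_that("founders are Hardy-Weinberg and pups conserve parental alleles", {
  cfg <- sim_config(n_founders = 4000, n_generations = 1, n_matings = 500,
                    risk_allele_freq = 0.3, seed = 21)
  sim <- simulate_pedigree(cfg)
  founders <- sim$dogs[is.na(sim$dogs$sire), ]
  freq <- table(factor(founders$true_genotype,
                       levels = c("risk_hom", "het", "norm_hom"))) /
    nrow(founders)
  hw <- c(0.3^2, 2 * 0.3 * 0.7, 0.7^2)
  expect_true(all(abs(as.numeric(freq) - hw) < 0.03))

  # every pup's genotype must be producible from its parents' alleles
  geno_of <- stats::setNames(sim$dogs$true_genotype, sim$dogs$id)
  pups <- sim$dogs[!is.na(sim$dogs$sire), ]
  can_give <- list(risk_hom = 1, het = c(0, 1), norm_hom = 0)
  ok <- vapply(seq_len(nrow(pups)), function(i) {
    target <- c(risk_hom = 2, het = 1, norm_hom = 0)[[pups$true_genotype[i]]]
    any(outer(can_give[[geno_of[[pups$sire[i]]]]],
              can_give[[geno_of[[pups$dam[i]]]]], "+") == target)
  }, logical(1))
  expect_true(all(ok))
})

test_that("segregation in simulated litters matches Mendelian expectation", {
  # recessive: risk_hom x het matings segregate 1-to-1 at full penetrance
  count_class <- function(mode, sire_g, dam_g, n_runs, seed0) {
    aff <- 0L; tot <- 0L
    for (r in seq_len(n_runs)) {
      cfg <- sim_config(mode = mode, risk_allele_freq = 0.5, penetrance = 1,
                        baseline_risk = 0, n_founders = 200,
                        n_generations = 1, n_matings = 100,
                        litter_size_mean = 8,
                        lifespan_mean = 14, lifespan_sd = 0.1,
                        seed = seed0 + r)
      sim <- simulate_pedigree(cfg)
      geno_of <- stats::setNames(sim$dogs$true_genotype, sim$dogs$id)
      pups <- sim$dogs[!is.na(sim$dogs$sire), ]
      # both orientations of the (sire_g, dam_g) mating are informative
      pick <- (geno_of[pups$sire] == sire_g & geno_of[pups$dam] == dam_g) |
        (sire_g != dam_g & geno_of[pups$sire] == dam_g &
           geno_of[pups$dam] == sire_g)
      aff <- aff + sum(pups$diagnosed[pick])
      tot <- tot + sum(pick)
    }
    list(aff = aff, tot = tot)
  }
  # lifespans far beyond the onset range make penetrance fully visible
  rec <- count_class("recessive", "risk_hom", "het", n_runs = 65, seed0 = 300)
  expect_gt(rec$tot, 10000)
  se <- sqrt(0.25 / rec$tot)
  expect_lt(abs(rec$aff / rec$tot - 0.5), 4 * se)

  # dominant: norm_hom sire, dam het -> 50%; dam risk_hom -> 100%; the
  # equal-weight average is the 75% affected-dam expectation
  dom_het <- count_class("dominant", "norm_hom", "het", 10, 600)
  dom_hom <- count_class("dominant", "norm_hom", "risk_hom", 10, 600)
  expect_lt(abs(dom_het$aff / dom_het$tot - 0.5),
            4 * sqrt(0.25 / dom_het$tot))
  expect_equal(dom_hom$aff, dom_hom$tot)  # all pups carry the risk allele
  mixture <- (dom_het$aff / dom_het$tot + dom_hom$aff / dom_hom$tot) / 2
  expect_lt(abs(mixture - 0.75), 0.02)
})

test_that("no dog without the risk genotype is diagnosed when baseline is 0", {
  for (mode in c("recessive", "dominant")) {
    sim <- simulate_pedigree(sim_config(mode = mode, penetrance = 1,
                                        baseline_risk = 0, seed = 77))
    safe <- if (mode == "recessive") c("het", "norm_hom") else "norm_hom"
    expect_false(any(sim$dogs$diagnosed[sim$dogs$true_genotype %in% safe]))
    # diagnosed implies onset before death
    dx <- sim$dogs[sim$dogs$diagnosed, ]
    expect_true(all(dx$onset_age <= dx$age_years))
  }
})

test_that("censoring to observed fields round-trips and loses only truth", {
  sim <- simulate_pedigree(sim_config(seed = 31))
  obs <- censor_to_observed(sim)
  expect_false(any(c("true_genotype", "onset_age") %in% names(obs$dogs)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(obs, path)
  expect_equal(read_pedigree(path)$dogs, obs$dogs)

  # dogs labeled unaffected despite an at-risk genotype are exactly the
  # late-onset censoring errors: disease would have arrived after death
  phen <- assign_phenotypes(obs)
  at_risk <- sim$dogs$true_genotype == "risk_hom"
  mislabeled <- sim$dogs$id[at_risk & phen[sim$dogs$id] == "unaffected"]
  for (id in mislabeled) {
    row <- sim$dogs[sim$dogs$id == id, ]
    expect_true(is.na(row$onset_age) || row$onset_age > row$age_years)
  }

  # a tiny cutoff makes every undiagnosed dog unaffected
  expect_false(any(assign_phenotypes(obs, cutoff = 1e-6) == "unevaluable"))
})

test_that("raising the cutoff never adds unaffected labels", {
  obs <- censor_to_observed(simulate_pedigree(sim_config(seed = 99)))
  n_unaff <- vapply(c(5, 6.5, 8.5, 10, 12), function(ct) {
    sum(assign_phenotypes(obs, cutoff = ct) == "unaffected")
  }, numeric(1))
  expect_true(all(diff(n_unaff) <= 0))
})

test_that("lifespan censoring produces cohort-like evaluability loss", {
  losses <- vapply(1:20, function(r) {
    obs <- censor_to_observed(simulate_pedigree(sim_config(seed = 800 + r)))
    phen <- assign_phenotypes(obs)
    mean(phen == "unevaluable")
  }, numeric(1))
  # real late-onset cohorts lose roughly a third to a half of dogs
  expect_gt(mean(losses), 0.15)
  expect_lt(mean(losses), 0.65)
})

test_that("mode recovery separates recessive from dominant truth", {
  cfgs <- list(sim_config(mode = "recessive", penetrance = 1),
               sim_config(mode = "dominant", penetrance = 1))
  out <- mode_recovery_experiment(cfgs, n_replicates = 15, seed = 42)
  expect_equal(nrow(out), 2L)
  rej_rec <- out$recessive_rejected_rate[out$mode == "recessive"]
  rej_dom <- out$recessive_rejected_rate[out$mode == "dominant"]
  expect_gt(rej_dom, rej_rec)
  expect_true(all(out$rejected_ci_low <= out$recessive_rejected_rate &
                    out$recessive_rejected_rate <= out$rejected_ci_high))
  # empty call yields an empty table
  empty <- mode_recovery_experiment(cfgs[[1]], n_replicates = 0)
  expect_equal(nrow(empty), 0L)
})
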