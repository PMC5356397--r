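# Independent oracles: these deliberately avoid the package's code paths.

# Mendelian affected-offspring probability by explicit enumeration of the
# four equally likely parental allele transmissions.
oracle_affected_fraction <- function(mode, sire, dam, penetrance = 1) {
  alleles <- list(risk_hom = c(1, 1), het = c(1, 0), norm_hom = c(0, 0))
  total <- 0
  for (a in alleles[[sire]]) {
    for (b in alleles[[dam]]) {
      at_risk <- if (mode == "recessive") (a + b) == 2 else (a + b) >= 1
      total <- total + at_risk * penetrance
    }
  }
  total / 4
}

# Two-sided exact binomial p-value by direct pmf summation (point-probability
# method, with the customary relative tolerance for ties).
oracle_binom_p <- function(k, n, p) {
  pm <- dbinom(0:n, n, p)
  sum(pm[pm <= dbinom(k, n, p) * (1 + 1e-7)])
}

dog_row <- function(id, sire = NA, dam = NA, sex = "male", diagnosed = FALSE,
                    age = 10, alive = FALSE, litter = NA) {
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             diagnosed = diagnosed, age_years = age, alive = alive,
             litter_id = litter, stringsAsFactors = FALSE)
}

make_ped <- function(..., cutoff = 8.5) {
  pedigree(do.call(rbind, list(...)), cutoff_age = cutoff)
}

# A minimal nuclear family: unaffected parents, one affected pup, one
# unaffected pup. Exercises obligate-carrier deduction.
nuclear_ped <- function() {
  make_ped(
    dog_row("SIR"), dog_row("DAMM", sex = "female"),
    dog_row("AFF1", "SIR", "DAMM", diagnosed = TRUE, age = 6, litter = "L1"),
    dog_row("UNA1", "SIR", "DAMM", sex = "female", age = 9, litter = "L1")
  )
}

# Per-litter compositions of the bundled cohorts' affected x unaffected
# crosses (affected, unaffected), frozen from the litter tables.
K_AFFXUNAFF <- list(K2 = c(1, 0), K3 = c(2, 1), K4 = c(2, 2), K5 = c(0, 1),
                    K6 = c(1, 3), K9 = c(2, 3), K10 = c(0, 3))
T_AFFXUNAFF <- list(T3 = c(7, 2), T6 = c(7, 3), T7 = c(4, 0))
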