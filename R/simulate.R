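#' Configuration for the gene-drop simulator
#'
#' Defaults describe a closed, inbred family segregating a single highly
#' penetrant autosomal risk factor for a late-onset disease, with onset ages
#' drawn from the packaged breed-survey distribution and lifespans that
#' censor a realistic share of undiagnosed dogs below the cutoff.
#'
#' @param mode inheritance mode of the simulated risk factor.
#' @param risk_allele_freq founder risk-allele frequency in (0, 1); default
#'   0.3, an enriched-family frequency (under recessive expression it puts
#'   roughly 9% of founders at risk, matching breed-level lifetime
#'   incidence, while the pedigree concentrates risk further).
#' @param penetrance probability that an at-risk genotype develops disease in
#'   an uncensored lifetime, in (0, 1]; default 1.
#' @param baseline_risk disease probability for genotypes without the risk
#'   factor (phenocopies); default 0.05.
#' @param n_founders number of founder dogs (>= 2, both sexes); default 10.
#' @param n_generations number of bred generations; default 3.
#' @param n_matings sire/dam pairs formed per generation (capped by the sex
#'   counts available); default 4.
#' @param litters_per_pair litters each pair produces; default 1.
#' @param litter_size_mean mean litter size (sizes are 1 + Poisson(mean - 1),
#'   so litters are never empty); default 6.
#' @param onset_table an [onset_table()] to draw onset ages from (uniform
#'   within the diagnosed bin, one year wide above the last edge); default
#'   the packaged survey table. Ignored if `onset_mean` is given.
#' @param onset_mean,onset_sd optional normal alternative for onset age.
#' @param lifespan_mean,lifespan_sd,lifespan_min lifespan distribution in
#'   years: normal, floored at `lifespan_min`. Defaults 9.5 / 1.8 / 1,
#'   calibrated so the evaluability loss at an 8.5-year cutoff is of the same
#'   order seen in real late-onset cohorts.
#' @param cutoff_age cutoff age carried into the output pedigree.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `sim_config` list.
#' @export
sim_config <- function(mode = c("recessive", "dominant"),
                       risk_allele_freq = 0.3,
                       penetrance = 1,
                       baseline_risk = 0.05,
                       n_founders = 10,
                       n_generations = 3,
                       n_matings = 4,
                       litters_per_pair = 1,
                       litter_size_mean = 6,
                       onset_table = NULL,
                       onset_mean = NULL,
                       onset_sd = 1,
                       lifespan_mean = 9.5,
                       lifespan_sd = 1.8,
                       lifespan_min = 1,
                       cutoff_age = 8.5,
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(risk_allele_freq > 0, risk_allele_freq < 1,
            penetrance > 0, penetrance <= 1,
            baseline_risk >= 0, baseline_risk < 1,
            n_founders >= 2, n_generations >= 1, n_matings >= 1,
            litters_per_pair >= 1, litter_size_mean > 0)
  structure(list(mode = mode, risk_allele_freq = risk_allele_freq,
                 penetrance = penetrance, baseline_risk = baseline_risk,
                 n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_matings = as.integer(n_matings),
                 litters_per_pair = as.integer(litters_per_pair),
                 litter_size_mean = litter_size_mean,
                 onset_table = onset_table, onset_mean = onset_mean,
                 onset_sd = onset_sd, lifespan_mean = lifespan_mean,
                 lifespan_sd = lifespan_sd, lifespan_min = lifespan_min,
                 cutoff_age = cutoff_age, seed = seed),
            class = "sim_config")
}

.sample_onset <- function(n, sex, config) {
  if (!is.null(config$onset_mean)) {
    return(pmax(0, stats::rnorm(n, config$onset_mean, config$onset_sd)))
  }
  tab <- config$onset_table
  if (is.null(tab)) tab <- survey_onset_table()
  edges <- tab$bin_edges
  out <- numeric(n)
  for (sx in unique(sex)) {
    counts <- tab$counts_by_sex[[sx]]
    idx <- which(sex == sx)
    bins <- sample.int(length(counts), length(idx), replace = TRUE,
                       prob = counts / sum(counts))
    lo <- edges[bins]
    hi <- c(edges[-1L], edges[length(edges)] + 1)[bins]
    out[idx] <- stats::runif(length(idx), lo, hi)
  }
  out
}

#' Simulate a pedigree by gene dropping
#'
#' Founders are drawn at Hardy-Weinberg proportions from the configured risk
#' allele frequency; each generation, sires and dams of the previous
#' generation are paired at random and each pair produces litters whose pups
#' inherit one allele from each parent uniformly. Disease is then expressed
#' with probability `penetrance` for at-risk genotypes (risk homozygotes
#' under recessive expression; carriers of any copy under dominant) and
#' `baseline_risk` otherwise; diseased dogs draw an onset age, every dog
#' draws a lifespan, and a dog is diagnosed only if onset precedes death.
#' All dogs are reported deceased at their lifespan.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] whose `dogs` table additionally carries
#'   `true_genotype` and `onset_age` (`NA` when never diseased); class
#'   `simulated_pedigree`.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  q <- config$risk_allele_freq
  p <- 1 - q

  n0 <- config$n_founders
  founders <- data.frame(
    id = sprintf("G0_%03d", seq_len(n0)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("male", "female"), length.out = n0),
    litter_id = NA_character_,
    true_genotype = sample(.GENOTYPES, n0, replace = TRUE,
                           prob = c(q^2, 2 * p * q, p^2)),
    stringsAsFactors = FALSE
  )
  all_dogs <- founders
  current <- founders

  for (g in seq_len(config$n_generations)) {
    males <- current[current$sex == "male", , drop = FALSE]
    females <- current[current$sex == "female", , drop = FALSE]
    n_pairs <- min(config$n_matings, nrow(males), nrow(females))
    if (n_pairs == 0L) {
      if (g == 1L) stop("founders contain no opposite-sex pair to mate")
      break  # a small generation can come out single-sex; stop breeding
    }
    sires <- males[sample.int(nrow(males), n_pairs), , drop = FALSE]
    dams <- females[sample.int(nrow(females), n_pairs), , drop = FALSE]
    pups <- list()
    counter <- 0L
    for (i in seq_len(n_pairs)) {
      for (l in seq_len(config$litters_per_pair)) {
        size <- 1L + stats::rpois(1L, max(config$litter_size_mean - 1, 0))
        lid <- sprintf("G%dL%d_%d", g, i, l)
        from_sire <- stats::runif(size) <
          .risk_transmission[[sires$true_genotype[i]]]
        from_dam <- stats::runif(size) <
          .risk_transmission[[dams$true_genotype[i]]]
        geno <- ifelse(from_sire & from_dam, "risk_hom",
                       ifelse(from_sire | from_dam, "het", "norm_hom"))
        pups[[length(pups) + 1L]] <- data.frame(
          id = sprintf("G%d_%03d", g, counter + seq_len(size)),
          sire = sires$id[i], dam = dams$id[i],
          sex = sample(c("male", "female"), size, replace = TRUE),
          litter_id = lid, true_genotype = geno,
          stringsAsFactors = FALSE
        )
        counter <- counter + size
      }
    }
    current <- do.call(rbind, pups)
    all_dogs <- rbind(all_dogs, current)
  }

  n <- nrow(all_dogs)
  at_risk <- if (config$mode == "recessive") {
    all_dogs$true_genotype == "risk_hom"
  } else {
    all_dogs$true_genotype != "norm_hom"
  }
  p_disease <- ifelse(at_risk, config$penetrance, config$baseline_risk)
  diseased <- stats::runif(n) < p_disease
  onset <- rep(NA_real_, n)
  if (any(diseased)) {
    onset[diseased] <- .sample_onset(sum(diseased), all_dogs$sex[diseased],
                                     config)
  }
  lifespan <- pmax(config$lifespan_min,
                   stats::rnorm(n, config$lifespan_mean, config$lifespan_sd))
  diagnosed <- diseased & onset <= lifespan
  diagnosed[is.na(diagnosed)] <- FALSE

  dogs <- data.frame(
    id = all_dogs$id, sire = all_dogs$sire, dam = all_dogs$dam,
    sex = all_dogs$sex, diagnosed = diagnosed, age_years = lifespan,
    alive = FALSE, litter_id = all_dogs$litter_id,
    true_genotype = all_dogs$true_genotype,
    onset_age = ifelse(diagnosed, onset, NA_real_),
    stringsAsFactors = FALSE
  )
  ped <- pedigree(dogs[, c("id", "sire", "dam", "sex", "diagnosed",
                           "age_years", "alive", "litter_id")],
                  cutoff_age = config$cutoff_age)
  ped$dogs$true_genotype <- dogs$true_genotype
  ped$dogs$onset_age <- dogs$onset_age
  class(ped) <- c("simulated_pedigree", class(ped))
  ped
}

#' Strip simulation truth, keeping only observable fields
#'
#' Emits exactly what a breeder could report: identity, parentage, sex,
#' diagnosis, age at death, vital status and litter. Undiagnosed dogs that
#' died before the cutoff become unevaluable downstream, reproducing the
#' data loss a late-onset disease inflicts on real cohorts.
#'
#' @param ped a [simulate_pedigree()] result.
#' @return a plain [pedigree()].
#' @export
censor_to_observed <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  dogs <- ped$dogs[, c("id", "sire", "dam", "sex", "diagnosed", "age_years",
                       "alive", "litter_id")]
  rownames(dogs) <- NULL
  pedigree(dogs, cutoff_age = ped$cutoff_age)
}

#' Mode-recovery experiment
#'
#' For each configuration and replicate: simulate a pedigree, censor it to
#' observable fields, assign phenotypes, filter to evaluable dogs, and run
#' [hypothesis_report()]. Records how often the recessive hypothesis is
#' rejected and how often the true mode survives (is not the rejected one).
#' Replicate seeds are derived deterministically from `seed`.
#'
#' @param configs a [sim_config()] or list of them.
#' @param n_replicates replicates per configuration; 0 yields an empty table.
#' @param alpha test size passed to [hypothesis_report()].
#' @param seed base integer seed.
#' @return data.frame with one row per configuration: `mode`,
#'   `n_replicates`, `recessive_rejected_rate` with 95% binomial confidence
#'   bounds, `recovery_rate`, and the mean evaluable-dog count.
#' @export
mode_recovery_experiment <- function(configs, n_replicates, alpha = 0.05,
                                     seed = 1) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1), "sim_config")),
            n_replicates >= 0)
  rows <- list()
  for (ci in seq_along(configs)) {
    config <- configs[[ci]]
    if (n_replicates == 0L) next
    rejected <- logical(n_replicates)
    recovered <- logical(n_replicates)
    n_eval <- integer(n_replicates)
    for (r in seq_len(n_replicates)) {
      config$seed <- (seed + 7919L * ci + r) %% .Machine$integer.max
      sim <- simulate_pedigree(config)
      obs <- censor_to_observed(sim)
      phen <- assign_phenotypes(obs)
      evaluable <- filter_evaluable(obs, phen)
      phen2 <- assign_phenotypes(evaluable)
      rep_out <- hypothesis_report(evaluable, phen2, alpha = alpha)
      rejected[r] <- identical(rep_out$recessive$verdict, "inconsistent")
      dom_bad <- identical(rep_out$dominant$verdict,
                           "low_penetrance_or_alternative")
      recovered[r] <- if (config$mode == "recessive") !rejected[r] else !dom_bad
      n_eval[r] <- nrow(evaluable$dogs)
    }
    ci_bounds <- stats::binom.test(sum(rejected), n_replicates)$conf.int
    rows[[length(rows) + 1L]] <- data.frame(
      mode = config$mode,
      n_replicates = n_replicates,
      recessive_rejected_rate = mean(rejected),
      rejected_ci_low = ci_bounds[1L],
      rejected_ci_high = ci_bounds[2L],
      recovery_rate = mean(recovered),
      mean_evaluable = mean(n_eval),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(mode = character(), n_replicates = integer(),
                      recessive_rejected_rate = numeric(),
                      rejected_ci_low = numeric(),
                      rejected_ci_high = numeric(),
                      recovery_rate = numeric(), mean_evaluable = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
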