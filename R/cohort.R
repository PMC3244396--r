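#' Default latent-class endorsement probabilities
#'
#' Class-conditional probabilities of endorsing each of the ten comorbidity
#' indicators used throughout the package's simulations: substance abuse
#' (SUBA), obsessive-compulsive disorder (OCD), panic disorder (PD), social
#' and specific phobia (SP), eating disorder (ED), attention-deficit
#' hyperactivity disorder (ADHD), alcohol abuse (ALCAB), alcohol dependence
#' (ALCDEP), nicotine dependence (NIC) and psychotic symptoms (PSYCH).
#' Class 1 is the substance-abuse/psychosis class, class 2 the
#' alcohol-dependence class, class 3 the low-comorbidity class.
#'
#' @return A 3 x 10 numeric matrix; rows are latent classes, columns items.
#' @export
default_endorsement_probs <- function() {
  items <- c("SUBA", "OCD", "PD", "SP", "ED", "ADHD",
             "ALCAB", "ALCDEP", "NIC", "PSYCH")
  m <- rbind(
    class1 = c(0.39, 0.17, 0.37, 0.24, 0.12, 0.15, 0.42, 0.00, 0.30, 0.40),
    class2 = c(0.78, 0.10, 0.31, 0.23, 0.10, 0.20, 0.00, 1.00, 0.47, 0.29),
    class3 = c(0.07, 0.03, 0.12, 0.08, 0.03, 0.01, 0.03, 0.18, 0.08, 0.17)
  )
  colnames(m) <- items
  m
}

#' Specify a simulated SNP
#'
#' Describes one SNP in the synthetic genotype panel, optionally carrying a
#' planted class-specific effect: after a null Hardy-Weinberg draw,
#' `n_forced_carriers` members of `effect_class` are overwritten with the
#' risk genotype (homozygous minor under the recessive model, heterozygous
#' under the dominant model, homozygous minor under the additive model).
#'
#' @param snp_id SNP identifier.
#' @param chromosome Chromosome label (autosomes "1".."22").
#' @param position 1-based position in base pairs.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param effect_class Latent class index carrying the planted effect, or
#'   `NA` for a null SNP.
#' @param effect_model One of `"recessive"`, `"dominant"`, `"additive"`, or
#'   `NA` for a null SNP.
#' @param n_forced_carriers Number of `effect_class` members forced to the
#'   risk genotype.
#' @return A list of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, chromosome, position, maf,
                     effect_class = NA_integer_, effect_model = NA_character_,
                     n_forced_carriers = 0L) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("`maf` must be a single value in (0, 0.5]", call. = FALSE)
  if (!is.na(effect_model) &&
      !effect_model %in% c("recessive", "dominant", "additive"))
    stop("`effect_model` must be recessive, dominant or additive", call. = FALSE)
  if (n_forced_carriers < 0)
    stop("`n_forced_carriers` must be non-negative", call. = FALSE)
  structure(list(snp_id = as.character(snp_id),
                 chromosome = as.character(chromosome),
                 position = as.integer(position),
                 maf = maf,
                 effect_class = effect_class,
                 effect_model = effect_model,
                 n_forced_carriers = as.integer(n_forced_carriers)),
            class = "snp_spec")
}

#' Specify a synthetic case/control cohort
#'
#' Defines the generative model for a cohort with latent-class comorbidity
#' structure among cases, auxiliary covariates, and a genotype panel with
#' optional planted effects and two-population structure. The defaults
#' reproduce the study conditions of the bipolar disorder sample the
#' package's simulations emulate: 1000 cases and 1034 controls, three latent
#' classes at proportions 26/25/49% with the endorsement probabilities of
#' [default_endorsement_probs()], class ages of mean 41/41/44 years
#' (SD 12.6/10.8/13.8), female proportions 62/39/49%, and age missing in
#' about 8 of 1000 cases.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param class_proportions Latent-class mixing proportions (sum to 1).
#' @param endorsement_probs K x J matrix of class-conditional endorsement
#'   probabilities.
#' @param item_names Indicator labels (defaults to the matrix column names).
#' @param aux_age_mean,aux_age_sd Per-class mean and SD of age (years).
#' @param aux_female Per-class probability of female sex.
#' @param control_age_mean,control_age_sd,control_female Control-stratum
#'   covariate parameters.
#' @param age_missing_rate Probability that a case's age is missing.
#' @param indicator_missing_rate Probability that an indicator cell is
#'   missing (default 0; the emulated data had complete indicators).
#' @param snp_specs List of [snp_spec()] objects (effect or bespoke SNPs).
#' @param n_null_snps Number of additional null SNPs.
#' @param null_maf_range MAF interval for null SNPs.
#' @param fst Balding-Nichols divergence for optional two-population
#'   structure; 0 disables structure.
#' @param case_pop2_prob Probability that a case belongs to subpopulation 2
#'   when `fst > 0`; defaults to `pop2_prob` (structure independent of case
#'   status), set higher to confound structure with phenotype.
#' @param pop2_prob Probability that an individual belongs to subpopulation 2.
#' @param genotype_missing_rate Probability a genotype call is missing.
#' @param seed Integer seed; fixes every random draw of the generator.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 1000L, n_controls = 1034L,
                        class_proportions = c(0.26, 0.25, 0.49),
                        endorsement_probs = default_endorsement_probs(),
                        item_names = colnames(endorsement_probs),
                        aux_age_mean = c(41, 41, 44),
                        aux_age_sd = c(12.6, 10.8, 13.8),
                        aux_female = c(0.62, 0.39, 0.49),
                        control_age_mean = 52, control_age_sd = 17.6,
                        control_female = 0.486,
                        age_missing_rate = 0.008,
                        indicator_missing_rate = 0,
                        snp_specs = list(),
                        n_null_snps = 0L,
                        null_maf_range = c(0.05, 0.5),
                        fst = 0,
                        pop2_prob = 0.5,
                        case_pop2_prob = pop2_prob,
                        genotype_missing_rate = 0,
                        seed = 1L) {
  endorsement_probs <- as.matrix(endorsement_probs)
  K <- length(class_proportions)
  J <- ncol(endorsement_probs)
  if (n_cases < 0 || n_controls < 0)
    stop("cohort sizes must be non-negative", call. = FALSE)
  if (K < 1L || J < 1L)
    stop("need at least one class and one indicator", call. = FALSE)
  if (nrow(endorsement_probs) != K)
    stop("`endorsement_probs` must have one row per class", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-12)
    stop("`class_proportions` must sum to 1", call. = FALSE)
  assert_probability(class_proportions, "class_proportions")
  assert_probability(endorsement_probs, "endorsement_probs")
  assert_probability(c(age_missing_rate, indicator_missing_rate,
                       genotype_missing_rate, pop2_prob, case_pop2_prob),
                     "missingness/structure rates")
  if (fst < 0 || fst >= 1)
    stop("`fst` must lie in [0, 1)", call. = FALSE)
  if (length(null_maf_range) != 2L || null_maf_range[1] <= 0 ||
      null_maf_range[2] > 0.5 || null_maf_range[1] > null_maf_range[2])
    stop("`null_maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  stopifnot(length(aux_age_mean) == K, length(aux_age_sd) == K,
            length(aux_female) == K)
  for (s in snp_specs) {
    if (!inherits(s, "snp_spec")) stop("`snp_specs` must hold snp_spec objects",
                                       call. = FALSE)
    if (!is.na(s$effect_class) && (s$effect_class < 1 || s$effect_class > K))
      stop("effect_class outside 1..K in snp_spec ", s$snp_id, call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 class_proportions = class_proportions,
                 endorsement_probs = endorsement_probs,
                 item_names = item_names,
                 aux_age_mean = aux_age_mean, aux_age_sd = aux_age_sd,
                 aux_female = aux_female,
                 control_age_mean = control_age_mean,
                 control_age_sd = control_age_sd,
                 control_female = control_female,
                 age_missing_rate = age_missing_rate,
                 indicator_missing_rate = indicator_missing_rate,
                 snp_specs = snp_specs,
                 n_null_snps = as.integer(n_null_snps),
                 null_maf_range = null_maf_range,
                 fst = fst, pop2_prob = pop2_prob,
                 case_pop2_prob = case_pop2_prob,
                 genotype_missing_rate = genotype_missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a case/control cohort with latent-class structure
#'
#' Draws each case's latent class from the mixing proportions, generates the
#' binary indicator table for cases only (controls carry no indicator data,
#' mirroring studies where symptom-level information exists for cases alone),
#' simulates genotypes for cases and controls, and attaches auxiliary
#' covariates. All draws are fixed by `spec$seed`.
#'
#' Indicators are conditionally independent Bernoulli draws given the latent
#' class, the same conditional-independence structure the latent class model
#' assumes.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `lc_cohort` with elements `indicators` (tibble,
#'   cases only), `genotypes` (a [genotype_matrix()], cases then controls),
#'   `case_flags` (0/1 vector over all individuals), `aux` (covariate
#'   tibble) and `truth` (true classes, planted SNPs, subpopulations).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_cases = 100, n_controls = 100,
#'                                    n_null_snps = 10, seed = 7))
#' dim(coh$indicators)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- sub_seeds(spec$seed, 4L)
  K <- length(spec$class_proportions)

  true_class <- with_seed(seeds[1], {
    sample.int(K, spec$n_cases, replace = TRUE, prob = spec$class_proportions)
  })

  indicators <- with_seed(seeds[2], {
    rho <- spec$endorsement_probs[true_class, , drop = FALSE]
    u <- matrix(stats::rbinom(length(rho), 1L, as.vector(rho)), nrow = spec$n_cases)
    if (spec$indicator_missing_rate > 0) {
      drop <- matrix(stats::runif(length(u)) < spec$indicator_missing_rate,
                     nrow = spec$n_cases)
      # never blank out a whole row: the model requires one observed item
      full_row <- rowSums(!drop) == 0
      drop[full_row, 1L] <- FALSE
      u[drop] <- NA_integer_
    }
    colnames(u) <- spec$item_names
    u
  })

  geno <- simulate_genotypes(spec, true_class, seed = seeds[3])
  aux <- simulate_auxiliary(spec, true_class, seed = seeds[4])

  case_flags <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  ind_tbl <- tibble::as_tibble(indicators)
  ind_tbl <- dplyr::bind_cols(
    tibble::tibble(case_id = geno$sample_ids[seq_len(spec$n_cases)]), ind_tbl)

  planted <- purrr::map_dfr(spec$snp_specs, function(s) {
    tibble::tibble(snp_id = s$snp_id,
                   effect_class = s$effect_class,
                   effect_model = s$effect_model %||% NA_character_,
                   n_forced_carriers = s$n_forced_carriers)
  })
  if (nrow(planted)) planted <- dplyr::filter(planted, !is.na(.data$effect_class))

  structure(list(indicators = ind_tbl,
                 genotypes = geno,
                 case_flags = case_flags,
                 aux = aux,
                 truth = list(true_class = true_class,
                              planted_snps = planted,
                              subpopulation = attr(geno, "subpopulation"))),
            class = "lc_cohort")
}

#' Simulate a genotype panel for a cohort
#'
#' Null SNPs are drawn at Hardy-Weinberg proportions from their MAF; when
#' `spec$fst > 0` subpopulation allele frequencies are drawn from the
#' Balding-Nichols beta model and individuals are assigned to two
#' subpopulations (independently of case status unless `case_pop2_prob`
#' differs from `pop2_prob`). Effect SNPs are drawn null first, then
#' `n_forced_carriers` randomly chosen members of the effect class are
#' overwritten with the risk genotype, so planted carrier counts are exact.
#' Missing calls are inserted at `genotype_missing_rate`, never on forced
#' carriers.
#'
#' @param spec A [cohort_spec()].
#' @param true_class Latent class index per case (length `spec$n_cases`).
#' @param seed Seed for this stage (defaults to `spec$seed`).
#' @return A [genotype_matrix()] for cases (first) then controls, with a
#'   `subpopulation` attribute when `fst > 0`.
#' @export
simulate_genotypes <- function(spec, true_class, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  specs <- spec$snp_specs
  for (s in specs) {
    if (!is.na(s$effect_class) && !any(true_class == s$effect_class))
      stop("effect_class ", s$effect_class, " absent from cohort", call. = FALSE)
  }
  with_seed(seed, {
    if (spec$n_null_snps > 0) {
      null_maf <- stats::runif(spec$n_null_snps, spec$null_maf_range[1],
                               spec$null_maf_range[2])
      null_specs <- lapply(seq_len(spec$n_null_snps), function(m) {
        snp_spec(sprintf("null_%05d", m),
                 chromosome = as.character(((m - 1L) %% 22L) + 1L),
                 position = 10000L + 1000L * m,
                 maf = null_maf[m])
      })
      specs <- c(specs, null_specs)
    }
    M <- length(specs)
    if (M == 0L) stop("no SNPs to simulate", call. = FALSE)

    subpop <- rep(1L, n)
    if (spec$fst > 0) {
      p2 <- c(rep(spec$case_pop2_prob, spec$n_cases),
              rep(spec$pop2_prob, spec$n_controls))
      subpop <- 1L + as.integer(stats::runif(n) < p2)
    }

    counts <- matrix(NA_integer_, nrow = n, ncol = M)
    mafs <- vapply(specs, `[[`, numeric(1), "maf")
    for (m in seq_len(M)) {
      p <- mafs[m]
      if (spec$fst > 0) {
        a <- p * (1 - spec$fst) / spec$fst
        b <- (1 - p) * (1 - spec$fst) / spec$fst
        p_sub <- stats::rbeta(2L, a, b)
        counts[, m] <- stats::rbinom(n, 2L, p_sub[subpop])
      } else {
        counts[, m] <- stats::rbinom(n, 2L, p)
      }
    }

    forced <- matrix(FALSE, nrow = n, ncol = M)
    for (m in seq_len(M)) {
      s <- specs[[m]]
      if (is.na(s$effect_class) || s$n_forced_carriers == 0L) next
      members <- which(true_class == s$effect_class)  # cases come first
      if (s$n_forced_carriers > length(members))
        stop("n_forced_carriers exceeds class size for ", s$snp_id, call. = FALSE)
      chosen <- sample(members, s$n_forced_carriers)
      risk <- switch(s$effect_model, dominant = 1L, 2L)
      # everyone else loses any stray risk genotype so carrier counts are exact
      if (s$effect_model %in% c("recessive", "additive")) {
        hom <- which(counts[, m] == 2L)
        counts[setdiff(hom, chosen), m] <- 1L
      }
      counts[chosen, m] <- risk
      forced[chosen, m] <- TRUE
    }

    if (spec$genotype_missing_rate > 0) {
      miss <- matrix(stats::runif(n * M) < spec$genotype_missing_rate,
                     nrow = n)
      miss[forced] <- FALSE
      counts[miss] <- NA_integer_
    }

    info <- tibble::tibble(
      snp_id = vapply(specs, `[[`, character(1), "snp_id"),
      chromosome = vapply(specs, `[[`, character(1), "chromosome"),
      position = vapply(specs, `[[`, integer(1), "position"))
    ids <- c(sprintf("case_%04d", seq_len(spec$n_cases)),
             sprintf("ctrl_%04d", seq_len(spec$n_controls)))
    g <- genotype_matrix(counts, info, ids)
    attr(g, "subpopulation") <- if (spec$fst > 0) subpop else NULL
    g
  })
}

#' Simulate auxiliary covariates (age, sex)
#'
#' Case ages are normal with class-specific mean and SD, truncated below at
#' 17 years (the youngest case age in the emulated sample); control ages use
#' a single stratum. Sex is Bernoulli with class-specific female
#' probability. Case ages are set missing at `spec$age_missing_rate`.
#'
#' @param spec A [cohort_spec()].
#' @param true_class Latent class index per case.
#' @param seed Seed for this stage.
#' @return Tibble with `sample_id`, `is_case`, `true_class`, `age`, `female`.
#' @export
simulate_auxiliary <- function(spec, true_class, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    rtnorm <- function(n, mean, sd, lower) {
      x <- stats::rnorm(n, mean, sd)
      while (any(bad <- x < lower)) {
        x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
      }
      x
    }
    mu <- spec$aux_age_mean[true_class]
    sdv <- spec$aux_age_sd[true_class]
    case_age <- rtnorm(spec$n_cases, mu, sdv, 17)
    case_female <- stats::rbinom(spec$n_cases, 1L, spec$aux_female[true_class])
    if (spec$age_missing_rate > 0) {
      case_age[stats::runif(spec$n_cases) < spec$age_missing_rate] <- NA_real_
    }
    ctrl_age <- ctrl_female <- numeric(0)
    if (spec$n_controls > 0) {
      ctrl_age <- rtnorm(spec$n_controls, rep(spec$control_age_mean, spec$n_controls),
                         rep(spec$control_age_sd, spec$n_controls), 18)
      ctrl_female <- stats::rbinom(spec$n_controls, 1L, spec$control_female)
    }
    tibble::tibble(
      sample_id = c(sprintf("case_%04d", seq_len(spec$n_cases)),
                    sprintf("ctrl_%04d", seq_len(spec$n_controls))),
      is_case = c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls)),
      true_class = c(true_class, rep(NA_integer_, spec$n_controls)),
      age = c(case_age, ctrl_age),
      female = as.integer(c(case_female, ctrl_female)))
  })
}

#' Estimate FST between two subpopulations from a genotype panel
#'
#' Moment estimator averaged over SNPs: for each SNP the squared difference
#' in subpopulation allele frequencies, corrected for binomial sampling
#' noise, divided by `2 p (1 - p)` at the pooled frequency. Used to check
#' that simulated structure has the requested divergence.
#'
#' @param genotypes A [genotype_matrix()] or dosage matrix.
#' @param subpop Subpopulation label (two levels) per individual.
#' @return Estimated FST (single number).
#' @export
estimate_fst <- function(genotypes, subpop) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes$counts else as.matrix(genotypes)
  pops <- sort(unique(subpop))
  stopifnot(length(pops) == 2L)
  i1 <- subpop == pops[1]; i2 <- subpop == pops[2]
  p1 <- colMeans(g[i1, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(g[i2, , drop = FALSE], na.rm = TRUE) / 2
  n1 <- colSums(!is.na(g[i1, , drop = FALSE]))
  n2 <- colSums(!is.na(g[i2, , drop = FALSE]))
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1) - p2 * (1 - p2) / (2 * n2)
  den <- 2 * pbar * (1 - pbar)
  keep <- is.finite(num / den) & den > 0
  mean(num[keep]) / mean(den[keep])
}
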