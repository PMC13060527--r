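#' Configuration for a synthetic cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()].  The
#' generative model for blood pressure is the same joint main + interaction
#' model the analysis fits,
#' \deqn{E(Y) = \beta_0 + \beta_{Alc} Alc + \beta_G G + \beta_{G\times Alc}
#'   G \cdot Alc + \beta_C C,}
#' with Gaussian residual noise, where \eqn{Alc} is the binary exposure of a
#' designated contrast (default current drinking), \eqn{G} a genotype dosage
#' in \[0, 2\], and \eqn{C} the covariates age, age squared and sex.
#'
#' Genotypes are Hardy-Weinberg hard calls blended with an independent draw to
#' emulate imputation at a target dosage-quality R-squared.  Drinks per week
#' are zero with probability `p_never` (sex-specific) and otherwise drawn from
#' a sex-specific lognormal left-truncated at 1 drink/week, so the generative
#' never/drinker split coincides with the <1 DPW classification boundary.
#' Antihypertensive medication is assigned by a logistic link on latent SBP
#' and lowers the *observed* BP by `treatment_effect_sbp`/`_dbp` mmHg, so the
#' downstream +15/+10 adjustment is a partial correction, as in real data.
#'
#' @param n_individuals number of individuals (>= 1).
#' @param n_variants number of variants.
#' @param allele_freq effect-allele frequency, scalar or length-`n_variants`
#'   vector, each in (0, 1).
#' @param target_impq target imputation quality (dosage R-squared with the
#'   hard genotype), scalar or per-variant, in (0, 1].
#' @param beta_G,beta_Alc,beta_GxAlc genetic main, exposure and interaction
#'   effects on SBP (mmHg per allele / per exposure unit); `beta_G` and
#'   `beta_GxAlc` may be per-variant vectors.
#' @param beta_age,beta_age2,beta_sex covariate effects on SBP (sex effect is
#'   male minus female, mmHg).
#' @param dbp_scale latent DBP shares the SBP linear predictor's non-intercept
#'   terms scaled by this factor.
#' @param intercept_sbp,intercept_dbp latent BP intercepts (mmHg).
#' @param noise_sd,noise_sd_dbp residual SDs (mmHg), > 0.
#' @param p_never probability of never drinking (<1 DPW), named vector
#'   `c(F=, M=)` or scalar.
#' @param dpw_meanlog,dpw_sdlog lognormal parameters of drinkers' drinks per
#'   week, named `c(F=, M=)` or scalar; `dpw_sdlog` > 0.
#' @param p_female probability an individual is female.
#' @param age_range uniform age range in years.
#' @param med_intercept,med_slope logistic-link parameters for medication:
#'   `P(med) = plogis(med_intercept + med_slope * latent SBP)`.
#' @param treatment_effect_sbp,treatment_effect_dbp true mmHg reduction of
#'   observed BP in medicated individuals.
#' @param gen_contrast exposure contrast whose binary indicator enters the
#'   generative model (see [classify_exposure()]).
#' @param chromosome,position_start,position_spacing variant map: all variants
#'   on one chromosome at evenly spaced 1-based positions unless overridden.
#' @param ld_block_size,ld_block_rho optional exchangeable LD blocks: hard
#'   genotypes within consecutive blocks of this size are generated from a
#'   latent Gaussian with correlation `ld_block_rho` (1 = independent
#'   variants).
#' @param seed integer seed; identical configs give bit-identical cohorts.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals,
                       n_variants,
                       allele_freq = 0.3,
                       target_impq = 1,
                       beta_G = 0,
                       beta_Alc = 2,
                       beta_GxAlc = 0,
                       beta_age = 0.4,
                       beta_age2 = 0,
                       beta_sex = 3,
                       dbp_scale = 0.5,
                       intercept_sbp = 120,
                       intercept_dbp = 75,
                       noise_sd = 15,
                       noise_sd_dbp = 10,
                       p_never = c(F = 0.40, M = 0.30),
                       dpw_meanlog = c(F = 1.0, M = 1.7),
                       dpw_sdlog = c(F = 0.7, M = 0.7),
                       p_female = 0.5,
                       age_range = c(30, 75),
                       med_intercept = -9,
                       med_slope = 0.05,
                       treatment_effect_sbp = 10,
                       treatment_effect_dbp = 6,
                       gen_contrast = "CURDRINK",
                       chromosome = 1L,
                       position_start = 1e6,
                       position_spacing = 1e5,
                       ld_block_size = 1L,
                       ld_block_rho = 0,
                       seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (n_variants < 1) stop("n_variants must be >= 1")
  allele_freq <- rep_len(allele_freq, n_variants)
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop("allele frequencies must lie in (0, 1)")
  target_impq <- rep_len(target_impq, n_variants)
  if (any(target_impq <= 0 | target_impq > 1))
    stop("target_impq must lie in (0, 1]")
  if (noise_sd <= 0 || noise_sd_dbp <= 0) stop("noise SDs must be > 0")
  p_never <- .sex_param(p_never, "p_never")
  if (any(p_never < 0 | p_never > 1)) stop("p_never must lie in [0, 1]")
  dpw_meanlog <- .sex_param(dpw_meanlog, "dpw_meanlog")
  dpw_sdlog <- .sex_param(dpw_sdlog, "dpw_sdlog")
  if (any(dpw_sdlog <= 0)) stop("dpw_sdlog must be > 0")
  gen_contrast <- match.arg(gen_contrast, alc_contrasts())
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (ld_block_rho < 0 || ld_block_rho >= 1)
    stop("ld_block_rho must lie in [0, 1)")
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    allele_freq = allele_freq,
    target_impq = target_impq,
    beta_G = rep_len(beta_G, n_variants),
    beta_Alc = beta_Alc,
    beta_GxAlc = rep_len(beta_GxAlc, n_variants),
    beta_age = beta_age, beta_age2 = beta_age2, beta_sex = beta_sex,
    dbp_scale = dbp_scale,
    intercept_sbp = intercept_sbp, intercept_dbp = intercept_dbp,
    noise_sd = noise_sd, noise_sd_dbp = noise_sd_dbp,
    p_never = p_never, dpw_meanlog = dpw_meanlog, dpw_sdlog = dpw_sdlog,
    p_female = p_female, age_range = age_range,
    med_intercept = med_intercept, med_slope = med_slope,
    treatment_effect_sbp = treatment_effect_sbp,
    treatment_effect_dbp = treatment_effect_dbp,
    gen_contrast = gen_contrast,
    chromosome = as.integer(chromosome),
    position_start = position_start,
    position_spacing = position_spacing,
    ld_block_size = as.integer(ld_block_size),
    ld_block_rho = ld_block_rho,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.sex_param <- function(x, what) {
  if (length(x) == 1L) x <- c(F = unname(x), M = unname(x))
  if (is.null(names(x)) && length(x) == 2L) names(x) <- c("F", "M")
  if (!all(c("F", "M") %in% names(x)))
    stop(what, " must be scalar or named c(F=, M=)")
  x[c("F", "M")]
}

#' Simulate genotype dosages with imputation noise
#'
#' Hard genotypes are Binomial(2, f) per variant (optionally block-correlated
#' through a latent exchangeable Gaussian).  Imputed dosages are the convex
#' blend `a * hard + (1 - a) * hard'` of the hard genotype with an independent
#' draw from the same marginal; the blend weight solves
#' `R^2 = a^2 / (a^2 + (1-a)^2)` so the squared correlation between dosage and
#' hard genotype equals `target_impq`.
#'
#' @param config a [sim_config()].  Uses the current RNG state; call via
#'   [simulate_cohort()] for the documented single-stream order.
#' @return list with `dosage` (n x V matrix in \[0, 2\]), `hard` (the hard
#'   genotype matrix) and `variant_meta` (id, chrom, pos, alleles, configured
#'   frequency, impq).
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_individuals; V <- config$n_variants
  f <- config$allele_freq
  hard <- .sim_hard_genotypes(config)
  a <- .impq_blend_weight(config$target_impq)
  indep <- matrix(stats::rbinom(n * V, 2L, rep(f, each = n)), n, V)
  dosage <- sweep(hard, 2L, a, `*`) + sweep(indep, 2L, 1 - a, `*`)
  meta <- data.frame(
    id = sprintf("v%05d", seq_len(V)),
    chrom = config$chromosome,
    pos = config$position_start + (seq_len(V) - 1L) * config$position_spacing,
    effect_allele = "A", other_allele = "G",
    freq = f, impq = config$target_impq,
    stringsAsFactors = FALSE)
  colnames(dosage) <- colnames(hard) <- meta$id
  list(dosage = dosage, hard = hard, variant_meta = meta)
}

# R^2 = a^2/(a^2+(1-a)^2)  =>  a = s/(1+s), s = sqrt(R^2/(1-R^2))
.impq_blend_weight <- function(r2) {
  a <- ifelse(r2 >= 1, 1, { s <- sqrt(r2 / (1 - r2)); s / (1 + s) })
  pmin(a, 1)
}

.sim_hard_genotypes <- function(config) {
  n <- config$n_individuals; V <- config$n_variants
  f <- config$allele_freq
  bs <- config$ld_block_size; rho <- config$ld_block_rho
  if (bs == 1L || rho == 0) {
    return(matrix(stats::rbinom(n * V, 2L, rep(f, each = n)), n, V))
  }
  # exchangeable latent Gaussian per block, thresholded at HW quantiles:
  # each allele copy shares a block factor with weight sqrt(rho)
  hard <- matrix(0L, n, V)
  blocks <- split(seq_len(V), (seq_len(V) - 1L) %/% bs)
  for (idx in blocks) {
    for (copy in 1:2) {
      z_common <- stats::rnorm(n)
      for (j in idx) {
        z <- sqrt(rho) * z_common + sqrt(1 - rho) * stats::rnorm(n)
        hard[, j] <- hard[, j] + (z < stats::qnorm(f[j]))
      }
    }
  }
  hard
}

#' Simulate sex-specific alcohol exposure (drinks per week)
#'
#' With probability `p_never` (per sex) DPW is 0; otherwise DPW is drawn from
#' the sex-specific lognormal left-truncated at 1, so drinkers always satisfy
#' the field's current-drinker boundary (>= 1 DPW).
#'
#' @param config a [sim_config()].
#' @param sex character vector of "F"/"M".
#' @return numeric vector of drinks per week (>= 0).
#' @export
simulate_exposure <- function(config, sex) {
  n <- length(sex)
  dpw <- numeric(n)
  never <- stats::runif(n) < config$p_never[sex]
  u <- stats::runif(n)  # drawn for all to keep the stream order fixed
  ml <- config$dpw_meanlog[sex]; sl <- config$dpw_sdlog[sex]
  p1 <- stats::plnorm(1, ml, sl)
  dpw <- stats::qlnorm(p1 + u * (1 - p1), ml, sl)
  dpw[never] <- 0
  unname(dpw)
}

#' Simulate blood pressure and medication status
#'
#' Latent BP is the linear predictor plus Gaussian noise; medication is
#' assigned by a logistic link on latent SBP; observed BP is latent minus the
#' configured treatment effect for medicated individuals.
#'
#' @param config a [sim_config()].
#' @param individuals data frame with `sex`, `age`, `dpw`.
#' @param genotypes dosage matrix (n x V).
#' @return data frame with `sbp_raw`, `dbp_raw`, `medicated`.
#' @export
simulate_bp <- function(config, individuals, genotypes) {
  alc <- classify_exposure(individuals$dpw, individuals$sex,
                           config$gen_contrast)
  alc[is.na(alc)] <- 0  # excluded arms carry no generative exposure effect
  male <- as.numeric(individuals$sex == "M")
  gpart <- drop(genotypes %*% config$beta_G) +
    alc * drop(genotypes %*% config$beta_GxAlc)
  lp <- config$beta_Alc * alc + gpart +
    config$beta_age * individuals$age +
    config$beta_age2 * individuals$age^2 +
    config$beta_sex * male
  n <- nrow(individuals)
  sbp <- config$intercept_sbp + lp + stats::rnorm(n, 0, config$noise_sd)
  dbp <- config$intercept_dbp + config$dbp_scale * lp +
    stats::rnorm(n, 0, config$noise_sd_dbp)
  medicated <- as.integer(
    stats::runif(n) < stats::plogis(config$med_intercept +
                                      config$med_slope * sbp))
  data.frame(
    sbp_raw = sbp - config$treatment_effect_sbp * medicated,
    dbp_raw = dbp - config$treatment_effect_dbp * medicated,
    medicated = medicated)
}

#' Simulate a complete cohort
#'
#' Seeds the RNG from `config$seed` and draws, in fixed order: sex, age,
#' exposure, genotypes, BP noise and medication.  Identical configurations
#' therefore yield bit-identical cohorts.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_cohort`: list with `individuals` (id, sex,
#'   age, dpw, medicated, sbp_raw, dbp_raw), `dosage` (n x V matrix),
#'   `hard` (hard genotypes, useful as an LD reference panel),
#'   `variant_meta`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  sex <- ifelse(stats::runif(n) < config$p_female, "F", "M")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  dpw <- simulate_exposure(config, sex)
  geno <- simulate_genotypes(config)
  ind <- data.frame(id = sprintf("i%06d", seq_len(n)), sex = sex,
                    age = age, dpw = dpw, stringsAsFactors = FALSE)
  bp <- simulate_bp(config, ind, geno$dosage)
  cohort <- list(individuals = cbind(ind, bp),
                 dosage = geno$dosage, hard = geno$hard,
                 variant_meta = geno$variant_meta, config = config)
  class(cohort) <- "sim_cohort"
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic GWIS cohort:", nrow(x$individuals), "individuals,",
      nrow(x$variant_meta), "variants\n")
  cat("  never-drinker fraction:",
      round(mean(x$individuals$dpw < 1), 3),
      " medicated:", round(mean(x$individuals$medicated), 3), "\n")
  cat("  mean SBP/DBP (raw):",
      round(mean(x$individuals$sbp_raw), 1), "/",
      round(mean(x$individuals$dbp_raw), 1), "mmHg\n")
  invisible(x)
}

#' Write a cohort to TSV files
#'
#' Emits `individuals.tsv`, `variants.tsv` and `dosage.tsv` (individuals x
#' variants, header = variant ids) under `dir`, each with a provenance stamp
#' header (see [version_stamp()]).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- version_stamp(cohort$config, cohort$config$seed)
  write_stamped_tsv(cohort$individuals, file.path(dir, "individuals.tsv"), stamp)
  write_stamped_tsv(cohort$variant_meta, file.path(dir, "variants.tsv"), stamp)
  dos <- as.data.frame(cohort$dosage)
  write_stamped_tsv(dos, file.path(dir, "dosage.tsv"), stamp)
  invisible(dir)
}
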