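# Variant/cohort-level QC and genomic control on summary statistics.

# median chi-square of the null 1df test; hard-coded to 5 decimals
.CHISQ1_MEDIAN <- 0.45494

#' Genomic-control inflation factor
#'
#' Lambda is the median observed 1df chi-square divided by the null median
#' (0.45494).
#'
#' @param p vector of 1df p-values (alternatively supply `chi2`).
#' @param chi2 optional vector of 1df chi-square statistics.
#' @return lambda (>= 0).
#' @export
gc_lambda <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p)) stop("supply p or chi2")
    chi2 <- stats::qchisq(p, 1, lower.tail = FALSE)
  }
  stats::median(chi2) / .CHISQ1_MEDIAN
}

#' Variant-level QC filters
#'
#' Removes variants with imputation quality below 0.5 or with
#' MAC x imputation-quality (the effective degrees of freedom of an imputed
#' variant) below 20 in the exposed, unexposed or total sample.
#'
#' @param stats summary-statistics data frame (see [gwis()]).
#' @param min_impq,min_mac_r2 filter thresholds (defaults 0.5 and 20).
#' @return list with `stats` (retained rows) and `report` (per-filter
#'   removal counts; removals sum to rows in minus rows out).
#' @export
filter_variants <- function(stats, min_impq = 0.5, min_mac_r2 = 20) {
  need <- c("impq", "mac_exposed", "mac_unexposed", "mac_total")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad_impq <- stats$impq < min_impq
  bad_mac <- stats$mac_exposed * stats$impq < min_mac_r2 |
    stats$mac_unexposed * stats$impq < min_mac_r2 |
    stats$mac_total * stats$impq < min_mac_r2
  drop <- bad_impq | bad_mac
  list(stats = stats[!drop, , drop = FALSE],
       report = list(n_in = nrow(stats), n_out = sum(!drop),
                     n_removed = sum(drop),
                     n_low_impq = sum(bad_impq),
                     n_low_mac_r2 = sum(bad_mac & !bad_impq)))
}

#' Cohort inclusion rule for meta-analysis
#'
#' A cohort/slice is excluded when it has fewer than 100 individuals or
#' fewer than 50 in either the exposed or unexposed group.
#'
#' @param n,n_exposed,n_unexposed sample sizes (vectors accepted).
#' @param min_n,min_stratum thresholds (defaults 100 and 50).
#' @return data frame with `include` (logical) and `reason`.
#' @export
filter_cohorts <- function(n, n_exposed, n_unexposed,
                           min_n = 100, min_stratum = 50) {
  reason <- rep("", length(n))
  reason[n < min_n] <- "fewer than 100 individuals"
  small <- n >= min_n & (n_exposed < min_stratum | n_unexposed < min_stratum)
  reason[small] <- "fewer than 50 in an exposure group"
  data.frame(include = reason == "", reason = reason,
             stringsAsFactors = FALSE)
}

#' Genomic-control correction of a summary-statistics file
#'
#' Computes lambda for the 1df interaction test, the genetic main-effect test
#' and the marginal test.  For each test with lambda > 1 the chi-square is
#' divided by lambda, i.e. the SE is inflated by sqrt(lambda), and p-values
#' are recomputed; lambda < 1 leaves the statistics unchanged (no deflation).
#' The 2df joint statistic is rebuilt from the corrected components, with the
#' main/interaction covariance scaled by sqrt(lambda_G * lambda_int).
#'
#' @param stats summary-statistics data frame (>= 100 variants recommended
#'   for a stable median).
#' @return list with corrected `stats` and `lambda` (named: `int`, `main`,
#'   `marg`).
#' @export
genomic_control <- function(stats) {
  if (nrow(stats) == 0L) stop("empty summary statistics")
  z2_int <- (stats$beta_int / stats$se_int)^2
  z2_main <- (stats$beta_G / stats$se_G)^2
  z2_marg <- (stats$beta_marg / stats$se_marg)^2
  lam <- c(int = gc_lambda(chi2 = z2_int),
           main = gc_lambda(chi2 = z2_main),
           marg = gc_lambda(chi2 = z2_marg))
  infl <- pmax(lam, 1)
  stats$se_int <- stats$se_int * sqrt(infl["int"])
  stats$se_G <- stats$se_G * sqrt(infl["main"])
  stats$se_marg <- stats$se_marg * sqrt(infl["marg"])
  stats$cov_G_int <- stats$cov_G_int * sqrt(infl["main"] * infl["int"])
  stats$p_int <- stats::pchisq((stats$beta_int / stats$se_int)^2, 1,
                               lower.tail = FALSE)
  stats$p_marg <- stats::pchisq((stats$beta_marg / stats$se_marg)^2, 1,
                                lower.tail = FALSE)
  chi2 <- .chi2_2df(stats$beta_G, stats$beta_int, stats$se_G, stats$se_int,
                    stats$cov_G_int)
  stats$p_2df <- stats::pchisq(chi2, 2, lower.tail = FALSE)
  list(stats = stats, lambda = lam)
}

# 2df Wald chi-square from components (vectorized); NA when the 2x2
# covariance is not positive-definite
.chi2_2df <- function(beta_G, beta_int, se_G, se_int, cov) {
  det <- se_G^2 * se_int^2 - cov^2
  chi2 <- (beta_G^2 * se_int^2 - 2 * beta_G * beta_int * cov +
             beta_int^2 * se_G^2) / det
  chi2[det <= 0] <- NA_real_
  chi2
}

#' Align effect alleles across cohort summary files
#'
#' Orients every file to the first file's effect/other alleles per variant:
#' swapped alleles flip the signs of all betas and the frequency; unresolvable
#' allele pairs are dropped.  Strand-ambiguous variants (A/T, C/G) are kept
#' but listed in the report.
#'
#' @param stats_list list of summary-statistics data frames.
#' @return list with `stats_list` (aligned) and `report` (per-file flip/drop
#'   counts, ambiguous variant ids).
#' @export
align_alleles <- function(stats_list) {
  if (length(stats_list) < 2L)
    return(list(stats_list = stats_list, report = list(n_flipped = 0L,
                                                       n_dropped = 0L,
                                                       ambiguous = character(0))))
  ref <- stats_list[[1]]
  key <- stats::setNames(paste(ref$effect_allele, ref$other_allele), ref$id)
  amb <- ref$id[paste0(ref$effect_allele, ref$other_allele) %in%
                  c("AT", "TA", "CG", "GC")]
  n_flip <- 0L; n_drop <- 0L
  for (i in seq_along(stats_list)[-1]) {
    s <- stats_list[[i]]
    refpair <- key[s$id]
    pair <- paste(s$effect_allele, s$other_allele)
    swapped <- paste(s$other_allele, s$effect_allele)
    ok <- is.na(refpair) | pair == refpair
    flip <- !is.na(refpair) & swapped == refpair & pair != refpair
    bad <- !ok & !flip
    if (any(flip)) {
      for (col in c("beta_G", "beta_int", "beta_marg"))
        s[[col]][flip] <- -s[[col]][flip]
      s$freq[flip] <- 1 - s$freq[flip]
      ea <- s$effect_allele[flip]
      s$effect_allele[flip] <- s$other_allele[flip]
      s$other_allele[flip] <- ea
    }
    n_flip <- n_flip + sum(flip)
    n_drop <- n_drop + sum(bad)
    stats_list[[i]] <- s[!bad, , drop = FALSE]
  }
  list(stats_list = stats_list,
       report = list(n_flipped = n_flip, n_dropped = n_drop,
                     ambiguous = amb))
}

#' Full QC of one cohort's summary statistics
#'
#' Variant filters followed by genomic control; returns the cleaned table and
#' a QC report suitable for JSON serialization.
#'
#' @param stats summary-statistics data frame.
#' @param n,n_exposed,n_unexposed slice sample sizes for the cohort filter
#'   (taken from the stats table when omitted).
#' @return list with `stats`, `include` (cohort verdict), and `report`.
#' @export
qc_summary_stats <- function(stats, n = NULL, n_exposed = NULL,
                             n_unexposed = NULL) {
  if (is.null(n)) n <- stats$n[1]
  if (is.null(n_exposed)) n_exposed <- stats$n_exposed[1]
  if (is.null(n_unexposed)) n_unexposed <- stats$n_unexposed[1]
  verdict <- filter_cohorts(n, n_exposed, n_unexposed)
  fv <- filter_variants(stats)
  gcr <- if (nrow(fv$stats)) genomic_control(fv$stats)
         else list(stats = fv$stats, lambda = c(int = NA, main = NA,
                                                marg = NA))
  list(stats = gcr$stats, include = verdict$include[1],
       report = list(cohort = as.list(verdict[1, ]),
                     variant_filters = fv$report,
                     lambda = as.list(gcr$lambda)))
}
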