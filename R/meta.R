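# Fixed-effects pooling of per-cohort summary statistics: scalar
# inverse-variance weighting for the 1df tests, inverse-covariance weighting
# for the (beta_G, beta_GxAlc) pair, Cochran heterogeneity.

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Weights `1/se^2`; pooled estimate is the weighted mean, pooled SE the
#' square root of the inverse total weight, p-value from the normal
#' approximation.
#'
#' @param beta,se per-study estimates and standard errors (`se > 0`).
#' @return list with `beta`, `se`, `p`, `k`.
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) < 1L) stop("need at least one study")
  if (any(se <= 0)) stop("standard errors must be > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s,
       p = stats::pchisq((b / s)^2, 1, lower.tail = FALSE), k = length(beta))
}

#' Joint 2df fixed-effects meta-analysis of (main, interaction) effects
#'
#' Inverse-covariance (multivariate) pooling: the pooled precision is the sum
#' of per-study precisions, the pooled vector the precision-weighted mean,
#' and the 2df Wald chi-square is the pooled vector's quadratic form in the
#' pooled precision.
#'
#' @param B k x 2 matrix of per-study (beta_G, beta_int).
#' @param covs list of k 2x2 positive-definite covariance matrices.
#' @return list with `beta` (length 2), `vcov` (2x2), `chi2`, `p`, `k`; NULL
#'   if any covariance is not positive-definite.
#' @export
joint_meta_2df <- function(B, covs) {
  B <- rbind(B)
  k <- nrow(B)
  P <- matrix(0, 2, 2); Pb <- c(0, 0)
  for (i in seq_len(k)) {
    O <- covs[[i]]
    det <- O[1, 1] * O[2, 2] - O[1, 2]^2
    if (!is.finite(det) || det <= 0 || O[1, 1] <= 0) return(NULL)
    Oi <- matrix(c(O[2, 2], -O[1, 2], -O[1, 2], O[1, 1]), 2, 2) / det
    P <- P + Oi
    Pb <- Pb + drop(Oi %*% B[i, ])
  }
  V <- solve(P)
  b <- drop(V %*% Pb)
  chi2 <- drop(t(b) %*% P %*% b)
  list(beta = b, vcov = V, chi2 = chi2,
       p = stats::pchisq(chi2, 2, lower.tail = FALSE), k = k)
}

#' Cochran's Q heterogeneity test
#'
#' @param beta,se per-study estimates (k >= 2; returns NAs otherwise).
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) return(list(Q = NA_real_, df = NA_integer_, p = NA_real_))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b)^2)
  list(Q = Q, df = k - 1L,
       p = stats::pchisq(Q, k - 1L, lower.tail = FALSE))
}

# Pool a list of per-source summary tables by variant id.  Sources may be
# cohorts (within-population stage) or population-level records (CPMA).
.pool_records <- function(stats_list, min_sources = 2L, label = "meta") {
  ids <- sort(unique(unlist(lapply(stats_list, `[[`, "id"))))
  rows <- lapply(ids, function(v) {
    sub <- do.call(rbind, lapply(stats_list, function(s)
      s[s$id == v, , drop = FALSE]))
    if (nrow(sub) < min_sources) return(NULL)
    iv <- ivw_meta(sub$beta_int, sub$se_int)
    mg <- ivw_meta(sub$beta_marg, sub$se_marg)
    # the 2df pool uses the joint-pooled components where an earlier pooling
    # stage provides them (population records), so CPMA preserves the 2df
    # statistic of a single contributing population
    bi2 <- if ("beta_int_joint" %in% names(sub)) sub$beta_int_joint
           else sub$beta_int
    si2 <- if ("se_int_joint" %in% names(sub)) sub$se_int_joint
           else sub$se_int
    covs <- lapply(seq_len(nrow(sub)), function(i)
      matrix(c(sub$se_G[i]^2, sub$cov_G_int[i],
               sub$cov_G_int[i], si2[i]^2), 2, 2))
    jt <- joint_meta_2df(cbind(sub$beta_G, bi2), covs)
    if (is.null(jt)) return(NULL)
    het <- cochran_q(sub$beta_int, sub$se_int)
    k_studies <- if ("k_studies" %in% names(sub)) sum(sub$k_studies)
                 else nrow(sub)
    data.frame(
      id = v, chrom = sub$chrom[1], pos = sub$pos[1],
      effect_allele = sub$effect_allele[1],
      other_allele = sub$other_allele[1],
      freq = sum(sub$freq * sub$n) / sum(sub$n),
      n = sum(sub$n), k_studies = k_studies, k_sources = nrow(sub),
      beta_G = jt$beta[1], se_G = sqrt(jt$vcov[1, 1]),
      beta_int = iv$beta, se_int = iv$se, p_int = iv$p,
      beta_int_joint = jt$beta[2], se_int_joint = sqrt(jt$vcov[2, 2]),
      cov_G_int = jt$vcov[1, 2],
      chi2_2df = jt$chi2, p_2df = jt$p,
      beta_marg = mg$beta, se_marg = mg$se, p_marg = mg$p,
      Q = het$Q, df_Q = het$df, p_het = het$p,
      population = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  class(out) <- c("gwis_meta", class(out))
  attr(out, "label") <- label
  out
}

#' Within-population meta-analysis of cohort summary statistics
#'
#' Aligns effect alleles to the first cohort's orientation, then pools the
#' cohorts of each population per variant: IVW for the interaction and
#' marginal effects, inverse-covariance 2df pooling of (beta_G, beta_int),
#' and Cochran heterogeneity of the interaction effect across cohorts.
#' Variants contributed by fewer than `min_studies` cohorts are dropped.
#'
#' @param stats_list list of cohort summary-statistics data frames.
#' @param populations character vector, one population label per cohort
#'   (AFR, BRA, EAS, EUR, HIS, SAS).
#' @param min_studies minimum contributing cohorts per variant (default 2).
#' @return named list of `gwis_meta` data frames, one per population.
#' @export
meta_by_population <- function(stats_list, populations, min_studies = 2L) {
  stopifnot(length(stats_list) == length(populations))
  al <- align_alleles(stats_list)
  stats_list <- al$stats_list
  out <- list()
  for (pop in unique(populations)) {
    grp <- stats_list[populations == pop]
    out[[pop]] <- .pool_records(grp, min_sources = min_studies, label = pop)
  }
  out
}

#' Cross-population meta-analysis (CPMA)
#'
#' Pools population-level meta-analysis records (not raw cohorts) by the same
#' fixed-effects estimators, and attaches per-variant heterogeneity of the
#' interaction effect across populations.
#'
#' @param pop_metas named list of population `gwis_meta` tables.
#' @param min_populations minimum contributing populations per variant
#'   (default 1; the CPMA reporting rule separately requires >= 2).
#' @return a `gwis_meta` data frame labelled `"CPMA"`, with `k_populations`.
#' @export
cross_population_meta <- function(pop_metas, min_populations = 1L) {
  pop_metas <- pop_metas[vapply(pop_metas, nrow, 0L) > 0L]
  cp <- .pool_records(pop_metas, min_sources = min_populations,
                      label = "CPMA")
  if (nrow(cp)) names(cp)[names(cp) == "k_sources"] <- "k_populations"
  cp
}

#' @export
print.gwis_meta <- function(x, ...) {
  cat("GWIS meta-analysis [", attr(x, "label"), "]:", nrow(x),
      "variants, max N =", if (nrow(x)) max(x$n) else 0, "\n")
  if (nrow(x)) {
    top <- x[order(x$p_int)[seq_len(min(3, nrow(x)))],
             c("id", "beta_int", "se_int", "p_int", "p_2df", "n")]
    print(format(as.data.frame(top), digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Reporting rule for meta-analysis results
#'
#' Population-specific results are reportable with more than 5,000
#' individuals in AFR, BRA, HIS and SAS, or more than 20,000 in EUR and EAS,
#' with at least two contributing studies per variant; cross-population
#' results require more than 20,000 individuals and at least two contributing
#' populations.
#'
#' @param records a `gwis_meta` table.
#' @param thresholds named minimum-N vector by population (strict `>`).
#' @param min_studies,min_populations contribution minima.
#' @return `records` with a logical `reportable` column.
#' @export
reporting_filter <- function(records,
                             thresholds = c(AFR = 5000, BRA = 5000,
                                            HIS = 5000, SAS = 5000,
                                            EUR = 20000, EAS = 20000,
                                            CPMA = 20000),
                             min_studies = 2L, min_populations = 2L) {
  if (!nrow(records)) { records$reportable <- logical(0); return(records) }
  pop <- records$population
  unknown <- setdiff(unique(pop), names(thresholds))
  if (length(unknown))
    stop("no reporting threshold configured for: ",
         paste(unknown, collapse = ", "))
  ok_n <- records$n > thresholds[pop]
  ok_k <- if ("k_populations" %in% names(records))
    records$k_populations >= min_populations
  else records$k_studies >= min_studies
  records$reportable <- unname(ok_n & ok_k)
  records
}
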