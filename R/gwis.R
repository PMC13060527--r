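# Core per-variant regression engine.  Both models are ordinary least squares
# solved through the normal equations with a Cholesky factorization; the
# model-based (homoscedastic) covariance of the coefficients is
# sigma^2 (X'X)^-1 with sigma^2 = RSS/(n - p).

# Solve OLS for design X and outcome y.  Returns NULL on a singular design.
.ols <- function(X, y, robust = FALSE) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) return(NULL)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  # guard against numerically singular but chol-factorable designs
  if (min(diag(ch))^2 < 1e-10 * max(diag(XtX))) return(NULL)
  beta <- drop(chol2inv(ch) %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  XtXinv <- chol2inv(ch)
  V <- if (robust) {
    Xe <- X * res
    XtXinv %*% crossprod(Xe) %*% XtXinv
  } else {
    (rss / (n - p)) * XtXinv
  }
  list(beta = beta, vcov = V, n = n, rss = rss, sigma2 = rss / (n - p))
}

#' Fit the joint main + interaction model to one variant
#'
#' Ordinary least squares for
#' \deqn{E(Y) = \beta_0 + \beta_{Alc} Alc + \beta_G G +
#'   \beta_{G\times Alc} G \cdot Alc + \beta_C C}
#' with model-based standard errors.  Reports the genetic main effect, the
#' interaction effect, their covariance, the 1df Wald test of the interaction
#' and the 2df joint Wald chi-square of \eqn{(\beta_G, \beta_{G\times Alc})}
#' using their 2x2 covariance.
#'
#' @param y outcome (mmHg).
#' @param g genotype dosage in \[0, 2\].
#' @param alc binary exposure (0/1).
#' @param covars numeric matrix of covariates (may be NULL).
#' @param robust use a heteroscedasticity-consistent (HC0) covariance instead
#'   of the model-based one; off by default.
#' @param covariate_alc_interactions also include covariate-by-exposure
#'   product terms; off by default.
#' @return list with `beta_G`, `se_G`, `beta_int`, `se_int`, `cov_G_int`,
#'   `p_int`, `chi2_2df`, `p_2df`, `n`, or `NULL` if the design is singular
#'   (monomorphic dosage, empty exposure stratum, collinearity).
#' @export
fit_model1 <- function(y, g, alc, covars = NULL, robust = FALSE,
                       covariate_alc_interactions = FALSE) {
  X <- cbind(1, alc, covars)
  if (covariate_alc_interactions && !is.null(covars))
    X <- cbind(X, covars * alc)
  X <- cbind(X, g, g * alc)
  fit <- .ols(X, y, robust)
  if (is.null(fit)) return(NULL)
  p <- ncol(X)
  idx <- c(p - 1L, p)
  b <- fit$beta[idx]
  V <- fit$vcov[idx, idx]
  z_int <- b[2] / sqrt(V[2, 2])
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) return(NULL)
  chi2 <- drop(t(b) %*% Vinv %*% b)
  list(beta_G = b[1], se_G = sqrt(V[1, 1]),
       beta_int = b[2], se_int = sqrt(V[2, 2]),
       cov_G_int = V[1, 2],
       p_int = stats::pchisq(z_int^2, 1, lower.tail = FALSE),
       chi2_2df = chi2,
       p_2df = stats::pchisq(chi2, 2, lower.tail = FALSE),
       n = fit$n)
}

#' Fit the marginal (main-effect-only) model to one variant
#'
#' OLS for \eqn{E(Y) = \beta_0 + \beta_G G + \beta_C C}: the standard GWAS
#' model, used both for reporting marginal effects and as step 1 of the
#' 2-step interaction screen.
#'
#' @inheritParams fit_model1
#' @return list with `beta_marg`, `se_marg`, `p_marg`, `n`, or `NULL` on a
#'   singular design.
#' @export
fit_model2 <- function(y, g, covars = NULL, robust = FALSE) {
  X <- cbind(1, covars, g)
  fit <- .ols(X, y, robust)
  if (is.null(fit)) return(NULL)
  p <- ncol(X)
  z <- fit$beta[p] / sqrt(fit$vcov[p, p])
  list(beta_marg = fit$beta[p], se_marg = sqrt(fit$vcov[p, p]),
       p_marg = stats::pchisq(z^2, 1, lower.tail = FALSE),
       n = fit$n)
}

#' Genome-wide interaction scan of one analysis slice
#'
#' Fits the joint main + interaction model (Model 1) and the marginal model
#' (Model 2) to every variant for one (trait, contrast, sex group) slice,
#' producing the per-variant summary statistics consumed by QC and
#' meta-analysis: effect sizes, model-based SEs, the main/interaction
#' covariance, the 1df interaction, 2df joint and marginal Wald p-values,
#' allele metadata, stratum sample sizes and stratum minor-allele counts
#' (MAC = sum of min(dosage, 2 - dosage), dosages never rounded).
#'
#' @param slice one element of [build_slices()].
#' @param dosage cohort dosage matrix (rows aligned with the harmonized
#'   cohort; the slice's `rows` index selects its individuals).
#' @param variant_meta variant metadata (`id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `impq`).
#' @param robust,covariate_alc_interactions passed to [fit_model1()].
#' @return object of class `gwis`: the per-variant statistics table plus the
#'   slice labels and a log of skipped variants with reasons.
#' @export
gwis <- function(slice, dosage, variant_meta, robust = FALSE,
                 covariate_alc_interactions = FALSE) {
  d <- slice$data
  D <- dosage[slice$rows, , drop = FALSE]
  covars <- as.matrix(d[, setdiff(names(d), c("id", "Y", "Alc")),
                        drop = FALSE])
  if (ncol(covars) == 0L) covars <- NULL
  y <- d$Y; alc <- d$Alc
  V <- ncol(D)
  stopifnot(V == nrow(variant_meta))
  exp_idx <- alc == 1
  out <- vector("list", V)
  skipped <- character(0); skip_reason <- character(0)
  for (j in seq_len(V)) {
    g <- D[, j]
    if (stats::var(g) == 0) {
      skipped <- c(skipped, variant_meta$id[j])
      skip_reason <- c(skip_reason, "monomorphic dosage")
      next
    }
    m1 <- fit_model1(y, g, alc, covars, robust, covariate_alc_interactions)
    m2 <- fit_model2(y, g, covars, robust)
    if (is.null(m1) || is.null(m2)) {
      skipped <- c(skipped, variant_meta$id[j])
      skip_reason <- c(skip_reason, "singular design")
      next
    }
    mac <- pmin(g, 2 - g)
    out[[j]] <- data.frame(
      id = variant_meta$id[j], chrom = variant_meta$chrom[j],
      pos = variant_meta$pos[j],
      effect_allele = variant_meta$effect_allele[j],
      other_allele = variant_meta$other_allele[j],
      freq = mean(g) / 2,
      n = length(y), n_exposed = sum(exp_idx),
      n_unexposed = sum(!exp_idx),
      beta_G = m1$beta_G, se_G = m1$se_G,
      beta_int = m1$beta_int, se_int = m1$se_int,
      cov_G_int = m1$cov_G_int,
      p_int = m1$p_int, p_2df = m1$p_2df,
      beta_marg = m2$beta_marg, se_marg = m2$se_marg, p_marg = m2$p_marg,
      impq = variant_meta$impq[j],
      mac_exposed = sum(mac[exp_idx]),
      mac_unexposed = sum(mac[!exp_idx]),
      mac_total = sum(mac),
      stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(stats)) stats <- .empty_variant_stats()
  res <- list(stats = stats, trait = slice$trait, contrast = slice$contrast,
              sex_group = slice$sex_group, n = length(y),
              n_exposed = sum(exp_idx), n_unexposed = sum(!exp_idx),
              skipped = data.frame(id = skipped, reason = skip_reason,
                                   stringsAsFactors = FALSE))
  class(res) <- "gwis"
  res
}

.empty_variant_stats <- function() {
  data.frame(id = character(0), chrom = integer(0), pos = numeric(0),
             effect_allele = character(0), other_allele = character(0),
             freq = numeric(0), n = integer(0), n_exposed = integer(0),
             n_unexposed = integer(0), beta_G = numeric(0), se_G = numeric(0),
             beta_int = numeric(0), se_int = numeric(0),
             cov_G_int = numeric(0), p_int = numeric(0), p_2df = numeric(0),
             beta_marg = numeric(0), se_marg = numeric(0),
             p_marg = numeric(0), impq = numeric(0),
             mac_exposed = numeric(0), mac_unexposed = numeric(0),
             mac_total = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.gwis <- function(x, ...) {
  cat("GWIS scan:", x$trait, "~", x$contrast, "(", x$sex_group, ")\n")
  cat("  n =", x$n, "(", x$n_exposed, "exposed /", x$n_unexposed,
      "unexposed ),", nrow(x$stats), "variants,",
      nrow(x$skipped), "skipped\n")
  if (nrow(x$stats)) {
    top <- x$stats[order(x$stats$p_int)[seq_len(min(3, nrow(x$stats)))],
                   c("id", "beta_G", "beta_int", "p_int", "p_2df")]
    cat("  top interaction signals:\n")
    print(format(top, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.gwis <- function(object, ...) {
  s <- object$stats
  out <- list(
    trait = object$trait, contrast = object$contrast,
    sex_group = object$sex_group, n = object$n,
    n_variants = nrow(s), n_skipped = nrow(object$skipped),
    lambda_int = if (nrow(s) >= 100) gc_lambda(s$p_int) else NA_real_,
    lambda_marg = if (nrow(s) >= 100) gc_lambda(s$p_marg) else NA_real_,
    min_p_int = if (nrow(s)) min(s$p_int) else NA_real_,
    min_p_2df = if (nrow(s)) min(s$p_2df) else NA_real_)
  class(out) <- "summary.gwis"
  out
}

#' @export
print.summary.gwis <- function(x, ...) {
  cat("GWIS scan summary:", x$trait, "~", x$contrast, "(", x$sex_group, ")\n")
  cat("  n =", x$n, ";", x$n_variants, "variants analysed,",
      x$n_skipped, "skipped\n")
  cat("  lambda_GC (interaction):", format(x$lambda_int, digits = 4),
      " lambda_GC (marginal):", format(x$lambda_marg, digits = 4), "\n")
  cat("  min P_GxAlc:", format(x$min_p_int, digits = 3),
      " min P_2df:", format(x$min_p_2df, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.gwis <- function(object, ...) {
  s <- object$stats
  m <- as.matrix(s[, c("beta_G", "beta_int", "beta_marg")])
  rownames(m) <- s$id
  m
}

#' QQ plot of a GWIS scan's p-values
#'
#' @param x a `gwis` object.
#' @param which which test's p-values to plot.
#' @param ... passed to [plot()].
#' @export
plot.gwis <- function(x, which = c("interaction", "2df", "marginal"), ...) {
  which <- match.arg(which)
  p <- switch(which, interaction = x$stats$p_int, `2df` = x$stats$p_2df,
              marginal = x$stats$p_marg)
  n <- length(p)
  obs <- -log10(sort(p))
  exp <- -log10(stats::ppoints(n))
  plot(exp, obs, xlab = "expected -log10(p)", ylab = "observed -log10(p)",
       main = paste0("QQ (", which, "): ", x$trait, " ~ ", x$contrast),
       ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Run the GWIS engine over many slices
#'
#' @param cohort a harmonized cohort.
#' @param slices output of [build_slices()]; defaults to the full grid.
#' @param out optional directory: each scan is also written as a
#'   summary-statistics TSV named `{trait}.{contrast}.{sexgroup}.tsv`.
#' @param ... passed to [gwis()].
#' @return named list of `gwis` objects (flagged/degenerate slices skipped
#'   with a message).
#' @export
run_gwis <- function(cohort, slices = build_slices(cohort), out = NULL, ...) {
  res <- list()
  for (nm in names(slices)) {
    sl <- slices[[nm]]
    if (sl$flagged) {
      message("slice ", nm, ": empty exposure arm, skipped")
      next
    }
    sc <- gwis(sl, cohort$dosage, cohort$variant_meta, ...)
    res[[nm]] <- sc
    if (!is.null(out)) {
      if (!dir.exists(out)) dir.create(out, recursive = TRUE)
      write_summary_stats(sc$stats, file.path(out, paste0(nm, ".tsv")))
    }
  }
  res
}
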