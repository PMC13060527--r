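# Tiered discovery on meta-analysed GWIS results: FDR, the four significance
# approaches, LD clumping into loci, novelty against a known-loci catalog,
# heterogeneity screens, effect decomposition and the enrichment test.

#' Benjamini-Hochberg discovery flags
#'
#' Step-up FDR control at level `q` (via [stats::p.adjust()]).
#'
#' @param p p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return logical vector of discoveries.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  stats::p.adjust(p, method = "BH") <= q
}

#' Effective number of independent tests (simpleM-style)
#'
#' Eigen-decomposes the correlation matrix of the given dosage columns and
#' returns the smallest number of leading eigenvalues explaining at least
#' `var_explained` of the total variance.
#'
#' @param dosage n x m dosage matrix of the variants of interest (m >= 1), or
#'   an m x m correlation matrix via `is_cor = TRUE`.
#' @param var_explained explained-variance threshold (default 0.995).
#' @param is_cor interpret `dosage` as a correlation matrix.
#' @return integer Meff (0 for zero variants).
#' @export
meff_simpleM <- function(dosage, var_explained = 0.995, is_cor = FALSE) {
  if (is.null(dosage) || NCOL(dosage) == 0L) return(0L)
  if (NCOL(dosage) == 1L) return(1L)
  C <- if (is_cor) dosage else stats::cor(dosage)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  which(cumsum(ev) / sum(ev) >= var_explained)[1]
}

# squared correlation between two panel columns; NA if either is missing
.panel_r2 <- function(panel, a, b) {
  if (is.null(panel) || !(a %in% colnames(panel)) ||
      !(b %in% colnames(panel))) return(NA_real_)
  stats::cor(panel[, a], panel[, b])^2
}

#' Clump significant variants into loci
#'
#' Greedy clumping by ascending p-value: each unclaimed variant in turn
#' becomes a lead and claims all unclaimed variants on the same chromosome
#' with LD r-squared >= `r2_min` against it; where r-squared is unavailable
#' (variant missing from the panel) a variant is claimed when it lies within
#' `max_dist` bp of the lead, so panel-missing variants form independent loci
#' only when more than 500 kb from every formed locus.  Ties in p are broken
#' by smaller position, then lexicographic allele.
#'
#' @param records data frame with `id`, `chrom`, `pos`, `effect_allele` and
#'   the p-value column named by `p_col`.
#' @param panel dosage matrix with variant-id column names (the LD reference);
#'   may be NULL (pure distance clumping).
#' @param p_col which p-value defines lead ranking (default `"p_int"`).
#' @param r2_min LD threshold (default 0.1).
#' @param max_dist distance fallback in bp (default 500000, inclusive).
#' @return data frame of loci: `lead`, `chrom`, `start`, `end`, `n_members`,
#'   `members` (comma-joined ids), `p_lead`.
#' @export
clump_loci <- function(records, panel = NULL, p_col = "p_int",
                       r2_min = 0.1, max_dist = 5e5) {
  if (!nrow(records))
    return(data.frame(lead = character(0), chrom = integer(0),
                      start = numeric(0), end = numeric(0),
                      n_members = integer(0), members = character(0),
                      p_lead = numeric(0), stringsAsFactors = FALSE))
  ord <- order(records[[p_col]], records$pos, records$effect_allele)
  rec <- records[ord, , drop = FALSE]
  claimed <- rep(FALSE, nrow(rec))
  loci <- list()
  for (i in seq_len(nrow(rec))) {
    if (claimed[i]) next
    lead <- rec[i, ]
    members <- i
    for (j in seq_len(nrow(rec))) {
      if (claimed[j] || j == i || rec$chrom[j] != lead$chrom) next
      r2 <- .panel_r2(panel, lead$id, rec$id[j])
      hit <- if (is.na(r2)) abs(rec$pos[j] - lead$pos) <= max_dist
             else r2 >= r2_min
      if (hit) members <- c(members, j)
    }
    claimed[members] <- TRUE
    loci[[length(loci) + 1L]] <- data.frame(
      lead = lead$id, chrom = lead$chrom,
      start = min(rec$pos[members]), end = max(rec$pos[members]),
      n_members = length(members),
      members = paste(rec$id[members], collapse = ","),
      p_lead = lead[[p_col]], stringsAsFactors = FALSE)
  }
  do.call(rbind, loci)
}

#' Classify loci as novel or known
#'
#' A locus is novel when every member variant is more than `max_dist` bp
#' (inclusive bound: exactly 500 kb counts as near) from every catalogued
#' variant, or is in linkage equilibrium (r-squared < `r2_min`) with all
#' nearby catalogued variants.  A nearby catalogued variant with no available
#' r-squared marks the locus as known.
#'
#' @param loci output of [clump_loci()].
#' @param known catalog data frame with `chrom`, `pos` and (for LD lookup)
#'   `id`; zero rows mark everything novel, with a warning.
#' @param records the records the loci were clumped from (for member
#'   positions).
#' @param panel optional dosage panel for r-squared lookups.
#' @param r2_min,max_dist thresholds as in [clump_loci()].
#' @return `loci` with a logical `novel` column.
#' @export
classify_novelty <- function(loci, known, records, panel = NULL,
                             r2_min = 0.1, max_dist = 5e5) {
  if (!nrow(loci)) { loci$novel <- logical(0); return(loci) }
  if (is.null(known) || !nrow(known)) {
    warning("empty known-loci catalog: all loci classified novel")
    loci$novel <- TRUE
    return(loci)
  }
  loci$novel <- vapply(seq_len(nrow(loci)), function(i) {
    ids <- strsplit(loci$members[i], ",", fixed = TRUE)[[1]]
    mem <- records[match(ids, records$id), , drop = FALSE]
    for (r in seq_len(nrow(mem))) {
      near <- known$chrom == mem$chrom[r] &
        abs(known$pos - mem$pos[r]) <= max_dist
      for (kk in which(near)) {
        r2 <- if ("id" %in% names(known))
          .panel_r2(panel, mem$id[r], known$id[kk]) else NA_real_
        if (is.na(r2) || r2 >= r2_min) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  loci
}

#' Two-sample Z-test for sex heterogeneity of interaction effects
#'
#' Assumes independence of the male and female estimates (conservative):
#' `Z = (beta_M - beta_F) / sqrt(se_M^2 + se_F^2)`, two-sided p, significance
#' at the Bonferroni level `0.05 / n_tests`.
#'
#' @param beta_M,se_M,beta_F,se_F sex-specific estimates (vectorized).
#' @param n_tests Bonferroni denominator (default 1).
#' @return data frame with `Z`, `p`, `significant`.
#' @export
sex_het_test <- function(beta_M, se_M, beta_F, se_F, n_tests = 1L) {
  Z <- (beta_M - beta_F) / sqrt(se_M^2 + se_F^2)
  p <- 2 * stats::pnorm(-abs(Z))
  data.frame(Z = Z, p = p, significant = p < 0.05 / n_tests)
}

#' Decompose a joint fit into exposure-stratum genetic effects
#'
#' The genetic effect among the unexposed is the main effect,
#' `b0 = beta_G`; among the exposed it is `b1 = beta_G + beta_GxAlc` with
#' `Var(b1) = se_G^2 + se_int^2 + 2 cov`.  The fold-change `b1/b0` quantifies
#' how much larger the genetic effect is under exposure (about 6 for the
#' 12q24/BRAP-type signal in current drinkers).
#'
#' @param beta_G,beta_int,se_G,se_int,cov joint-model components
#'   (vectorized).
#' @return data frame with `b0`, `b1`, `se_b0`, `se_b1`, `fold` (`NA` when
#'   `|b0|` < 1e-12).  Errors if any implied Var(b1) is negative.
#' @export
decompose_effects <- function(beta_G, beta_int, se_G, se_int, cov) {
  v1 <- se_G^2 + se_int^2 + 2 * cov
  if (any(v1 < 0, na.rm = TRUE))
    stop("negative Var(b1): inconsistent SE/covariance inputs")
  b0 <- beta_G
  b1 <- beta_G + beta_int
  fold <- ifelse(abs(b0) < 1e-12, NA_real_, b1 / b0)
  data.frame(b0 = b0, b1 = b1, se_b0 = se_G, se_b1 = sqrt(v1), fold = fold)
}

#' Exact binomial enrichment test
#'
#' One-sided upper tail `P(X >= k)` for `X ~ Binomial(n, p0)`, computed in
#' log space so extreme tails (down to ~1e-300) remain accurate.  Used to
#' test whether loci are enriched for nominally significant interactions.
#'
#' @param k observed count of successes (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability (default 0.05).
#' @return the tail p-value.
#' @export
enrichment_test <- function(k, n, p0 = 0.05) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (k == 0) return(1)
  exp(stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE))
}

#' Approach A: genome-wide significant interactions
#'
#' Flags variants with `P_GxAlc < gw` that also pass BH FDR at `q` within the
#' scan.
#'
#' @param records a `gwis_meta` table (one scan).
#' @param gw genome-wide threshold (default 5e-8).
#' @param q FDR level (default 0.05).
#' @return logical vector of tier-A hits.
#' @export
approach_A <- function(records, gw = 5e-8, q = 0.05) {
  if (!nrow(records)) return(logical(0))
  records$p_int < gw & bh_fdr(records$p_int, q)
}

#' Approach B: 2-step interaction screen
#'
#' Step 1 filters variants with marginal `P < p_marg_max`; step 2 tests the
#' filtered variants' interaction p-values at the Bonferroni level
#' `0.05 / Meff` (Meff from simpleM PCA of the filtered variants' dosage
#' correlation) together with BH FDR among the filtered set.  Valid because
#' the marginal and interaction tests are statistically independent.
#'
#' @param records a `gwis_meta` table (one scan).
#' @param panel dosage panel for the Meff computation.
#' @param p_marg_max step-1 threshold (default 1e-5).
#' @param q FDR level; `var_explained` passed to [meff_simpleM()].
#' @return list with `hits` (logical over `records`), `meff`, `n_filtered`.
#' @export
approach_B <- function(records, panel, p_marg_max = 1e-5, q = 0.05,
                       var_explained = 0.995) {
  hits <- rep(FALSE, nrow(records))
  filt <- which(records$p_marg < p_marg_max)
  if (!length(filt)) return(list(hits = hits, meff = 0L, n_filtered = 0L))
  ids <- intersect(records$id[filt], colnames(panel))
  meff <- if (length(ids)) meff_simpleM(panel[, ids, drop = FALSE],
                                        var_explained)
          else length(filt)  # no LD information: treat as independent
  pf <- records$p_int[filt]
  hits[filt] <- pf < 0.05 / meff & bh_fdr(pf, q)
  list(hits = hits, meff = as.integer(meff), n_filtered = length(filt))
}

#' Approaches C and D: interactions at, and main effects of, 2df loci
#'
#' Clumps the genome-wide significant 2df variants (`P_2df < gw` and BH FDR
#' < `q` within the scan) into loci; `M_2df` is their count.  Approach C
#' flags loci whose lead interaction p is below `0.05 / M_2df`; Approach D
#' flags loci whose lead interaction p is above the no-interaction cutoff
#' (`0.05` by default, or `0.05 / M_2df` with `d_bonferroni = TRUE`).
#'
#' @param records a `gwis_meta` table (one scan).
#' @param panel LD dosage panel for clumping.
#' @param gw,q significance and FDR thresholds.
#' @param d_bonferroni use the Bonferroni form of the Approach-D cutoff.
#' @return list with `loci` (clumped 2df loci with `tier_C`/`tier_D` flags),
#'   `m_2df`.
#' @export
approach_CD <- function(records, panel, gw = 5e-8, q = 0.05,
                        d_bonferroni = FALSE) {
  sig <- records[records$p_2df < gw & bh_fdr(records$p_2df, q), ,
                 drop = FALSE]
  loci <- clump_loci(sig, panel, p_col = "p_2df")
  m <- nrow(loci)
  if (!m) return(list(loci = loci, m_2df = 0L))
  lead_pint <- records$p_int[match(loci$lead, records$id)]
  loci$p_int_lead <- lead_pint
  loci$tier_C <- lead_pint < 0.05 / m
  d_cut <- if (d_bonferroni) 0.05 / m else 0.05
  loci$tier_D <- lead_pint > d_cut
  list(loci = loci, m_2df = m)
}

#' Tiered discovery report for one analysis scan
#'
#' Runs Approaches A-D on one meta-analysed scan, clumps the 1df hits into
#' primary interaction loci (tier A when the lead is genome-wide significant,
#' otherwise tier B), derives secondary (tier C) and main-effect-only
#' (tier D) loci from the 2df scan, classifies novelty against a known-loci
#' catalog, decomposes every interaction lead into unexposed/exposed effects
#' (b0, b1, fold), and tests 2df loci for enrichment of nominal
#' (`P_GxAlc < 0.05`) interactions.
#'
#' @param records a `gwis_meta` table (one scan, after
#'   [reporting_filter()] if desired).
#' @param panel LD dosage reference panel (columns named by variant id).
#' @param known optional known-loci catalog (`chrom`, `pos`, optional `id`).
#' @param q,gw,p_marg_max,var_explained,d_bonferroni tuning as in the
#'   approach functions.
#' @return object of class `discovery_report`: list with `interaction_loci`
#'   (tiered, novelty-flagged, decomposed), `loci_2df`, `meff`, `m_2df`, and
#'   `enrichment` (k, n, p).
#' @export
discover <- function(records, panel = NULL, known = NULL, q = 0.05,
                     gw = 5e-8, p_marg_max = 1e-5, var_explained = 0.995,
                     d_bonferroni = FALSE) {
  hitsA <- approach_A(records, gw, q)
  appB <- approach_B(records, panel, p_marg_max, q, var_explained)
  prim <- records[hitsA | appB$hits, , drop = FALSE]
  iloci <- clump_loci(prim, panel, p_col = "p_int")
  if (nrow(iloci)) {
    lead_row <- records[match(iloci$lead, records$id), ]
    iloci$tier <- ifelse(hitsA[match(iloci$lead, records$id)], "A", "B")
    dec <- decompose_effects(lead_row$beta_G, lead_row$beta_int,
                             lead_row$se_G, lead_row$se_int,
                             lead_row$cov_G_int)
    iloci <- cbind(iloci, dec)
  }
  if (!is.null(known)) iloci <- classify_novelty(iloci, known, records, panel)
  cd <- approach_CD(records, panel, gw, q, d_bonferroni)
  enr <- if (cd$m_2df > 0) {
    k <- sum(cd$loci$p_int_lead < 0.05)
    list(k = k, n = cd$m_2df, p = enrichment_test(k, cd$m_2df))
  } else list(k = 0L, n = 0L, p = NA_real_)
  out <- list(interaction_loci = iloci, loci_2df = cd$loci,
              meff = appB$meff, n_filtered = appB$n_filtered,
              m_2df = cd$m_2df, enrichment = enr,
              label = attr(records, "label"))
  class(out) <- "discovery_report"
  out
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("Discovery report", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat("  primary interaction loci:", nrow(x$interaction_loci),
      "( Meff =", x$meff, "over", x$n_filtered, "screened variants )\n")
  if (nrow(x$interaction_loci)) {
    cols <- intersect(c("lead", "chrom", "p_lead", "tier", "b0", "b1",
                        "fold", "novel"), names(x$interaction_loci))
    print(format(x$interaction_loci[, cols], digits = 3),
          row.names = FALSE)
  }
  cat("  2df loci (M_2df):", x$m_2df,
      "; tier C:", if (x$m_2df) sum(x$loci_2df$tier_C) else 0,
      "; tier D:", if (x$m_2df) sum(x$loci_2df$tier_D) else 0, "\n")
  if (x$m_2df)
    cat("  nominal-interaction enrichment: k =", x$enrichment$k, "of",
        x$enrichment$n, ", P =", format(x$enrichment$p, digits = 3), "\n")
  invisible(x)
}

#' Population-heterogeneity screen of lead variants
#'
#' For variants analysed in more than one population, tests heterogeneity of
#' the interaction effect across populations (Cochran's Q) at the Bonferroni
#' level `0.05 / n_multi`, `n_multi` being the number of such variants.
#'
#' @param pop_metas named list of population `gwis_meta` tables.
#' @param ids variant ids to screen (e.g. discovery leads).
#' @return data frame with `id`, `k_populations`, `Q`, `p_het`,
#'   `significant`.
#' @export
population_het_screen <- function(pop_metas, ids) {
  rows <- lapply(ids, function(v) {
    est <- do.call(rbind, lapply(pop_metas, function(m)
      m[m$id == v, c("beta_int", "se_int"), drop = FALSE]))
    if (is.null(est) || nrow(est) < 2L) return(NULL)
    q <- cochran_q(est$beta_int, est$se_int)
    data.frame(id = v, k_populations = nrow(est), Q = q$Q, p_het = q$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(id = character(0), k_populations = integer(0),
                      Q = numeric(0), p_het = numeric(0),
                      significant = logical(0)))
  out$significant <- out$p_het < 0.05 / nrow(out)
  out
}
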