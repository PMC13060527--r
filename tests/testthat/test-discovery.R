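test_that("BH step-up flags follow the hand-computed rule", {
  expect_equal(bh_fdr(rep(0.04, 4)), rep(TRUE, 4))
  expect_true(bh_fdr(0.049))
  expect_equal(bh_fdr(numeric(0)), logical(0))
  # monotone: lowering any p never removes a discovery
  set.seed(66)
  p <- runif(20)
  f1 <- bh_fdr(p)
  p2 <- p; p2[7] <- p2[7] / 10
  f2 <- bh_fdr(p2)
  expect_true(all(f2[f1]))
})

test_that("simpleM Meff matches an independent eigen-decomposition", {
  expect_equal(meff_simpleM(diag(5), is_cor = TRUE), 5L)
  ones <- matrix(1, 4, 4)
  expect_equal(meff_simpleM(ones, is_cor = TRUE), 1)
  # block of 10 highly correlated + 5 independent variants
  C <- diag(15)
  C[1:10, 1:10] <- sqrt(0.95)
  diag(C) <- 1
  m <- meff_simpleM(C, is_cor = TRUE)
  # oracle: step-up count on eigenvalues computed via svd
  ev <- svd(C)$d
  oracle <- which(cumsum(sort(ev, decreasing = TRUE)) / sum(ev) >= 0.995)[1]
  expect_equal(m, oracle)
  expect_gte(m, 6); expect_lt(m, 15)  # block counts as ~1 effective test
  # dosage-matrix interface agrees with its own correlation matrix
  set.seed(67)
  D <- matrix(rbinom(200 * 6, 2, 0.4), 200, 6)
  expect_equal(meff_simpleM(D), meff_simpleM(cor(D), is_cor = TRUE))
  expect_equal(meff_simpleM(D[, 1, drop = FALSE]), 1L)
  expect_equal(meff_simpleM(NULL), 0L)
})

test_that("clumping merges by LD and falls back to distance", {
  rec <- data.frame(id = c("a", "b"), chrom = 1L, pos = c(1e6, 1.6e6 + 1),
                    effect_allele = "A", p_int = c(1e-9, 1e-8),
                    stringsAsFactors = FALSE)
  # 600 kb apart, no panel: two loci
  expect_equal(nrow(clump_loci(rec)), 2L)
  # within 500 kb, no panel: one locus led by the smaller p
  rec2 <- rec; rec2$pos <- c(1e6, 1.4e6)
  cl <- clump_loci(rec2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$lead, "a")
  # r2 = 1 proxy pair merges regardless of distance; r2 ~ 0 pair does not
  set.seed(68)
  g1 <- rbinom(400, 2, 0.5)
  panel <- cbind(a = g1, b = g1, c = rbinom(400, 2, 0.5))
  rec3 <- data.frame(id = c("a", "b", "c"), chrom = 1L,
                     pos = c(1e6, 2e6, 1.05e6), effect_allele = "A",
                     p_int = c(1e-9, 1e-8, 1e-7), stringsAsFactors = FALSE)
  cl3 <- clump_loci(rec3, panel)
  expect_equal(nrow(cl3), 2L)
  expect_equal(sort(cl3$lead), c("a", "c"))
  expect_equal(cl3$members[cl3$lead == "a"], "a,b")
  # output is a partition; re-clumping the leads returns the same leads
  leads <- rec3[rec3$id %in% cl3$lead, ]
  expect_equal(sort(clump_loci(leads, panel)$lead), sort(cl3$lead))
  # tie in p: lead is the smaller position
  rec4 <- data.frame(id = c("x", "y"), chrom = 1L, pos = c(2e6, 1.9e6),
                     effect_allele = "A", p_int = c(1e-8, 1e-8),
                     stringsAsFactors = FALSE)
  expect_equal(clump_loci(rec4)$lead, "y")
})

test_that("novelty honours the 500 kb bound and linkage equilibrium", {
  set.seed(69)
  panel <- cbind(lead1 = rbinom(500, 2, 0.4), known1 = rbinom(500, 2, 0.4))
  rec <- data.frame(id = "lead1", chrom = 1L, pos = 1e6,
                    effect_allele = "A", p_int = 1e-9,
                    stringsAsFactors = FALSE)
  loci <- clump_loci(rec, panel)
  # known variant 300 kb away but in linkage equilibrium: still novel
  known_le <- data.frame(chrom = 1L, pos = 1.3e6, id = "known1",
                         stringsAsFactors = FALSE)
  expect_true(classify_novelty(loci, known_le, rec, panel)$novel)
  # same distance, correlated (r2 >= 0.1): known
  panel2 <- panel; panel2[, "known1"] <- panel[, "lead1"]
  expect_false(classify_novelty(loci, known_le, rec, panel2)$novel)
  # exactly 500 kb away with no r2 information: known (inclusive bound)
  known_na <- data.frame(chrom = 1L, pos = 1.5e6, id = "absent",
                         stringsAsFactors = FALSE)
  expect_false(classify_novelty(loci, known_na, rec, panel)$novel)
  # beyond 500 kb: novel
  known_far <- data.frame(chrom = 1L, pos = 1.5e6 + 1, id = "absent",
                          stringsAsFactors = FALSE)
  expect_true(classify_novelty(loci, known_far, rec, panel)$novel)
  expect_warning(out <- classify_novelty(loci, known_le[0, ], rec, panel),
                 "empty")
  expect_true(out$novel)
})

test_that("sex heterogeneity Z-test matches normal-tail arithmetic", {
  h0 <- sex_het_test(1, 0.5, 1, 0.5)
  expect_equal(h0$Z, 0); expect_equal(h0$p, 1)
  h <- sex_het_test(3, 1, 0, 1, n_tests = 21)
  expect_equal(h$Z, 2.1213, tolerance = 1e-4)
  expect_equal(h$p, 0.0339, tolerance = 1e-3)
  expect_true(h$p > 0.05 / 21 && !h$significant)
  # scaling both betas and ses leaves Z unchanged
  hs <- sex_het_test(30, 10, 0, 10)
  expect_equal(hs$Z, h$Z)
})

test_that("effect decomposition reproduces the exposed/unexposed split", {
  d <- decompose_effects(0.1, 0.5, 0.05, 0.08, -0.001)
  expect_equal(d$b0, 0.1); expect_equal(d$b1, 0.6)
  expect_equal(d$fold, 6)  # the ~6x drinker amplification structure
  d0 <- decompose_effects(0.3, 0, 0.1, 0.1, 0)
  expect_equal(d0$fold, 1); expect_equal(d0$b1, d0$b0)
  expect_equal(decompose_effects(1, 1, 1, 1, 0)$se_b1, sqrt(2))
  expect_true(is.na(decompose_effects(0, 1, 1, 1, 0)$fold))
  expect_error(decompose_effects(1, 1, 0.1, 0.1, -1), "Var")
})

test_that("binomial enrichment reproduces the printed tail probabilities", {
  expect_equal(signif(enrichment_test(13, 36), 2), 9.5e-9)
  expect_equal(signif(enrichment_test(258, 2070), 2), 4.7e-40)
  expect_equal(enrichment_test(0, 100), 1)
  expect_equal(enrichment_test(3, 10, 0.5),
               sum(dbinom(3:10, 10, 0.5)), tolerance = 1e-12)
  expect_error(enrichment_test(5, 10, 0), "p0")
  expect_error(enrichment_test(11, 10), "k")
})

test_that("tier assignment follows the four-approach rules", {
  set.seed(70)
  n <- 40
  rec <- make_stats(n)
  rec$p_int <- runif(n, 0.2, 1)
  rec$p_marg <- runif(n, 0.2, 1)
  rec$p_2df <- runif(n, 0.2, 1)
  rec$pos <- 1e6 + (seq_len(n) - 1) * 2e6  # all independent by distance
  # variant 1: genome-wide interaction (tier A)
  rec$p_int[1] <- 1e-9; rec$p_marg[1] <- 1e-9; rec$p_2df[1] <- 1e-10
  # variant 2: detected only by the 2-step screen (tier B)
  rec$p_int[2] <- 1e-4; rec$p_marg[2] <- 1e-7; rec$p_2df[2] <- 1e-9
  # variant 3: 2df-significant, no interaction (tier D)
  rec$p_int[3] <- 0.5; rec$p_marg[3] <- 1e-12; rec$p_2df[3] <- 1e-12
  attr(rec, "label") <- "EUR"
  hitsA <- approach_A(rec)
  expect_equal(which(hitsA), 1L)
  appB <- approach_B(rec, panel = NULL)
  expect_equal(appB$n_filtered, 3L)  # variants 1-3 pass the marginal screen
  expect_equal(appB$meff, 3L)        # no LD info: counted independent
  expect_equal(which(appB$hits), c(1L, 2L))  # 1e-4 < 0.05/3; 0.5 fails
  cd <- approach_CD(rec, panel = NULL)
  expect_equal(cd$m_2df, 3L)
  expect_equal(sum(cd$loci$tier_C), 2L)   # leads 1 and 2
  expect_equal(sum(cd$loci$tier_D), 1L)   # lead 3
  expect_false(any(cd$loci$tier_C & cd$loci$tier_D))
  drep <- discover(rec, panel = NULL)
  il <- drep$interaction_loci
  expect_equal(sort(il$lead), c("v00001", "v00002"))
  expect_equal(il$tier[il$lead == "v00001"], "A")
  expect_equal(il$tier[il$lead == "v00002"], "B")
  expect_equal(drep$m_2df, 3L)
  expect_equal(drep$enrichment$k, 2L)
  # Approach-D Bonferroni variant of the cutoff
  cdb <- approach_CD(rec, panel = NULL, d_bonferroni = TRUE)
  expect_equal(sum(cdb$loci$tier_D), 1L)
})

test_that("the 2-step screen detects a variant genome-wide search misses", {
  # constructed scenario: strong marginal effect, moderate interaction
  cfg <- sim_config(6000, 8, allele_freq = 0.3,
                    beta_G = c(1.5, rep(0, 7)),
                    beta_GxAlc = c(1.1, rep(0, 7)),
                    noise_sd = 10, seed = 71)
  co <- harmonize_cohort(simulate_cohort(cfg))
  sl <- build_slices(co, "SBP", "CURDRINK", "combined")[[1]]
  s <- gwis(sl, co$dosage, co$variant_meta)$stats
  attr(s, "label") <- "EUR"
  appB <- approach_B(s, panel = co$hard)
  hitsA <- approach_A(s)
  expect_gt(s$p_int[1], 5e-8)          # misses genome-wide significance
  expect_lt(s$p_int[1], 0.05 / appB$meff)
  expect_false(hitsA[1])
  expect_true(appB$hits[1])
})

test_that("population heterogeneity screen uses the Bonferroni rule", {
  pm <- list(
    EUR = make_stats(2, beta_int = c(1, 0.1), se_int = 0.1),
    EAS = make_stats(2, beta_int = c(-1, 0.12), se_int = 0.1))
  sc <- population_het_screen(pm, c("v00001", "v00002"))
  expect_equal(sc$k_populations, c(2L, 2L))
  expect_true(sc$significant[1])
  expect_false(sc$significant[2])
  expect_equal(sc$Q[1], cochran_q(c(1, -1), c(0.1, 0.1))$Q)
})
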