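test_that("inverse-variance weighting reproduces hand arithmetic", {
  m <- ivw_meta(c(1, 3), c(1, 1))
  expect_equal(m$beta, 2)
  expect_equal(m$se, sqrt(0.5), tolerance = 1e-4)
  # k identical studies: same estimate, se / sqrt(k)
  m5 <- ivw_meta(rep(0.4, 5), rep(0.2, 5))
  expect_equal(m5$beta, 0.4)
  expect_equal(m5$se, 0.2 / sqrt(5))
  # unequal weights against spreadsheet-style arithmetic
  b <- c(0.5, 1.2, -0.3); se <- c(0.2, 0.5, 0.8)
  w <- 1 / se^2
  m3 <- ivw_meta(b, se)
  expect_equal(m3$beta, sum(w * b) / sum(w))
  expect_equal(m3$se, 1 / sqrt(sum(w)))
  expect_error(ivw_meta(1, 0), "standard errors")
})

test_that("2df pooling matches hand linear algebra", {
  B <- rbind(c(0.5, 0.2), c(0.5, 0.2))
  covs <- list(diag(c(0.01, 0.04)), diag(c(0.01, 0.04)))
  jt <- joint_meta_2df(B, covs)
  expect_equal(jt$vcov, diag(c(0.005, 0.02)))
  expect_equal(jt$chi2, 0.25 / 0.005 + 0.04 / 0.02)  # = 52
  expect_equal(jt$chi2, 52)
  # all-zero betas
  jt0 <- joint_meta_2df(rbind(c(0, 0)), list(diag(2)))
  expect_equal(jt0$chi2, 0); expect_equal(jt0$p, 1)
  # diagonal covariances: chi2 = sum of squared pooled Z-scores
  B2 <- rbind(c(0.3, -0.1), c(0.5, 0.2))
  covs2 <- list(diag(c(0.02, 0.05)), diag(c(0.01, 0.03)))
  jt2 <- joint_meta_2df(B2, covs2)
  zg <- jt2$beta[1] / sqrt(jt2$vcov[1, 1])
  zi <- jt2$beta[2] / sqrt(jt2$vcov[2, 2])
  expect_equal(jt2$chi2, zg^2 + zi^2)
  # non-positive-definite covariance is rejected
  expect_null(joint_meta_2df(rbind(c(1, 1)),
                             list(matrix(c(1, 2, 2, 1), 2))))
  # IVW is the 1d special case of the first component under diagonal covs
  iv <- ivw_meta(B2[, 2], sqrt(c(0.05, 0.03)))
  expect_equal(jt2$beta[2], iv$beta, tolerance = 1e-12)
})

test_that("Cochran's Q behaves as derived", {
  q0 <- cochran_q(c(1, 1, 1), c(0.3, 0.3, 0.3))
  expect_equal(q0$Q, 0); expect_equal(q0$p, 1)
  q <- cochran_q(c(1, -1), c(1, 1))
  expect_equal(q$Q, 2)
  expect_equal(q$p, 0.1573, tolerance = 1e-4)
  # invariant to common rescaling
  qs <- cochran_q(c(3, -3), c(3, 3))
  expect_equal(qs$Q, q$Q)
  expect_true(is.na(cochran_q(1, 1)$Q))
})

test_that("pooling is invariant to study order and stage structure", {
  set.seed(55)
  stats <- lapply(1:4, function(i)
    make_stats(3, beta_int = rnorm(3, 0.2, 0.1), se_int = runif(3, .1, .3),
               beta_G = rnorm(3), se_G = runif(3, .1, .3),
               beta_marg = rnorm(3), se_marg = runif(3, .1, .2),
               n = 1000 + i))
  pm <- meta_by_population(stats, rep("EUR", 4))$EUR
  pm_rev <- meta_by_population(rev(stats), rep("EUR", 4))$EUR
  expect_equal(pm$beta_int, pm_rev$beta_int, tolerance = 1e-12)
  expect_equal(pm$se_int, pm_rev$se_int, tolerance = 1e-12)
  expect_equal(pm$chi2_2df, pm_rev$chi2_2df, tolerance = 1e-12)
  # N conserved through both stages; pooled SE <= min per-study SE
  expect_equal(pm$n, rep(sum(1000 + 1:4), 3))
  expect_true(all(pm$se_int <= sapply(1:3, function(j)
    min(sapply(stats, function(s) s$se_int[j])))))
  # one population: CPMA equals that population's record
  cp <- cross_population_meta(list(EUR = pm))
  expect_equal(cp$beta_int, pm$beta_int)
  expect_equal(cp$p_2df, pm$p_2df)
  expect_equal(cp$n, pm$n)
})

test_that("variants below the study minimum are dropped within population", {
  a <- make_stats(2); b <- make_stats(1)  # v00002 only in cohort a
  pm <- meta_by_population(list(a, b), c("EUR", "EUR"))$EUR
  expect_equal(pm$id, "v00001")
  expect_equal(pm$k_studies, 2L)
})

test_that("fixed-effects meta agrees with pooled-data OLS (small scale)", {
  stats <- list(); dat <- list()
  for (i in 1:3) {
    cfg <- sim_config(2000, 1, allele_freq = 0.3, beta_G = 0.3,
                      beta_GxAlc = 0.8, seed = 600 + i)
    co <- harmonize_cohort(simulate_cohort(cfg))
    sl <- build_slices(co, "SBP", "CURDRINK", "combined")[[1]]
    stats[[i]] <- gwis(sl, co$dosage, co$variant_meta)$stats
    d <- sl$data; d$g <- co$dosage[sl$rows, 1]
    dat[[i]] <- d
  }
  cp <- cross_population_meta(meta_by_population(stats, rep("EUR", 3)))
  all3 <- do.call(rbind, dat)
  mega <- fit_model1(all3$Y, all3$g, all3$Alc,
                     as.matrix(all3[, c("age", "age2", "sex")]))
  expect_lt(abs(cp$beta_int - mega$beta_int),
            3 * sqrt(cp$se_int^2 + mega$se_int^2))
})

test_that("reporting thresholds follow the population rules", {
  r <- make_stats(3)
  r$population <- c("AFR", "EUR", "EUR")
  r$n <- c(5001, 19000, 30000)
  r$k_studies <- c(2, 5, 1)
  class(r) <- c("gwis_meta", class(r))
  rf <- reporting_filter(r)
  expect_equal(rf$reportable, c(TRUE, FALSE, FALSE))
  cp <- make_stats(2)
  cp$population <- "CPMA"; cp$n <- c(25000, 25000)
  cp$k_studies <- c(3, 3); cp$k_populations <- c(1, 2)
  rf2 <- reporting_filter(cp)
  expect_equal(rf2$reportable, c(FALSE, TRUE))
  bad <- make_stats(1); bad$population <- "XXX"; bad$k_studies <- 2
  expect_error(reporting_filter(bad), "threshold")
})
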