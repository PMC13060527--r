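test_that("medication adjustment adds 15/10 mmHg to treated readings", {
  a <- adjust_medication(130, 80, 1)
  expect_equal(a$sbp_adj, 145)
  expect_equal(a$dbp_adj, 90)
  b <- adjust_medication(130, 80, 0)
  expect_equal(b$sbp_adj, 130)
  expect_equal(b$dbp_adj, 80)
  set.seed(1)
  med <- rbinom(50, 1, 0.5)
  sbp <- rnorm(50, 130, 15)
  d <- adjust_medication(sbp, sbp, med)$sbp_adj - sbp
  expect_true(all(abs(d) < 1e-9 | abs(d - 15) < 1e-9))
})

test_that("pulse pressure is the SBP-DBP difference after adjustment", {
  expect_equal(compute_pp(145, 90), 55)
  expect_equal(compute_pp(120, 120), 0)
  sbp <- rnorm(20, 130, 10); dbp <- rnorm(20, 80, 8)
  expect_equal(compute_pp(sbp, dbp) + dbp, sbp)
})

test_that("winsorization caps at exactly mean +/- 6 SD of the input", {
  x <- c(rep(c(-1, 1), 500), 8)
  m <- mean(x); s <- sd(x)
  stopifnot(8 > m + 6 * s)  # fixture sanity
  w <- winsorize(x)
  expect_equal(max(w), m + 6 * s)
  expect_equal(w[-length(x)], x[-length(x)])
  # in-range input unchanged; symmetric input stays symmetric
  y <- rnorm(100)
  expect_equal(winsorize(y, k = 6), y)
  z <- c(-50, -1, 0, 1, 50)
  expect_equal(winsorize(z), -rev(winsorize(z)))
  # never increases distance from the mean; range within the bounds
  v <- c(rnorm(200), 30, -25)
  wv <- winsorize(v)
  expect_true(all(abs(wv - mean(v)) <= abs(v - mean(v)) + 1e-12))
  expect_true(all(wv >= mean(v) - 6 * sd(v) & wv <= mean(v) + 6 * sd(v)))
  expect_equal(winsorize(rep(3, 10)), rep(3, 10))  # zero variance
})

test_that("standard-drink conversion reproduces the printed constants", {
  # a 12 fl oz beer at 5% ABV is one US standard drink (14 g ethanol)
  grams <- 12 * 29.5735 * 0.05 * 0.78945
  expect_equal(round(grams, 1), 14.0)
  expect_equal(standard_drinks(12, 0.05, "floz_abv"), grams / 14)
  expect_equal(round(standard_drinks(12, 0.05, "floz_abv"), 2), 1.00)
  expect_equal(standard_drinks(0, 0.4, "ml_abv"), 0)
  expect_equal(standard_drinks(1000, 0.40, "ml_abv"),
               1000 * 0.40 * 0.78945 / 14)
  expect_equal(round(standard_drinks(1000, 0.40, "ml_abv"), 2), 22.56)
  expect_equal(standard_drinks(14, mode = "grams"), 1)
  # fl oz and ml modes agree to <0.1% on equivalent volumes
  vol_floz <- c(5, 12, 1.5)
  ml <- vol_floz * 29.5735
  expect_equal(standard_drinks(vol_floz, 0.12, "floz_abv"),
               standard_drinks(ml, 0.12, "ml_abv"), tolerance = 1e-6)
  expect_error(standard_drinks(-1, 0.05, "ml_abv"), "volume")
  expect_error(standard_drinks(10, 1.5, "ml_abv"), "abv")
})

test_that("exposure contrasts follow the never/light/heavy cutoffs", {
  expect_equal(classify_exposure(8, "F", "HEAVYvsNEVER"), 1L)
  expect_equal(classify_exposure(8, "M", "HEAVYvsNEVER"), NA_integer_)
  expect_equal(classify_exposure(0.5, "F", "LIGHTvsNEVER"), 0L)
  expect_equal(classify_exposure(14, "M", "HEAVYvsLIGHT"), 0L)  # boundary
  expect_equal(classify_exposure(7, "F", "HEAVYvsLIGHT"), 0L)
  expect_equal(classify_exposure(7.1, "F", "HEAVYvsLIGHT"), 1L)
  expect_equal(classify_exposure(0.99, "M", "CURDRINK"), 0L)
  expect_equal(classify_exposure(1, "M", "CURDRINK"), 1L)
  expect_error(classify_exposure(1, "M", "NOPE"))
  # never/light/heavy partition dpw >= 0 exhaustively and exclusively
  dpw <- c(0, 0.5, 1, 3, 7, 7.01, 14, 14.01, 50)
  for (sx in c("F", "M")) {
    lab <- alcgwis:::.drink_category(dpw, rep(sx, length(dpw)))
    expect_true(all(lab %in% c("never", "light", "heavy")))
    never <- dpw < 1
    heavy <- dpw > ifelse(sx == "F", 7, 14)
    expect_equal(lab == "never", never)
    expect_equal(lab == "heavy", heavy)
    expect_equal(lab == "light", !never & !heavy)
  }
})

test_that("very-heavy exclusion drops only 6-SD outliers of DPW", {
  expect_true(all(exclude_very_heavy(rep(5, 100), rep("M", 100))))
  dpw <- c(rep(2, 100), rep(3, 100), 50)
  sex <- rep(c("F", "M"), length.out = 201)
  keep <- exclude_very_heavy(dpw, sex)
  ref <- dpw[dpw >= 1]
  stopifnot(50 > mean(ref) + 6 * sd(ref))  # fixture sanity
  expect_equal(which(!keep), 201L)
})

test_that("slice construction yields the 36-scan grid with binary exposure", {
  co <- harmonize_cohort(simulate_cohort(sim_config(600, 4, seed = 21)))
  slices <- build_slices(co)
  expect_length(slices, 36)
  expect_true(all(vapply(slices, function(s)
    all(s$data$Alc %in% 0:1), logical(1))))
  # PP identity holds for every retained row
  ind <- co$individuals
  expect_equal(ind$PP, ind$SBP - ind$DBP)
  # CURDRINK keeps everyone left after exclusions
  cd <- slices[["SBP.CURDRINK.combined"]]
  expect_equal(nrow(cd$data), nrow(ind))
  # a single-sex cohort flags the other sex's slices
  cof <- simulate_cohort(sim_config(300, 2, p_female = 1, seed = 22))
  cof <- harmonize_cohort(cof)
  slf <- build_slices(cof, "SBP", "CURDRINK")
  expect_true(slf[["SBP.CURDRINK.M"]]$flagged)
  expect_false(slf[["SBP.CURDRINK.F"]]$flagged)
})
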