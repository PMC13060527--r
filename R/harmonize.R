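#' Supported alcohol exposure contrasts
#'
#' `CURDRINK` codes current drinker (>= 1 drink/week) vs not; `LIGHTvsNEVER`,
#' `HEAVYvsNEVER` and `HEAVYvsLIGHT` compare the light (1-7 DPW for females,
#' 1-14 for males), heavy (>7 / >14 DPW) and never (<1 DPW) groups, with
#' individuals outside either arm excluded from the contrast.
#'
#' @return character vector of contrast names.
#' @export
alc_contrasts <- function() c("CURDRINK", "LIGHTvsNEVER", "HEAVYvsNEVER",
                              "HEAVYvsLIGHT")

#' BP traits analysed
#' @return character vector: systolic, diastolic, pulse pressure.
#' @export
bp_traits <- function() c("SBP", "DBP", "PP")

#' Adjust blood pressure for antihypertensive medication
#'
#' Adds 15 mmHg to SBP and 10 mmHg to DBP of medicated individuals, the
#' standard partial correction for treated BP in genetic association studies.
#'
#' @param sbp_raw,dbp_raw observed BP (mmHg).
#' @param medicated 0/1 medication indicator.
#' @return list with `sbp_adj`, `dbp_adj`.
#' @export
adjust_medication <- function(sbp_raw, dbp_raw, medicated) {
  list(sbp_adj = sbp_raw + 15 * medicated,
       dbp_adj = dbp_raw + 10 * medicated)
}

#' Pulse pressure
#'
#' Difference between (medication-adjusted) systolic and diastolic BP.
#' @param sbp_adj,dbp_adj adjusted BP (mmHg).
#' @return numeric vector, mmHg.
#' @export
compute_pp <- function(sbp_adj, dbp_adj) sbp_adj - dbp_adj

#' Winsorize extreme values at mean +/- k standard deviations
#'
#' Values beyond `mean +/- k*SD` of the input (moments estimated from the
#' non-missing input values) are set to exactly that bound.  Zero-variance
#' input is returned unchanged.
#'
#' @param x numeric vector (may contain NA).
#' @param k SD multiple; default 6.
#' @return winsorized vector, same length and NA pattern.
#' @export
winsorize <- function(x, k = 6) {
  m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x)
  pmin(pmax(x, m - k * s), m + k * s)
}

#' Convert beverage intake to US standard drinks
#'
#' One US standard drink (StDrk) is 14 g of pure ethanol.  Three conversion
#' modes are supported: `"ml_abv"` computes grams of ethanol as
#' `volume_ml * abv * 0.78945` (ethanol density, g/ml at 20 C) and divides by
#' 14; `"grams"` divides a known gram amount by 14; `"floz_abv"` converts
#' fluid ounces to ml (29.5735 ml/fl oz) and then applies `"ml_abv"`.
#'
#' @param volume beverage volume (ml, fl oz) or grams of ethanol per `mode`.
#' @param abv alcohol by volume as a fraction in \[0, 1\] (ignored for
#'   `"grams"`).
#' @param mode one of `"ml_abv"`, `"grams"`, `"floz_abv"`.
#' @return standard drinks (numeric, >= 0).
#' @examples
#' standard_drinks(12, 0.05, "floz_abv")  # a 12 fl oz beer at 5% ~ 1 StDrk
#' @export
standard_drinks <- function(volume, abv = NULL, mode = c("ml_abv", "grams",
                                                         "floz_abv")) {
  mode <- match.arg(mode)
  if (any(volume < 0)) stop("volume must be >= 0")
  if (mode != "grams") {
    if (is.null(abv)) stop("abv required for volume-based modes")
    if (any(abv < 0 | abv > 1)) stop("abv must lie in [0, 1]")
  }
  switch(mode,
         grams = volume / 14,
         ml_abv = volume * abv * 0.78945 / 14,
         floz_abv = volume * 29.5735 * abv * 0.78945 / 14)
}

# never/light/heavy category given DPW and sex; boundaries inclusive of the
# light range (1-7 female / 1-14 male)
.drink_category <- function(dpw, sex) {
  heavy_cut <- ifelse(sex == "F", 7, 14)
  ifelse(dpw < 1, "never", ifelse(dpw <= heavy_cut, "light", "heavy"))
}

#' Classify individuals into an exposure contrast
#'
#' Returns the 0/1 exposure indicator for the requested contrast, or `NA` for
#' individuals outside both arms (e.g. heavy drinkers under `LIGHTvsNEVER`).
#' Categories: never (<1 DPW), light (1-7 DPW females / 1-14 males, boundary
#' inclusive), heavy (>7 / >14 DPW).
#'
#' @param dpw drinks per week (>= 0).
#' @param sex "F"/"M".
#' @param contrast one of [alc_contrasts()].
#' @return integer vector of 0/1/NA.
#' @export
classify_exposure <- function(dpw, sex, contrast) {
  contrast <- match.arg(contrast, alc_contrasts())
  if (any(dpw < 0, na.rm = TRUE)) stop("dpw must be >= 0")
  cat3 <- .drink_category(dpw, sex)
  out <- switch(contrast,
    CURDRINK = ifelse(cat3 == "never", 0L, 1L),
    LIGHTvsNEVER = ifelse(cat3 == "light", 1L,
                          ifelse(cat3 == "never", 0L, NA_integer_)),
    HEAVYvsNEVER = ifelse(cat3 == "heavy", 1L,
                          ifelse(cat3 == "never", 0L, NA_integer_)),
    HEAVYvsLIGHT = ifelse(cat3 == "heavy", 1L,
                          ifelse(cat3 == "light", 0L, NA_integer_)))
  as.integer(out)
}

#' Flag very heavy drinkers for exclusion
#'
#' An individual is dropped when their DPW is at or above mean + 6 SD of the
#' reference distribution, evaluated both in their sex stratum and in the
#' sex-combined sample.  By default the reference moments are computed among
#' current drinkers (DPW >= 1); computing them over everyone (including the
#' mass at zero) would make the rule vacuous in low-drinking cohorts.  Flags
#' are computed once from the pre-exclusion moments.
#'
#' @param dpw drinks per week.
#' @param sex "F"/"M".
#' @param k SD multiple (default 6).
#' @param among_drinkers if `TRUE` (default) moments use only DPW >= 1.
#' @return logical vector, `TRUE` = keep.
#' @export
exclude_very_heavy <- function(dpw, sex, k = 6, among_drinkers = TRUE) {
  ref <- if (among_drinkers) dpw >= 1 else rep(TRUE, length(dpw))
  lim <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) Inf else m + k * s
  }
  keep <- rep(TRUE, length(dpw))
  if (!any(ref)) return(keep)
  comb <- lim(dpw[ref])
  keep <- dpw < comb
  for (sx in unique(sex)) {
    sel <- sex == sx
    if (any(ref & sel)) keep[sel] <- keep[sel] & dpw[sel] < lim(dpw[ref & sel])
  }
  keep
}

#' Harmonize a cohort's phenotypes
#'
#' Applies, in order: medication adjustment (+15/+10 mmHg), pulse pressure,
#' very-heavy-drinker exclusion, and per-trait 6-SD winsorization with
#' sex-combined moments on the retained sample.
#'
#' @param cohort a `sim_cohort` (or compatible list with `individuals`,
#'   `dosage`, `variant_meta`).
#' @param winsor_k winsorization SD multiple.
#' @return the cohort with `individuals` gaining `SBP`, `DBP`, `PP`
#'   (adjusted + winsorized analysis traits) and rows failing the very-heavy
#'   rule removed (dosage rows removed in step).
#' @export
harmonize_cohort <- function(cohort, winsor_k = 6) {
  ind <- cohort$individuals
  adj <- adjust_medication(ind$sbp_raw, ind$dbp_raw, ind$medicated)
  ind$SBP <- adj$sbp_adj
  ind$DBP <- adj$dbp_adj
  ind$PP <- compute_pp(adj$sbp_adj, adj$dbp_adj)
  keep <- exclude_very_heavy(ind$dpw, ind$sex)
  ind <- ind[keep, , drop = FALSE]
  cohort$dosage <- cohort$dosage[keep, , drop = FALSE]
  if (!is.null(cohort$hard))
    cohort$hard <- cohort$hard[keep, , drop = FALSE]
  for (tr in bp_traits()) ind[[tr]] <- winsorize(ind[[tr]], winsor_k)
  cohort$individuals <- ind
  cohort$n_excluded_very_heavy <- sum(!keep)
  cohort
}

#' Build per-analysis slices from a harmonized cohort
#'
#' One slice per (trait, contrast, sex group): outcome `Y`, binary exposure
#' `Alc` (rows outside the contrast arms removed), and covariates age, age
#' squared and — in the sex-combined group — sex.
#'
#' @param cohort a harmonized cohort (see [harmonize_cohort()]).
#' @param traits,contrasts,sex_groups subsets of [bp_traits()],
#'   [alc_contrasts()] and `c("combined","F","M")`; defaults give the full
#'   36-slice grid.
#' @return named list of slices, each a list with `trait`, `contrast`,
#'   `sex_group`, `data` (id, Y, Alc, covariates), `rows` (row index into the
#'   harmonized cohort, for aligning dosages) and `flagged` (TRUE when an arm
#'   is empty).
#' @export
build_slices <- function(cohort, traits = bp_traits(),
                         contrasts = alc_contrasts(),
                         sex_groups = c("combined", "F", "M")) {
  ind <- cohort$individuals
  slices <- list()
  for (tr in traits) for (ct in contrasts) for (sg in sex_groups) {
    sel <- if (sg == "combined") rep(TRUE, nrow(ind)) else ind$sex == sg
    alc <- classify_exposure(ind$dpw, ind$sex, ct)
    use <- sel & !is.na(alc)
    d <- data.frame(id = ind$id[use], Y = ind[[tr]][use], Alc = alc[use],
                    age = ind$age[use], age2 = ind$age[use]^2,
                    stringsAsFactors = FALSE)
    if (sg == "combined") d$sex <- as.numeric(ind$sex[use] == "M")
    sl <- list(trait = tr, contrast = ct, sex_group = sg, data = d,
               rows = which(use),
               flagged = !all(c(0, 1) %in% d$Alc))
    slices[[paste(tr, ct, sg, sep = ".")]] <- sl
  }
  slices
}
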