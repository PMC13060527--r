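# Shared fixtures: small cohorts, an independent least-squares oracle, and a
# lazily computed null scan reused by the calibration tests.

# independent oracle for the joint model: R's lm() with model-based vcov
oracle_model1 <- function(y, g, alc, age = NULL) {
  df <- data.frame(y = y, g = g, alc = alc)
  fm <- if (is.null(age)) y ~ alc + g + g:alc else {
    df$age <- age
    y ~ alc + age + g + g:alc
  }
  fit <- lm(fm, data = df)
  V <- vcov(fit)
  nm_int <- grep(":", names(coef(fit)), value = TRUE)
  list(beta_G = unname(coef(fit)["g"]), beta_int = unname(coef(fit)[nm_int]),
       se_G = sqrt(V["g", "g"]), se_int = sqrt(V[nm_int, nm_int]),
       cov_G_int = V["g", nm_int])
}

oracle_model2 <- function(y, g, age = NULL) {
  df <- data.frame(y = y, g = g)
  fm <- if (is.null(age)) y ~ g else { df$age <- age; y ~ age + g }
  fit <- lm(fm, data = df)
  list(beta_marg = unname(coef(fit)["g"]),
       se_marg = sqrt(vcov(fit)["g", "g"]))
}

# minimal valid summary-statistics row(s) for constructing fixtures
make_stats <- function(V = 1, ...) {
  base <- data.frame(
    id = sprintf("v%05d", seq_len(V)), chrom = 1L,
    pos = 1e6 + (seq_len(V) - 1) * 1e5,
    effect_allele = "A", other_allele = "G", freq = 0.3,
    n = 1000L, n_exposed = 600L, n_unexposed = 400L,
    beta_G = 0.1, se_G = 0.2, beta_int = 0.1, se_int = 0.3,
    cov_G_int = -0.01, p_int = 0.5, p_2df = 0.5,
    beta_marg = 0.1, se_marg = 0.15, p_marg = 0.5,
    impq = 0.9, mac_exposed = 200, mac_unexposed = 150, mac_total = 350,
    stringsAsFactors = FALSE)
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  base
}

# null scan shared by the calibration/GC/independence checks (computed once)
.null_cache <- new.env(parent = emptyenv())
null_scan <- function(n_ind = 5000, n_var = 5000, seed = 3) {
  key <- paste(n_ind, n_var, seed, sep = "_")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  cfg <- sim_config(n_ind, n_var, beta_Alc = 2, seed = seed)
  co <- harmonize_cohort(simulate_cohort(cfg))
  sl <- build_slices(co, "SBP", "CURDRINK", "combined")[[1]]
  .null_cache[[key]] <- gwis(sl, co$dosage, co$variant_meta)$stats
  .null_cache[[key]]
}
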