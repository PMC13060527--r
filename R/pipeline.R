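#' Run the full synthetic GWIS pipeline
#'
#' Simulates the configured cohorts, harmonizes phenotypes, runs the
#' per-cohort GWIS engine for every requested (trait, contrast, sex-group)
#' scan, applies variant/cohort QC with genomic control, meta-analyses within
#' populations and across populations (CPMA), applies the reporting rule, and
#' runs the tiered discovery framework on each scan, with sex- and
#' population-heterogeneity screens of the discovery leads.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{seed}{integer run seed (cohort i simulates with `seed + i`).}
#'     \item{cohorts}{list of cohort entries: `id`, `population`, plus any
#'       [sim_config()] arguments (`n_individuals`, `n_variants`,
#'       `allele_freq`, `beta_G`, `beta_GxAlc`, ...).  All cohorts must share
#'       `n_variants`.}
#'     \item{traits, contrasts, sex_groups}{the scan grid (defaults: SBP,
#'       CURDRINK, combined).}
#'     \item{known_loci}{optional path to a known-loci TSV.}
#'     \item{apply_reporting}{apply the sample-size reporting rule before
#'       discovery (default TRUE).}
#'     \item{out}{optional output directory for TSV/JSON artifacts.}
#'   }
#' @return object of class `gwis_pipeline`: per-scan population and CPMA
#'   meta tables, discovery reports, heterogeneity screens, QC log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  traits <- if (is.null(config$traits)) "SBP" else config$traits
  contrasts <- if (is.null(config$contrasts)) "CURDRINK" else config$contrasts
  sex_groups <- if (is.null(config$sex_groups)) "combined"
                else config$sex_groups
  apply_rep <- !identical(config$apply_reporting, FALSE)
  known <- if (!is.null(config$known_loci)) read_known_loci(config$known_loci)
  stamp <- version_stamp(config, seed)
  out_dir <- config$out
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # stage 1-2: simulate and harmonize every cohort
  cohorts <- list(); pops <- character(0); log <- list()
  for (i in seq_along(config$cohorts)) {
    entry <- config$cohorts[[i]]
    cid <- if (is.null(entry$id)) paste0("cohort", i) else entry$id
    pops[cid] <- entry$population
    sim_args <- entry[setdiff(names(entry), c("id", "population"))]
    sim_args$seed <- seed + i
    cfg <- do.call(sim_config, sim_args)
    cohorts[[cid]] <- harmonize_cohort(simulate_cohort(cfg))
    log[[cid]] <- list(
      population = entry$population,
      n = nrow(cohorts[[cid]]$individuals),
      n_excluded_very_heavy = cohorts[[cid]]$n_excluded_very_heavy)
  }
  nv <- unique(vapply(cohorts, function(co) nrow(co$variant_meta), 0L))
  if (length(nv) != 1L) stop("all cohorts must share n_variants")
  panel <- cohorts[[1]]$hard  # LD reference: first cohort's hard genotypes

  # stages 3-6 per scan
  scans <- list()
  for (tr in traits) for (ct in contrasts) for (sg in sex_groups) {
    scan_id <- paste(tr, ct, sg, sep = ".")
    stats_list <- list(); scan_pops <- character(0)
    for (cid in names(cohorts)) {
      sl <- build_slices(cohorts[[cid]], tr, ct, sg)[[1]]
      if (sl$flagged) {
        log[[cid]][[scan_id]] <- list(excluded = "empty exposure arm")
        next
      }
      sc <- gwis(sl, cohorts[[cid]]$dosage, cohorts[[cid]]$variant_meta)
      qc <- qc_summary_stats(sc$stats)
      log[[cid]][[scan_id]] <- qc$report
      if (!qc$include) next
      stats_list[[cid]] <- qc$stats
      scan_pops[cid] <- pops[cid]
    }
    if (!length(stats_list)) next
    pm <- meta_by_population(stats_list, unname(scan_pops))
    cpma <- cross_population_meta(pm)
    cpma <- reporting_filter(cpma)
    pm <- lapply(pm, reporting_filter)
    drec <- if (apply_rep) cpma[cpma$reportable, , drop = FALSE] else cpma
    attr(drec, "label") <- "CPMA"
    rep_d <- discover(drec, panel, known,
                      d_bonferroni = isTRUE(config$d_bonferroni))
    leads <- rep_d$interaction_loci$lead
    pop_het <- population_het_screen(pm, leads)
    scans[[scan_id]] <- list(trait = tr, contrast = ct, sex_group = sg,
                             population_meta = pm, cpma = cpma,
                             discovery = rep_d, population_het = pop_het)
    if (!is.null(out_dir)) {
      write_stamped_tsv(as.data.frame(cpma),
                        file.path(out_dir, paste0(scan_id, ".cpma.tsv")),
                        stamp)
      if (nrow(rep_d$interaction_loci))
        write_stamped_tsv(rep_d$interaction_loci,
                          file.path(out_dir, paste0(scan_id, ".loci.tsv")),
                          stamp)
    }
  }

  # sex-heterogeneity screen: F and M scans of the same trait/contrast
  sex_het <- list()
  for (tr in traits) for (ct in contrasts) {
    fm <- paste(tr, ct, c("F", "M"), sep = ".")
    if (!all(fm %in% names(scans))) next
    f <- scans[[fm[1]]]$cpma; m <- scans[[fm[2]]]$cpma
    shared <- intersect(f$id, m$id)
    if (!length(shared)) next
    fi <- f[match(shared, f$id), ]; mi <- m[match(shared, m$id), ]
    ht <- sex_het_test(mi$beta_int, mi$se_int, fi$beta_int, fi$se_int,
                       n_tests = length(shared))
    sex_het[[paste(tr, ct, sep = ".")]] <-
      cbind(data.frame(id = shared, stringsAsFactors = FALSE), ht)
  }

  res <- list(scans = scans, sex_het = sex_het, log = log, stamp = stamp,
              seed = seed)
  class(res) <- "gwis_pipeline"
  if (!is.null(out_dir))
    jsonlite::write_json(log, file.path(out_dir, "qc_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}

#' @export
print.gwis_pipeline <- function(x, ...) {
  cat("GWIS pipeline run (seed", x$seed, "):", length(x$scans), "scan(s)\n")
  for (nm in names(x$scans)) {
    s <- x$scans[[nm]]
    cat("\n--", nm, "--\n")
    print(s$discovery)
  }
  invisible(x)
}
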