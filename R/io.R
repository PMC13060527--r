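# TSV interchange formats and provenance stamping.  All files are plain TSV
# with '#key=value' provenance header lines and a mandatory column header;
# '.' encodes missing values, positions are 1-based inclusive.

.SUMMARY_COLS <- c("id", "chrom", "pos", "effect_allele", "other_allele",
                   "freq", "n", "n_exposed", "n_unexposed", "beta_G", "se_G",
                   "beta_int", "se_int", "cov_G_int", "p_int", "p_2df",
                   "beta_marg", "se_marg", "p_marg", "impq", "mac_exposed",
                   "mac_unexposed", "mac_total")
.SUMMARY_CHR <- c("id", "effect_allele", "other_allele")

#' Provenance stamp for output files
#'
#' @param config any R object describing the run configuration (hashed after
#'   deparsing, so identical configurations give identical hashes).
#' @param seed the run seed.
#' @return named character vector: tool, version, config hash, seed.
#' @export
version_stamp <- function(config, seed = NA) {
  tf <- tempfile()
  writeLines(deparse(config), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  c(tool = "alcgwis",
    version = as.character(utils::packageVersion("alcgwis")),
    config_hash = h, seed = as.character(seed))
}

#' Write a data frame as a stamped TSV
#'
#' @param df data frame.
#' @param path output path.
#' @param stamp optional [version_stamp()]; written as `#key=value` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_stamped_tsv <- function(df, path, stamp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp))
    writeLines(paste0("#", names(stamp), "=", stamp), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read the provenance stamp of a TSV
#'
#' @param path file path.
#' @return named character vector of `#key=value` header fields (empty if
#'   none).
#' @export
read_stamp <- function(path) {
  out <- character(0)
  for (ln in readLines(path, n = 10L)) {
    if (!startsWith(ln, "#")) break
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    out[substr(kv, 1, eq - 1)] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}

#' Write per-variant summary statistics
#'
#' One row per variant with exactly the GWIS summary columns; missing values
#' written as '.'.
#'
#' @param stats summary-statistics data frame.
#' @param path output path.
#' @param stamp optional provenance stamp.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path, stamp = NULL) {
  miss <- setdiff(.SUMMARY_COLS, names(stats))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  write_stamped_tsv(stats[, .SUMMARY_COLS], path, stamp)
}

#' Read per-variant summary statistics
#'
#' Validates the header against the summary-statistics schema, parses '.' as
#' missing, and reports the 1-based line number of any malformed row.
#'
#' @param path TSV path (provenance header lines, `#...`, are skipped).
#' @return summary-statistics data frame.
#' @export
read_summary_stats <- function(path) {
  lines <- readLines(path)
  skip <- which(!startsWith(lines, "#"))[1]
  if (is.na(skip)) stop("no header row in ", path)
  header <- strsplit(lines[skip], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(.SUMMARY_COLS, header)
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  body <- lines[-seq_len(skip)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop("malformed row at line ", skip + bad, " of ", path, ": expected ",
         length(header), " fields, found ", nf[bad])
  }
  m <- do.call(rbind, fields)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  for (col in header) {
    if (col %in% .SUMMARY_CHR) next
    v <- df[[col]]
    v[v == "."] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("malformed value in column '", col, "' at line ",
           skip + bad[1], " of ", path)
    df[[col]] <- num
  }
  df[, .SUMMARY_COLS]
}

#' Read a known-loci catalog
#'
#' Plain TSV with columns `chrom`, `pos` and optional `id`, `trait`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_known_loci <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop("known-loci catalog needs 'chrom' and 'pos' columns")
  df
}

#' Read a cohort manifest
#'
#' YAML mapping cohort id to population (AFR, BRA, EAS, EUR, HIS, SAS),
#' summary-statistics path and sample size.
#'
#' @param path YAML path.
#' @return list of cohort entries.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  pops <- vapply(man$cohorts, `[[`, "", "population")
  bad <- setdiff(pops, c("AFR", "BRA", "EAS", "EUR", "HIS", "SAS"))
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "))
  man
}
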