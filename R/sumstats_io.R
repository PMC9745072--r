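# Reading and writing GWAS summary-statistics tables.
#
# A summary-statistics table is an ordinary data.frame with one row per
# variant and the canonical columns
#   rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n, trait
# (chrom/pos/eaf/pval/n/trait may be NA).  chrom/pos are carried as annotation
# only; variants are always matched across studies by rsid, never by position,
# because two studies may report different genome builds.

SUMSTATS_FIELDS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n", "trait")
MANDATORY_FIELDS <- c("rsid", "effect_allele", "other_allele", "beta", "se")

#' Describe how a summary-statistics file maps onto the canonical columns
#'
#' @param rsid,chrom,pos,effect_allele,other_allele,eaf,beta,se,pval,n Source
#'   column names. `rsid`, `effect_allele`, `other_allele`, `beta` and `se`
#'   are mandatory; pass `NULL` for any optional field absent from the file.
#' @param delim Field delimiter (default tab).
#' @param na Missing-value sentinel(s) in the file.
#' @return An object of class `column_map`.
#' @seealso [gwas_catalog_map()] for the GWAS-catalog harmonised preset.
#' @export
column_map <- function(rsid = "rsid", chrom = "chrom", pos = "pos",
                       effect_allele = "effect_allele",
                       other_allele = "other_allele", eaf = "eaf",
                       beta = "beta", se = "se", pval = "pval", n = "n",
                       delim = "\t", na = c("NA", "")) {
  map <- list(rsid = rsid, chrom = chrom, pos = pos,
              effect_allele = effect_allele, other_allele = other_allele,
              eaf = eaf, beta = beta, se = se, pval = pval, n = n)
  missing_mand <- MANDATORY_FIELDS[vapply(map[MANDATORY_FIELDS], is.null, logical(1))]
  if (length(missing_mand)) {
    stop("mandatory column-map fields missing: ",
         paste(missing_mand, collapse = ", "), call. = FALSE)
  }
  structure(list(map = map, delim = delim, na = na), class = "column_map")
}

#' Column-map preset for GWAS-catalog harmonised summary statistics
#'
#' Maps the harmonised column names used by GWAS-catalog downloads
#' (`hm_rsid`, `hm_effect_allele`, ...), the format in which both the
#' heart-failure (GCST009541) and Alzheimer's-disease (GCST90027158)
#' studies are distributed.
#'
#' @inheritParams column_map
#' @return A `column_map`.
#' @export
gwas_catalog_map <- function(delim = "\t", na = c("NA", "")) {
  column_map(rsid = "hm_rsid", chrom = "hm_chrom", pos = "hm_pos",
             effect_allele = "hm_effect_allele",
             other_allele = "hm_other_allele",
             eaf = "effect_allele_frequency", beta = "hm_beta",
             se = "standard_error", pval = "p_value", n = NULL,
             delim = delim, na = na)
}

# Validate rows against the variant-record invariants, dropping (not
# aborting on) rows that fail.  Returns the kept rows with a `drops`
# attribute recording rsid + reason for every removal.
#' @noRd
validate_sumstats <- function(dat, trait = NA_character_) {
  dat$effect_allele <- toupper(trimws(as.character(dat$effect_allele)))
  dat$other_allele <- toupper(trimws(as.character(dat$other_allele)))
  dat$rsid <- as.character(dat$rsid)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
  }
  if (!"trait" %in% names(dat) || all(is.na(dat$trait))) {
    dat$trait <- rep(trait, nrow(dat))
  }

  reason <- rep(NA_character_, nrow(dat))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(dat$rsid) | dat$rsid == "", "missing rsid")
  reason <- flag(!dat$effect_allele %in% c("A", "C", "G", "T") |
                   !dat$other_allele %in% c("A", "C", "G", "T"),
                 "allele not a single-nucleotide A/C/G/T")
  reason <- flag(dat$effect_allele == dat$other_allele, "identical alleles")
  reason <- flag(is.na(dat$beta), "unparseable or missing beta")
  reason <- flag(is.na(dat$se) | dat$se <= 0, "standard error not > 0")
  reason <- flag(!is.na(dat$pval) & (dat$pval <= 0 | dat$pval > 1),
                 "p-value outside (0, 1]")
  reason <- flag(!is.na(dat$eaf) & (dat$eaf < 0 | dat$eaf > 1),
                 "eaf outside [0, 1]")

  bad <- !is.na(reason)
  drops <- data.frame(rsid = dat$rsid[bad], reason = reason[bad],
                      stringsAsFactors = FALSE)
  out <- dat[!bad, SUMSTATS_FIELDS, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file, renames columns through a [column_map()],
#' uppercases alleles, and drops rows violating the variant-record
#' invariants (non-ACGT alleles, `se <= 0`, p-values outside `(0, 1]`,
#' unparseable numerics), preserving input row order.  Dropped rows are not
#' an error: they are counted and the reasons recorded.
#'
#' @param path File path.
#' @param map A [column_map()]; default [gwas_catalog_map()].
#' @param trait Free-text trait label attached to every record.
#' @return A summary-statistics data.frame with attributes `drops` (a
#'   data.frame of rsid/reason for each dropped row) and `n_dropped`.
#' @export
read_sumstats <- function(path, map = gwas_catalog_map(), trait = NA_character_) {
  stopifnot(inherits(map, "column_map"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = map$delim,
                           na.strings = map$na, colClasses = "character",
                           check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- unlist(map$map[MANDATORY_FIELDS])
  absent <- need[!need %in% names(raw)]
  if (length(absent)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(matrix(nrow = nrow(raw), ncol = 0))
  for (field in SUMSTATS_FIELDS[SUMSTATS_FIELDS != "trait"]) {
    src <- map$map[[field]]
    dat[[field]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]]
                    else rep(NA, nrow(raw))
  }
  out <- validate_sumstats(dat, trait = trait)
  attr(out, "n_dropped") <- nrow(attr(out, "drops"))
  out
}

#' The five heart-failure instruments from the CVDKP HF GWAS
#'
#' The five genome-wide-significant, mutually independent SNPs used as
#' instruments for genetically predicted heart failure (exposure GWAS
#' GCST009541: 47,309 cases / 930,014 controls of European ancestry).
#' Effect sizes are per-allele log-odds ratios for heart failure.
#'
#' The `f_reported` column carries the instrument-strength F statistic as
#' published alongside these instruments, computed from unrounded summary
#' statistics; recomputing `beta^2/se^2` from the rounded values printed
#' here gives slightly different numbers (e.g. 31.2 rather than 32.31 for
#' rs1510226).  Use [f_statistic()] on `beta`/`se` when you need a value
#' consistent with the rest of a computation, and `f_reported` when you
#' need the published figure.
#'
#' @return A summary-statistics data.frame of 5 rows with the extra columns
#'   `gene` and `f_reported`.
#' @export
hf_instruments <- function() {
  path <- system.file("extdata", "hf_instruments.tsv", package = "twosmr",
                      mustWork = TRUE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           stringsAsFactors = FALSE)
  dat <- validate_sumstats(raw[SUMSTATS_FIELDS[SUMSTATS_FIELDS != "trait"]],
                           trait = "heart failure")
  dat$gene <- raw$gene
  dat$f_reported <- raw$f_reported
  dat
}

#' Write a result table to delimited text
#'
#' Writes any result data.frame (MR estimates, heterogeneity, leave-one-out,
#' ...) as tab-separated text with a header; numeric values round-trip
#' through [utils::read.table()] to full double precision.
#'
#' @param results A data.frame.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an exclusion list
#'
#' One rsid per line, optionally followed by a tab and a free-text reason
#' (e.g. variants flagged by an external phenome screen such as PhenoScanner
#' as directly associated with the outcome).
#'
#' @param path File path.
#' @return data.frame with columns `rsid` and `reason`.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(rsid = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(rsid = vapply(parts, `[`, "", 1),
             reason = vapply(parts, function(p)
               if (length(p) > 1) p[2] else "listed for exclusion", ""),
             stringsAsFactors = FALSE)
}
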