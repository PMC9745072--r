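# Instrument selection: significance filtering, LD clumping, exclusion
# screening, proxy lookup, and instrument-strength F statistics.

#' Filter associations at a genome-wide significance threshold
#'
#' @param assocs Summary-statistics data.frame.
#' @param p_threshold Keep records with `pval < p_threshold`
#'   (default `5e-8`, the conventional genome-wide level).
#' @return The qualifying subset, input order preserved.
#' @export
filter_genomewide <- function(assocs, p_threshold = 5e-8) {
  if (any(is.na(assocs$pval))) {
    stop("all records must carry a p-value to filter on significance",
         call. = FALSE)
  }
  out <- assocs[assocs$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a pairwise-LD matrix
#'
#' Builds the symmetric r-squared matrix used by [clump()] from a long
#' table of pairs.  Unlisted pairs have r-squared 0; the diagonal is 1.
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2`.
#' @param rsids Optional character vector fixing the variant set/order;
#'   defaults to the variants appearing in `pairs`.
#' @return An object of class `ld_matrix`: list with `rsid` and the
#'   `r2` matrix.
#' @export
ld_matrix <- function(pairs, rsids = NULL) {
  stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(pairs)))
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
    stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  }
  rsids <- rsids %||% unique(c(pairs$rsid_a, pairs$rsid_b))
  m <- matrix(0, length(rsids), length(rsids), dimnames = list(rsids, rsids))
  diag(m) <- 1
  keep <- pairs$rsid_a %in% rsids & pairs$rsid_b %in% rsids
  pairs <- pairs[keep, , drop = FALSE]
  m[cbind(pairs$rsid_a, pairs$rsid_b)] <- pairs$r2
  m[cbind(pairs$rsid_b, pairs$rsid_a)] <- pairs$r2
  structure(list(rsid = rsids, r2 = m), class = "ld_matrix")
}

#' Read pairwise LD from a 3-column text file
#'
#' Plain whitespace- or tab-delimited `rsidA rsidB r2` rows (header
#' optional, detected from a non-numeric third field on line one).
#'
#' @param path File path.
#' @param rsids Passed through to [ld_matrix()].
#' @return An `ld_matrix`.
#' @export
read_ld_pairs <- function(path, rsids = NULL) {
  first <- utils::read.table(path, nrows = 1, stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[3]])))
  dat <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  names(dat)[1:3] <- c("rsid_a", "rsid_b", "r2")
  ld_matrix(dat, rsids = rsids)
}

#' @noRd
check_ld <- function(ld) {
  if (!inherits(ld, "ld_matrix") || !is.matrix(ld$r2) ||
      nrow(ld$r2) != ncol(ld$r2) || !isTRUE(all.equal(ld$r2, t(ld$r2))) ||
      any(ld$r2 < 0 | ld$r2 > 1) || any(abs(diag(ld$r2) - 1) > 1e-12)) {
    stop("malformed LD matrix: need a symmetric r2 matrix in [0,1] with unit diagonal",
         call. = FALSE)
  }
  invisible(ld)
}

#' Greedy p-value-ranked LD clumping
#'
#' Standard clumping semantics: repeatedly take the remaining record with
#' the smallest p-value as an index variant and discard every remaining
#' record on the same chromosome within `window_kb` of it whose r-squared
#' with the index is at least `r2_max`.  The returned set is mutually below
#' `r2_max` within the window.  P-value ties break lexicographically by
#' rsid, so the result does not depend on input order.
#'
#' Variants absent from `ld` are treated as independent (r-squared 0) with
#' a warning rather than dropped.  Variants with missing chromosome or
#' position are always considered within the window, so the r-squared rule
#' alone decides.
#'
#' @param assocs Summary-statistics data.frame (needs `pval`; `chrom`/`pos`
#'   used for the distance window).
#' @param ld An [ld_matrix()].
#' @param window_kb Half-width of the physical window around the index
#'   variant, in kilobases (default 10,000 kb).
#' @param r2_max Records with r-squared `>= r2_max` to an index variant are
#'   discarded (default 0.001).
#' @return The independent subset, ordered by selection (ascending p-value),
#'   with attribute `removed` (data.frame rsid, index_rsid, r2).
#' @export
clump <- function(assocs, ld, window_kb = 10000, r2_max = 0.001) {
  check_ld(ld)
  if (any(is.na(assocs$pval))) {
    stop("clumping requires a p-value for every record", call. = FALSE)
  }
  absent <- setdiff(assocs$rsid, ld$rsid)
  if (length(absent)) {
    warning("variant(s) absent from the LD matrix treated as independent: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  r2_of <- function(a, b) {
    if (a %in% ld$rsid && b %in% ld$rsid) ld$r2[a, b] else 0
  }
  ord <- order(assocs$pval, assocs$rsid)
  pool <- assocs[ord, , drop = FALSE]
  kept_idx <- integer()
  removed <- data.frame(rsid = character(), index_rsid = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  while (nrow(pool) > 0) {
    index <- pool[1, ]
    kept_idx <- c(kept_idx, which(assocs$rsid == index$rsid)[1])
    pool <- pool[-1, , drop = FALSE]
    if (nrow(pool) == 0) break
    same_chrom <- !is.na(index$chrom) & !is.na(pool$chrom) &
      pool$chrom == index$chrom
    near <- is.na(index$pos) | is.na(pool$pos) |
      abs(pool$pos - index$pos) <= window_kb * 1000
    in_window <- (same_chrom & near) |
      (is.na(index$chrom) | is.na(pool$chrom))
    r2 <- vapply(pool$rsid, r2_of, numeric(1), b = index$rsid)
    drop <- in_window & r2 >= r2_max
    if (any(drop)) {
      removed <- rbind(removed, data.frame(
        rsid = pool$rsid[drop], index_rsid = index$rsid, r2 = r2[drop],
        stringsAsFactors = FALSE))
      pool <- pool[!drop, , drop = FALSE]
    }
  }
  out <- assocs[kept_idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Remove listed variants with an audit trail
#'
#' Applies a user-supplied exclusion list (e.g. variants an external
#' phenome-wide screen linked directly to the outcome) to an instrument set.
#'
#' @param assocs Summary-statistics data.frame.
#' @param exclusions Character vector of rsids, or a data.frame with
#'   columns `rsid` and `reason` as from [read_exclusion_list()].
#' @return The remaining records with attribute `audit` (data.frame of the
#'   removals with reasons).  Listed rsids not present in `assocs` trigger
#'   a warning and are otherwise ignored.
#' @export
apply_exclusions <- function(assocs, exclusions) {
  if (is.character(exclusions)) {
    exclusions <- data.frame(rsid = exclusions,
                             reason = rep("listed for exclusion",
                                          length(exclusions)),
                             stringsAsFactors = FALSE)
  }
  unknown <- setdiff(exclusions$rsid, assocs$rsid)
  if (length(unknown)) {
    warning("exclusion list rsid(s) not present in the instrument set: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit <- assocs$rsid %in% exclusions$rsid
  audit <- merge(data.frame(rsid = assocs$rsid[hit], stringsAsFactors = FALSE),
                 exclusions, by = "rsid", sort = FALSE)
  out <- assocs[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Find an LD proxy present in the outcome study
#'
#' If `rsid` itself is present in `outcome_rsids` it is returned.  Otherwise
#' the proxy with the highest r-squared strictly above `r2_min` that is
#' present in the outcome is returned, or `NA` if none qualifies.
#'
#' @param rsid Query variant.
#' @param outcome_rsids Character vector of variants available in the
#'   outcome study.
#' @param proxies data.frame with columns `rsid`, `proxy_rsid`, `r2`.
#' @param r2_min Proxies must have `r2 > r2_min` (default 0.8).
#' @return A single rsid or `NA_character_`.
#' @export
find_proxy <- function(rsid, outcome_rsids, proxies, r2_min = 0.8) {
  if (rsid %in% outcome_rsids) return(rsid)
  if (is.null(proxies) || !nrow(proxies)) return(NA_character_)
  cand <- proxies[proxies$rsid == rsid &
                    proxies$r2 > r2_min &
                    proxies$proxy_rsid %in% outcome_rsids, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  cand$proxy_rsid[which.max(cand$r2)]
}

#' Instrument-strength F statistic
#'
#' `F = beta^2 / se^2` for the variant-exposure association.  `F <= 10` is
#' the conventional weak-instrument flag (see [is_weak_instrument()]).
#'
#' @param beta,se Effect estimate and standard error (vectorised).
#' @return F values (`>= 0`).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) stop("`se` must be > 0", call. = FALSE)
  (beta / se)^2
}

#' Weak-instrument flag
#'
#' @param f F statistic(s) from [f_statistic()].
#' @param threshold Flag instruments with `f <= threshold` (default 10).
#' @return Logical vector.
#' @export
is_weak_instrument <- function(f, threshold = 10) f <= threshold
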