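# Allele harmonization: align exposure and outcome associations to a common
# effect allele, resolving allele swaps and strand flips, and handling
# palindromic (A/T, C/G) variants whose strand cannot be read off the
# alleles alone.

#' @noRd
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Classify the allele configuration of an exposure/outcome pair
#'
#' @param exp_a1,exp_a2 Exposure effect and other allele.
#' @param out_a1,out_a2 Outcome effect and other allele.
#' @return One of `"same"`, `"swapped"`, `"complement_same"`,
#'   `"complement_swapped"`, `"palindromic"` (the exposure pair is A/T or
#'   C/G, so strand is ambiguous), or `"incompatible"`.  Vectorised.
#' @export
classify_alleles <- function(exp_a1, exp_a2, out_a1, out_a2) {
  ok <- function(x) x %in% names(COMPLEMENT)
  if (any(!ok(exp_a1) | !ok(exp_a2) | !ok(out_a1) | !ok(out_a2))) {
    stop("alleles must be single nucleotides A/C/G/T", call. = FALSE)
  }
  pal <- exp_a1 == COMPLEMENT[exp_a2]
  same_set <- (out_a1 == exp_a1 & out_a2 == exp_a2) |
    (out_a1 == exp_a2 & out_a2 == exp_a1)
  cls <- rep("incompatible", length(exp_a1))
  cls[pal & same_set] <- "palindromic"
  np <- !pal
  cls[np & out_a1 == exp_a1 & out_a2 == exp_a2] <- "same"
  cls[np & out_a1 == exp_a2 & out_a2 == exp_a1] <- "swapped"
  cls[np & COMPLEMENT[out_a1] == exp_a1 & COMPLEMENT[out_a2] == exp_a2] <-
    "complement_same"
  cls[np & COMPLEMENT[out_a1] == exp_a2 & COMPLEMENT[out_a2] == exp_a1] <-
    "complement_swapped"
  cls
}

#' @noRd
empty_harmonised <- function(n = 0) {
  data.frame(rsid = character(n), effect_allele = character(n),
             other_allele = character(n),
             beta_exposure = numeric(n), se_exposure = numeric(n),
             eaf_exposure = numeric(n),
             beta_outcome = numeric(n), se_outcome = numeric(n),
             eaf_outcome = numeric(n),
             action = character(n), proxy_rsid = rep(NA_character_, n),
             dropped = logical(n), drop_reason = character(n),
             stringsAsFactors = FALSE)
}

#' Harmonise one exposure/outcome record pair
#'
#' Aligns the outcome association to the exposure's effect allele:
#'
#' * identical orientation: copied (`kept_as_is`);
#' * alleles swapped (directly or as reverse complements): the outcome beta
#'   is negated and its EAF replaced by `1 - eaf` (`outcome_flipped`);
#' * same alleles on the opposite strand: copied (`strand_complemented`);
#' * palindromic variant: orientation is inferred from allele-frequency
#'   concordance, but only when both EAFs are available and both fall
#'   outside the ambiguity band `[0.5 - band, 0.5 + band]`; if the two
#'   frequencies lie on the same side of 0.5 the record is kept as is,
#'   otherwise the outcome is flipped (`palindromic_inferred`).  A
#'   palindromic variant with an intermediate or (in strict mode) missing
#'   frequency is dropped;
#' * incompatible alleles: dropped.
#'
#' @param exp,out Single-row summary-statistics data.frames for the same
#'   rsid.
#' @param ambiguity_band Half-width of the intermediate-frequency band
#'   around 0.5 within which palindromic variants are unresolvable
#'   (default 0.08, i.e. EAF in \[0.42, 0.58\]).
#' @param strict If `TRUE` (default), palindromic variants missing an EAF on
#'   either side are dropped; if `FALSE`, both studies are assumed to report
#'   the same strand and the alleles are compared directly.
#' @return A one-row harmonised data.frame (see [harmonise()]).
#' @export
harmonise_pair <- function(exp, out, ambiguity_band = 0.08, strict = TRUE) {
  if (exp$rsid != out$rsid) {
    stop("exposure and outcome records are for different variants (",
         exp$rsid, " vs ", out$rsid, ")", call. = FALSE)
  }
  rec <- empty_harmonised(1)
  rec$rsid <- exp$rsid
  rec$effect_allele <- exp$effect_allele
  rec$other_allele <- exp$other_allele
  rec$beta_exposure <- exp$beta
  rec$se_exposure <- exp$se
  rec$eaf_exposure <- exp$eaf
  rec$beta_outcome <- out$beta
  rec$se_outcome <- out$se
  rec$eaf_outcome <- out$eaf
  rec$proxy_rsid <- NA_character_
  rec$dropped <- FALSE
  rec$drop_reason <- ""

  keep_as <- function(rec, action) { rec$action <- action; rec }
  flip <- function(rec, action) {
    rec$beta_outcome <- -rec$beta_outcome
    rec$eaf_outcome <- 1 - rec$eaf_outcome
    rec$action <- action
    rec
  }
  drop <- function(rec, reason) {
    rec$dropped <- TRUE
    rec$drop_reason <- reason
    rec$action <- "dropped"
    rec
  }

  cls <- classify_alleles(exp$effect_allele, exp$other_allele,
                          out$effect_allele, out$other_allele)
  if (cls == "same") return(keep_as(rec, "kept_as_is"))
  if (cls == "complement_same") return(keep_as(rec, "strand_complemented"))
  if (cls %in% c("swapped", "complement_swapped")) {
    return(flip(rec, "outcome_flipped"))
  }
  if (cls == "incompatible") return(drop(rec, "incompatible alleles"))

  # palindromic
  if (!strict && out$effect_allele == exp$effect_allele) {
    return(keep_as(rec, "palindromic_inferred"))
  }
  if (!strict && out$effect_allele == exp$other_allele) {
    return(flip(rec, "palindromic_inferred"))
  }
  if (is.na(exp$eaf) || is.na(out$eaf)) {
    return(drop(rec, "palindromic, missing allele frequency"))
  }
  intermediate <- abs(exp$eaf - 0.5) <= ambiguity_band |
    abs(out$eaf - 0.5) <= ambiguity_band
  if (intermediate) {
    return(drop(rec, "palindromic, intermediate allele frequency"))
  }
  if ((exp$eaf < 0.5) == (out$eaf < 0.5)) {
    keep_as(rec, "palindromic_inferred")
  } else {
    flip(rec, "palindromic_inferred")
  }
}

#' Harmonise an instrument set against an outcome study
#'
#' For each exposure instrument, locates the outcome record by rsid
#' (falling back to an LD proxy via [find_proxy()] when a proxy table is
#' supplied) and harmonises the pair with [harmonise_pair()].  Records that
#' cannot be harmonised are retained with `dropped = TRUE` and a reason, so
#' the attrition from candidate instruments to analysable instruments is
#' fully auditable.
#'
#' @param exposure,outcome Summary-statistics data.frames.
#' @param proxies Optional proxy table (`rsid`, `proxy_rsid`, `r2`).
#' @param proxy_r2_min Minimum proxy r-squared (strict inequality;
#'   default 0.8).
#' @inheritParams harmonise_pair
#' @return Data.frame with one row per exposure instrument: common
#'   `effect_allele`/`other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`, the
#'   harmonisation `action`, `proxy_rsid` (NA unless a proxy supplied the
#'   outcome record), `dropped` and `drop_reason`.  Attribute `attrition`
#'   is a list with counts `input`, `matched`, `proxied`, `kept` and a
#'   `dropped_by_reason` table.  Rows usable for estimation are
#'   `!dropped`; see [harmonised_kept()].
#' @export
harmonise <- function(exposure, outcome, proxies = NULL, proxy_r2_min = 0.8,
                      ambiguity_band = 0.08, strict = TRUE) {
  assert_prob(ambiguity_band, "ambiguity_band")
  rows <- vector("list", nrow(exposure))
  n_proxied <- 0L
  for (i in seq_len(nrow(exposure))) {
    exp_i <- exposure[i, ]
    target <- find_proxy(exp_i$rsid, outcome$rsid, proxies,
                         r2_min = proxy_r2_min)
    if (is.na(target)) {
      rec <- empty_harmonised(1)
      rec$rsid <- exp_i$rsid
      rec$effect_allele <- exp_i$effect_allele
      rec$other_allele <- exp_i$other_allele
      rec$beta_exposure <- exp_i$beta
      rec$se_exposure <- exp_i$se
      rec$eaf_exposure <- exp_i$eaf
      rec$beta_outcome <- NA_real_
      rec$se_outcome <- NA_real_
      rec$eaf_outcome <- NA_real_
      rec$action <- "dropped"
      rec$proxy_rsid <- NA_character_
      rec$dropped <- TRUE
      rec$drop_reason <- "not found in outcome"
      rows[[i]] <- rec
      next
    }
    out_i <- outcome[match(target, outcome$rsid), ]
    if (target != exp_i$rsid) {
      # proxy record stands in for the query variant: harmonise on the
      # proxy's own alleles/frequencies, report under the query rsid
      n_proxied <- n_proxied + 1L
      exp_proxy <- exp_i
      exp_proxy$rsid <- target
      rec <- harmonise_pair(exp_proxy, out_i, ambiguity_band = ambiguity_band,
                            strict = strict)
      rec$rsid <- exp_i$rsid
      rec$proxy_rsid <- target
    } else {
      rec <- harmonise_pair(exp_i, out_i, ambiguity_band = ambiguity_band,
                            strict = strict)
    }
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_harmonised(0)
  rownames(out) <- NULL
  reasons <- table(out$drop_reason[out$dropped])
  attr(out, "attrition") <- list(
    input = nrow(exposure),
    matched = sum(!out$dropped & is.na(out$proxy_rsid)),
    proxied = n_proxied,
    kept = sum(!out$dropped),
    dropped_by_reason = reasons
  )
  if (nrow(out) && !any(!out$dropped)) {
    warning("no instruments survived harmonization", call. = FALSE)
  }
  out
}

#' Harmonised records usable for estimation
#'
#' @param h Output of [harmonise()].
#' @return The non-dropped rows.
#' @export
harmonised_kept <- function(h) {
  out <- h[!h$dropped, , drop = FALSE]
  rownames(out) <- NULL
  out
}
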