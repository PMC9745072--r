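# Heterogeneity and pleiotropy diagnostics, sensitivity analyses, and
# homogeneous-subset selection.

#' Cochran Q heterogeneity test
#'
#' For the IVW reference, `Q = sum_j w_j (ratio_j - b)^2` over the Wald
#' ratios with `b` the fixed-effect IVW estimate (or a supplied reference)
#' and `df = m - 1`.  For MR-Egger, Q is the weighted residual sum of
#' squares of the Egger fit with `df = m - 2`.  The p-value is the
#' chi-square upper tail.
#'
#' @param h Harmonised data.frame.
#' @param method `"ivw"` (default) or `"egger"`.
#' @param reference_beta Optional fixed reference estimate for the IVW Q
#'   (defaults to the fixed-effect IVW estimate of `h`).
#' @return One-row data.frame `method`, `Q`, `df`, `pval`, with attribute
#'   `contributions`: per-variant Q terms (summing to Q).
#' @export
cochran_q <- function(h, method = c("ivw", "egger"), reference_beta = NULL) {
  method <- match.arg(method)
  if (method == "egger") {
    fit <- mr_egger(h)
    hh <- h[!(h$dropped %||% FALSE), , drop = FALSE]
    sgn <- ifelse(hh$beta_exposure < 0, -1, 1)
    resid <- sgn * hh$beta_outcome -
      (fit$intercept + fit$b * sgn * hh$beta_exposure)
    contrib <- resid^2 / hh$se_outcome^2
    out <- data.frame(method = "MR Egger", Q = sum(contrib),
                      df = nrow(hh) - 2,
                      pval = stats::pchisq(sum(contrib), nrow(hh) - 2,
                                           lower.tail = FALSE),
                      stringsAsFactors = FALSE)
    attr(out, "contributions") <- data.frame(rsid = hh$rsid, q = contrib,
                                             stringsAsFactors = FALSE)
    return(out)
  }
  r <- wald_ratios(h)
  m <- nrow(r)
  if (m < 2) stop("Cochran Q needs at least 2 instruments", call. = FALSE)
  b <- reference_beta %||% (sum(r$weight * r$ratio) / sum(r$weight))
  contrib <- r$weight * (r$ratio - b)^2
  out <- data.frame(method = "IVW", Q = sum(contrib), df = m - 1,
                    pval = stats::pchisq(sum(contrib), m - 1,
                                         lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "contributions") <- data.frame(rsid = r$rsid, q = contrib,
                                           stringsAsFactors = FALSE)
  out
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; a two-sided
#' t-test with `m - 2` degrees of freedom assesses departure from zero.
#'
#' @param h Harmonised data.frame (>= 3 usable instruments).
#' @return One-row data.frame `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  data.frame(intercept = fit$intercept, se = fit$intercept_se,
             pval = fit$intercept_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate `m` times, omitting one instrument each
#' time, and flags instruments whose omission shifts the estimate by more
#' than `flag_multiple` all-SNP standard errors.
#'
#' @param h Harmonised data.frame (>= 2 usable instruments).
#' @param ivw_mode Passed to [mr_ivw()].
#' @param flag_multiple Influence threshold in units of the all-SNP SE
#'   (default 1).
#' @return data.frame with one row per omitted variant plus a final
#'   `"All"` row; columns `rsid`, `b`, `se`, `pval`, `or`, `or_lo95`,
#'   `or_hi95`, `influential`.
#' @export
leave_one_out <- function(h, ivw_mode = "mre", flag_multiple = 1) {
  hh <- h[!(h$dropped %||% FALSE), , drop = FALSE]
  m <- nrow(hh)
  if (m < 2) stop("leave-one-out needs at least 2 instruments", call. = FALSE)
  all_fit <- mr_ivw(hh, mode = ivw_mode)
  rows <- lapply(seq_len(m), function(i) {
    fit <- mr_ivw(hh[-i, , drop = FALSE], mode = ivw_mode)
    data.frame(rsid = hh$rsid[i], b = fit$b, se = fit$se, pval = fit$pval,
               or = fit$or, or_lo95 = fit$or_lo95, or_hi95 = fit$or_hi95,
               influential = abs(fit$b - all_fit$b) > flag_multiple * all_fit$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(rsid = "All", b = all_fit$b, se = all_fit$se,
                               pval = all_fit$pval, or = all_fit$or,
                               or_lo95 = all_fit$or_lo95,
                               or_hi95 = all_fit$or_hi95,
                               influential = FALSE,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Single-SNP (forest-plot) analysis
#'
#' Per-variant Wald ratio estimates with 95% CIs plus combined IVW and (for
#' >= 3 instruments) MR-Egger rows — the data behind a forest plot.
#'
#' @param h Harmonised data.frame (>= 1 usable instrument).
#' @param ivw_mode Passed to [mr_ivw()].
#' @return data.frame with columns `rsid`, `b`, `se`, `pval`, `or`,
#'   `or_lo95`, `or_hi95`.
#' @export
single_snp_analysis <- function(h, ivw_mode = "mre") {
  r <- wald_ratios(h)
  ci <- to_odds_ratio(r$ratio, r$se)
  out <- data.frame(rsid = r$rsid, b = r$ratio, se = r$se,
                    pval = two_sided_normal_p(r$ratio / r$se),
                    or = ci$or, or_lo95 = ci$ci_low, or_hi95 = ci$ci_high,
                    stringsAsFactors = FALSE)
  combined <- list(mr_ivw(h, mode = ivw_mode))
  if (nrow(r) >= 3) combined <- c(combined, list(mr_egger(h)))
  for (fit in combined) {
    out <- rbind(out, data.frame(rsid = paste("All -", fit$method),
                                 b = fit$b, se = fit$se, pval = fit$pval,
                                 or = fit$or, or_lo95 = fit$or_lo95,
                                 or_hi95 = fit$or_hi95,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Funnel-plot data
#'
#' Per-variant `(ratio, precision)` pairs plus the combined reference
#' lines; symmetry of the ratios around the reference across precisions is
#' the visual check for directional pleiotropy.
#'
#' @param h Harmonised data.frame.
#' @return data.frame `rsid`, `ratio`, `precision` (`1/se`), with attribute
#'   `reference`: data.frame of method/estimate for the IVW and (if
#'   estimable) MR-Egger lines.
#' @export
funnel_data <- function(h) {
  r <- wald_ratios(h)
  out <- data.frame(rsid = r$rsid, ratio = r$ratio, precision = 1 / r$se,
                    stringsAsFactors = FALSE)
  ref <- data.frame(method = "IVW", estimate = mr_ivw(h)$b,
                    stringsAsFactors = FALSE)
  if (nrow(r) >= 3) {
    ref <- rbind(ref, data.frame(method = "MR Egger",
                                 estimate = mr_egger(h)$b,
                                 stringsAsFactors = FALSE))
  }
  attr(out, "reference") <- ref
  out
}

#' Select a homogeneous instrument subset
#'
#' Formalises the common practice of pruning heterogeneous instrument sets
#' (often done by eye from a leave-one-out plot) into a deterministic,
#' logged rule:
#'
#' * `"greedy_q"` (default): while the IVW Cochran-Q p-value is at or below
#'   `q_p_min` and more than 3 instruments remain, remove the instrument
#'   with the largest individual Q contribution (recomputed each round).
#' * `"exhaustive_small"` (m <= 12): enumerate all subsets of size >= 3 and
#'   return the largest subset whose Q p-value exceeds `q_p_min`, breaking
#'   size ties by the larger p-value (then lexicographically smallest rsid
#'   set, for determinism).
#'
#' @param h Harmonised data.frame (>= 3 usable instruments).
#' @param q_p_min Required Cochran-Q p-value (default 0.05).
#' @param strategy `"greedy_q"` or `"exhaustive_small"`.
#' @return List with elements `subset` (harmonised rows retained),
#'   `removed` (data.frame of removals with their Q contribution at
#'   removal time; empty for the exhaustive strategy beyond rsids),
#'   `q_pval` (final Q p-value), `success` (whether `q_pval > q_p_min`),
#'   and `strategy`.  When no qualifying subset exists the best one found
#'   is returned with `success = FALSE`.
#' @export
select_homogeneous_subset <- function(h, q_p_min = 0.05,
                                      strategy = c("greedy_q",
                                                   "exhaustive_small")) {
  strategy <- match.arg(strategy)
  hh <- h[!(h$dropped %||% FALSE), , drop = FALSE]
  m <- nrow(hh)
  if (m < 3) stop("subset selection needs at least 3 instruments", call. = FALSE)

  if (strategy == "greedy_q") {
    keep <- hh
    removed <- data.frame(rsid = character(), q_contribution = numeric(),
                          stringsAsFactors = FALSE)
    repeat {
      q <- cochran_q(keep)
      if (q$pval > q_p_min || nrow(keep) <= 3) break
      contrib <- attr(q, "contributions")
      worst <- contrib$rsid[which.max(contrib$q)]
      removed <- rbind(removed, data.frame(
        rsid = worst, q_contribution = max(contrib$q),
        stringsAsFactors = FALSE))
      keep <- keep[keep$rsid != worst, , drop = FALSE]
    }
    q <- cochran_q(keep)
    rownames(keep) <- NULL
    return(list(subset = keep, removed = removed, q_pval = q$pval,
                success = q$pval > q_p_min, strategy = strategy))
  }

  if (m > 12) {
    stop("exhaustive_small is limited to 12 instruments; use greedy_q",
         call. = FALSE)
  }
  best <- NULL
  for (size in seq(m, 3)) {
    combos <- utils::combn(m, size, simplify = FALSE)
    cand <- lapply(combos, function(ix) {
      sub <- hh[ix, , drop = FALSE]
      list(ix = ix, pval = cochran_q(sub)$pval)
    })
    ok <- Filter(function(x) x$pval > q_p_min, cand)
    pool <- if (length(ok)) ok else cand
    key <- vapply(pool, function(x)
      paste(hh$rsid[x$ix], collapse = ","), "")
    pick <- pool[[order(-vapply(pool, `[[`, 0, "pval"), key)[1]]]
    if (length(ok)) { best <- pick; break }
    if (is.null(best) || pick$pval > best$pval) best <- pick
  }
  keep <- hh[best$ix, , drop = FALSE]
  rownames(keep) <- NULL
  list(subset = keep,
       removed = data.frame(rsid = setdiff(hh$rsid, keep$rsid),
                            q_contribution = rep(NA_real_,
                                                 length(setdiff(hh$rsid,
                                                                keep$rsid))),
                            stringsAsFactors = FALSE),
       q_pval = best$pval, success = best$pval > q_p_min,
       strategy = strategy)
}
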