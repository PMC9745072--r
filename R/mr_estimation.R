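# The four causal estimators on harmonised summary statistics.
#
# Per-SNP Wald ratios feed the inverse-variance weighted, weighted-median
# and weighted-mode estimators; MR-Egger is fit directly as a weighted
# regression of outcome betas on exposure betas with an intercept.  All
# causal effects are on the log-odds-ratio scale and converted to odds
# ratios with 95% confidence intervals.

#' Per-SNP Wald ratio estimates
#'
#' `ratio = beta_outcome / beta_exposure`, with the first-order
#' delta-method standard error `se_outcome / |beta_exposure|` (exposure-side
#' uncertainty ignored, the convention under the no-measurement-error
#' approximation), and inverse-variance weight `1 / se^2`.
#'
#' @param h Harmonised data.frame from [harmonise()]; dropped rows are
#'   excluded automatically.
#' @return data.frame with columns `rsid`, `ratio`, `se`, `weight`.
#' @export
wald_ratios <- function(h) {
  h <- h[!(h$dropped %||% FALSE), , drop = FALSE]
  if (any(h$beta_exposure == 0)) {
    stop("zero exposure effect for variant(s): ",
         paste(h$rsid[h$beta_exposure == 0], collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(rsid = h$rsid,
                    ratio = h$beta_outcome / h$beta_exposure,
                    se = h$se_outcome / abs(h$beta_exposure),
                    stringsAsFactors = FALSE)
  out$weight <- 1 / out$se^2
  out
}

#' @noRd
mr_estimate_row <- function(method, nsnp, b, se, pval,
                            Q = NA_real_, Q_df = NA_real_, Q_pval = NA_real_,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_pval = NA_real_) {
  ci <- to_odds_ratio(b, se)
  data.frame(method = method, nsnp = nsnp, b = b, se = se, pval = pval,
             or = ci[["or"]], or_lo95 = ci[["ci_low"]],
             or_hi95 = ci[["ci_high"]],
             Q = Q, Q_df = Q_df, Q_pval = Q_pval,
             intercept = intercept, intercept_se = intercept_se,
             intercept_pval = intercept_pval,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' The precision-weighted mean of the per-SNP Wald ratios, equivalently the
#' slope of the `1/se^2`-weighted regression of outcome betas on exposure
#' betas through the origin.  The default `"mre"` mode (multiplicative
#' random effects) scales the fixed-effect standard error by
#' `max(1, sqrt(Q/(m-1)))`, so overdispersion across instruments widens the
#' interval but underdispersion never narrows it below the fixed-effect
#' one.  P-values are two-sided normal.
#'
#' @param h Harmonised data.frame (or anything accepted by [wald_ratios()]).
#' @param mode `"mre"` (default) or `"fixed"`.
#' @return One-row MR-estimate data.frame (`method`, `nsnp`, `b`, `se`,
#'   `pval`, `or`, `or_lo95`, `or_hi95`, `Q`, `Q_df`, `Q_pval`, and
#'   intercept columns that are `NA` for non-Egger methods).
#' @export
mr_ivw <- function(h, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  r <- wald_ratios(h)
  m <- nrow(r)
  if (m < 1) stop("IVW needs at least one instrument", call. = FALSE)
  b <- sum(r$weight * r$ratio) / sum(r$weight)
  se_fixed <- sqrt(1 / sum(r$weight))
  Q <- sum(r$weight * (r$ratio - b)^2)
  se <- se_fixed
  if (mode == "mre" && m >= 2) se <- se_fixed * max(1, sqrt(Q / (m - 1)))
  mr_estimate_row(if (mode == "fixed") "IVW (fixed)" else "IVW",
                  m, b, se, two_sided_normal_p(b / se),
                  Q = Q, Q_df = m - 1,
                  Q_pval = if (m >= 2) stats::pchisq(Q, m - 1, lower.tail = FALSE) else NA_real_)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept, weights `1/se_outcome^2`, after orienting every exposure beta
#' to be non-negative (outcome betas flipped along).  The slope estimates
#' the causal effect under the InSIDE assumption; the intercept estimates
#' average directional pleiotropy (see [egger_intercept_test()]).  Standard
#' errors use the multiplicative random-effects scale floored at 1
#' (`max(1, sqrt(Q'/(m-2)))`), p-values are two-sided t with `m - 2`
#' degrees of freedom.
#'
#' @param h Harmonised data.frame with at least 3 usable instruments.
#' @return One-row MR-estimate data.frame including `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h) {
  h <- h[!(h$dropped %||% FALSE), , drop = FALSE]
  m <- nrow(h)
  if (m < 3) stop("insufficient instruments for MR-Egger (need >= 3)", call. = FALSE)
  sgn <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- h$beta_exposure * sgn
  by <- h$beta_outcome * sgn
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  if (!"bx" %in% rownames(cf)) {
    stop("MR-Egger is undefined when the exposure effects are constant",
         call. = FALSE)
  }
  phi <- sqrt(sum(w * stats::residuals(fit)^2) / (m - 2))
  # lm's coefficient SEs already carry the residual scale phi; floor it at 1
  adj <- max(1, phi) / phi
  b_se <- cf["bx", "Std. Error"] * adj
  i_se <- cf["(Intercept)", "Std. Error"] * adj
  b <- cf["bx", "Estimate"]
  a <- cf["(Intercept)", "Estimate"]
  Qp <- sum(w * stats::residuals(fit)^2)
  mr_estimate_row("MR Egger", m, b, b_se,
                  2 * stats::pt(abs(b / b_se), m - 2, lower.tail = FALSE),
                  Q = Qp, Q_df = m - 2,
                  Q_pval = stats::pchisq(Qp, m - 2, lower.tail = FALSE),
                  intercept = a, intercept_se = i_se,
                  intercept_pval = 2 * stats::pt(abs(a / i_se), m - 2,
                                                 lower.tail = FALSE))
}

#' @noRd
boot_se <- function(ratios, ses, n_boot, seed, point_fun) {
  if (n_boot < 2) return(NA_real_)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      point_fun(stats::rnorm(length(ratios), ratios, ses))
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The Wald ratio at cumulative inverse-variance weight one half (linear
#' interpolation across the ordered ratios); consistent when at least half
#' of the total weight comes from valid instruments.  The standard error is
#' a parametric bootstrap: each ratio is resampled from
#' `Normal(ratio_j, se_j)` and the weighted median recomputed.
#'
#' @param h Harmonised data.frame with at least 3 usable instruments.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap stream (the caller's RNG state is
#'   left untouched).
#' @return One-row MR-estimate data.frame.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  r <- wald_ratios(h)
  if (nrow(r) < 3) {
    stop("insufficient instruments for the weighted median (need >= 3)",
         call. = FALSE)
  }
  b <- weighted_median(r$ratio, r$weight)
  se <- boot_se(r$ratio, r$se, n_boot, seed,
                function(x) weighted_median(x, r$weight))
  mr_estimate_row("Weighted median", nrow(r), b, se,
                  two_sided_normal_p(b / se))
}

#' @noRd
mode_bandwidth <- function(ratio, weight, bandwidth_factor = 1) {
  s <- min(weighted_mean_sd(ratio, weight)[["sd"]],
           weighted_mad(ratio, weight))
  bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
}

#' @noRd
mode_point <- function(ratio, weight, bw) {
  if (bw <= 0 || length(unique(ratio)) == 1) {
    # degenerate density: the most heavily weighted value
    agg <- tapply(weight, ratio, sum)
    return(as.numeric(names(agg)[which.max(agg)]))
  }
  d <- stats::density(ratio, weights = weight / sum(weight), bw = bw, n = 2048)
  d$x[which.max(d$y)]
}

#' Weighted-mode estimator
#'
#' The mode of an inverse-variance-weighted Gaussian kernel density over
#' the Wald ratios; consistent when the largest homogeneous cluster of
#' instruments is valid.  The bandwidth follows a modified Silverman
#' rule-of-thumb on the precision-weighted ratios,
#' `0.9 * min(weighted sd, weighted MAD) * m^(-1/5)`, scaled by
#' `bandwidth_factor`.  The standard error is the same parametric
#' bootstrap as [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth
#'   (default 1).
#' @return One-row MR-estimate data.frame.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL) {
  r <- wald_ratios(h)
  if (nrow(r) < 3) {
    stop("insufficient instruments for the weighted mode (need >= 3)",
         call. = FALSE)
  }
  bw <- mode_bandwidth(r$ratio, r$weight, bandwidth_factor)
  b <- mode_point(r$ratio, r$weight, bw)
  se <- boot_se(r$ratio, r$se, n_boot, seed, function(x) {
    mode_point(x, r$weight, mode_bandwidth(x, r$weight, bandwidth_factor))
  })
  mr_estimate_row("Weighted mode", nrow(r), b, se,
                  two_sided_normal_p(b / se))
}

#' Convert a log odds ratio to an odds ratio with 95% CI
#'
#' @param beta Causal log odds ratio(s).
#' @param se Standard error(s) (`>= 0`).
#' @return data.frame with columns `or`, `ci_low`, `ci_high`
#'   (`exp(beta)` and `exp(beta -/+ 1.959964 * se)`).
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(!is.na(se) & se < 0)) stop("`se` must be >= 0", call. = FALSE)
  data.frame(or = exp(beta), ci_low = exp(beta - Z95 * se),
             ci_high = exp(beta + Z95 * se))
}

#' Run the standard battery of 2SMR estimators
#'
#' @param h Harmonised data.frame.
#' @param methods Any of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"` (default all four).
#' @param ivw_mode Passed to [mr_ivw()].
#' @param n_boot,seed Passed to the bootstrap-based estimators; the
#'   weighted-mode bootstrap uses `seed + 1` so the two stochastic SEs use
#'   distinct streams.
#' @param bandwidth_factor Passed to [mr_weighted_mode()].
#' @return MR-estimate data.frame, one row per method.
#' @export
mr_all <- function(h, methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                   ivw_mode = "mre", n_boot = 1000, seed = NULL,
                   bandwidth_factor = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  if ("ivw" %in% methods) rows$ivw <- mr_ivw(h, mode = ivw_mode)
  if ("egger" %in% methods) rows$egger <- mr_egger(h)
  if ("weighted_median" %in% methods) {
    rows$wmedian <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  }
  if ("weighted_mode" %in% methods) {
    rows$wmode <- mr_weighted_mode(h, bandwidth_factor = bandwidth_factor,
                                   n_boot = n_boot,
                                   seed = if (is.null(seed)) NULL else seed + 1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
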