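# Instrument R-squared and statistical power for a binary outcome.

#' Per-variant exposure variance explained
#'
#' Two conventions are implemented, because published analyses rarely state
#' which their power calculation used:
#'
#' * `"eaf"` (default): `2 * beta^2 * eaf * (1 - eaf)`, the variance
#'   explained on the standardised-trait scale;
#' * `"f"`: `F / (F + n - 2)` with `F = beta^2/se^2`, the
#'   sample-size-based equivalent.
#'
#' The instrument set's total R-squared is the sum over variants.
#'
#' @param beta Per-allele effect(s).
#' @param se Standard error(s) (required for `method = "f"`).
#' @param eaf Effect-allele frequencies in (0,1) (required for
#'   `method = "eaf"`).
#' @param n Exposure-study sample size (required for `method = "f"`).
#' @param method `"eaf"` or `"f"`.
#' @param rsid Optional labels used in error messages.
#' @return Numeric vector of per-variant R-squared values.
#' @export
snp_r2 <- function(beta, se = NULL, eaf = NULL, n = NULL,
                   method = c("eaf", "f"), rsid = NULL) {
  method <- match.arg(method)
  lab <- function(i) if (is.null(rsid)) paste0("#", i) else rsid[i]
  if (method == "eaf") {
    if (is.null(eaf)) stop("`eaf` is required for the eaf R2 convention", call. = FALSE)
    bad <- which(is.na(eaf) | eaf <= 0 | eaf >= 1)
    if (length(bad)) {
      stop("missing or out-of-range eaf for variant(s): ",
           paste(vapply(bad, lab, ""), collapse = ", "), call. = FALSE)
    }
    return(2 * beta^2 * eaf * (1 - eaf))
  }
  if (is.null(se) || is.null(n)) {
    stop("`se` and `n` are required for the F-based R2 convention", call. = FALSE)
  }
  f <- f_statistic(beta, se)
  f / (f + n - 2)
}

#' Power of a two-sample MR test with a binary outcome
#'
#' The standard normal approximation for the power of the IVW test of a
#' causal log odds ratio `b` against zero at two-sided level `alpha`:
#' `power = Phi(|b| * sqrt(n * r2 * K * (1 - K)) - z_{1 - alpha/2})`,
#' where `n` is the outcome-study size, `K` its case fraction, and `r2`
#' the exposure variance explained by the instruments.  Only the tail on
#' the side of the true effect is counted, matching the convention of the
#' widely used online 2SMR power calculators.
#'
#' @param n_outcome Total outcome sample size.
#' @param case_fraction Outcome case fraction `K` in (0,1).
#' @param b Causal log odds ratio.
#' @param r2 Instrument R-squared in (0,1), e.g. `sum(snp_r2(...))`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0,1).
#' @export
binary_outcome_power <- function(n_outcome, case_fraction, b, r2,
                                 alpha = 0.05) {
  assert_prob(case_fraction, "case_fraction", open_left = TRUE, open_right = TRUE)
  assert_prob(r2, "r2", open_left = FALSE, open_right = TRUE)
  assert_prob(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  stopifnot(n_outcome > 0)
  ncp <- abs(b) * sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Power summary for an instrument table under both R-squared conventions
#'
#' Convenience wrapper: sums [snp_r2()] over an instrument set under the
#' `"eaf"` and (when `se`/`n` permit) `"f"` conventions and evaluates
#' [binary_outcome_power()] for each.
#'
#' @param instruments Summary-statistics data.frame of the exposure
#'   instruments.
#' @inheritParams binary_outcome_power
#' @param n_exposure Exposure-study size for the F-based convention
#'   (default: the instruments' `n` column).
#' @return data.frame with one row per convention: `r2_method`, `r2`,
#'   `power`.
#' @export
mr_power_analysis <- function(instruments, n_outcome, case_fraction, b,
                              alpha = 0.05, n_exposure = NULL) {
  r2_eaf <- sum(snp_r2(instruments$beta, eaf = instruments$eaf,
                       method = "eaf", rsid = instruments$rsid))
  out <- data.frame(r2_method = "eaf", r2 = r2_eaf,
                    power = binary_outcome_power(n_outcome, case_fraction,
                                                 b, r2_eaf, alpha),
                    stringsAsFactors = FALSE)
  n_exp <- n_exposure %||% instruments$n
  if (!is.null(n_exp) && all(!is.na(n_exp))) {
    r2_f <- sum(snp_r2(instruments$beta, se = instruments$se, n = n_exp,
                       method = "f", rsid = instruments$rsid))
    out <- rbind(out, data.frame(
      r2_method = "f", r2 = r2_f,
      power = binary_outcome_power(n_outcome, case_fraction, b, r2_f, alpha),
      stringsAsFactors = FALSE))
  }
  out
}
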