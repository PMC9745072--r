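# Internal helpers shared across modules.

Z95 <- 1.959964

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state; the caller's stream is untouched.
# Used wherever a user-supplied seed controls a bootstrap.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Weighted median with linear interpolation on the cumulative-weight scale:
# s_j = (cumsum(w)_j - w_j/2) / sum(w), estimate = x at s = 0.5.
#' @noRd
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' @noRd
weighted_mean_sd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  m <- length(x)
  v <- sum(w * (x - mu)^2) * m / max(1, m - 1)
  c(mean = mu, sd = sqrt(v))
}

# Weighted analogue of stats::mad built on the interpolated weighted median.
#' @noRd
weighted_mad <- function(x, w, constant = 1.4826) {
  med <- weighted_median(x, w)
  constant * weighted_median(abs(x - med), w)
}

#' @noRd
two_sided_normal_p <- function(z) 2 * stats::pnorm(-abs(z))

#' @noRd
assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!all(is.finite(x) & lo_ok & hi_ok)) {
    stop(sprintf("`%s` must lie in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}
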