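test_that("Wald ratios follow the delta-method definition", {
  h <- make_harmonised(c(0, 2), c(0.5, 0.5),
                       beta_exposure = c(0.1, 0.1))
  r <- wald_ratios(h)
  expect_equal(r$ratio, c(0, 2))
  expect_equal(r$se, c(0.5, 0.5))
  expect_equal(r$weight, 1 / r$se^2)
  # simultaneous sign flip of both betas leaves the ratio unchanged
  h2 <- h
  h2$beta_exposure <- -h2$beta_exposure
  h2$beta_outcome <- -h2$beta_outcome
  expect_equal(wald_ratios(h2)$ratio, r$ratio)
  # a zero exposure effect is a domain error naming the variant
  h$beta_exposure[2] <- 0
  expect_error(wald_ratios(h), h$rsid[2])
})

test_that("IVW is the precision-weighted mean with the documented SEs", {
  h <- make_harmonised(c(0.5, 1.0), c(0.1, 0.2))
  fit <- mr_ivw(h, mode = "fixed")
  expect_equal(fit$b, 0.6)
  expect_equal(fit$se, 125^-0.5)
  expect_equal(fit$Q, 5)
  expect_equal(fit$Q_df, 1)
  # multiplicative random effects widen the SE under overdispersion only
  mre <- mr_ivw(h)
  expect_equal(mre$b, fit$b)
  expect_equal(mre$se, fit$se * sqrt(5 / 1))
  under <- make_harmonised(c(0.6, 0.6001), c(0.1, 0.2))
  expect_equal(mr_ivw(under)$se, mr_ivw(under, mode = "fixed")$se)
  # a single instrument reduces to its Wald ratio
  one <- make_harmonised(0.7, 0.3)
  fit1 <- mr_ivw(one)
  expect_equal(fit1$b, 0.7)
  expect_equal(fit1$se, 0.3)
  expect_error(mr_ivw(make_harmonised(numeric(), numeric())), "at least one")
})

test_that("IVW equals the weighted through-origin regression slope", {
  set.seed(1)
  for (i in 1:20) {
    m <- sample(3:30, 1)
    h <- make_harmonised(rnorm(m), runif(m, 0.05, 0.5),
                         beta_exposure = runif(m, 0.5, 2))
    r <- wald_ratios(h)
    fit <- mr_ivw(h, mode = "fixed")
    lmfit <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
                weights = 1 / se_outcome^2)
    expect_equal(fit$b, unname(coef(lmfit)), tolerance = 1e-12)
    expect_equal(fit$b, sum(r$weight * r$ratio) / sum(r$weight),
                 tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers an exact affine relationship", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  a <- 0.02; slope <- -0.3
  h <- make_harmonised(rep(0, 5), rep(1, 5))
  h$beta_exposure <- bx
  h$se_exposure <- 1e-6
  h$beta_outcome <- a + slope * bx
  h$se_outcome <- rep(0.05, 5)
  fit <- mr_egger(h)
  expect_equal(fit$b, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, a, tolerance = 1e-10)
  expect_equal(fit$Q, 0, tolerance = 1e-16)
  # orientation invariance: flipping any instrument's pair of betas
  h2 <- h
  h2$beta_exposure[2] <- -h2$beta_exposure[2]
  h2$beta_outcome[2] <- -h2$beta_outcome[2]
  fit2 <- mr_egger(h2)
  expect_equal(fit2$b, fit$b)
  expect_equal(fit2$intercept, fit$intercept)
  expect_error(mr_egger(h[1:2, ]), "insufficient instruments for MR-Egger")
})

test_that("the weighted median interpolates cumulative weight one half", {
  h <- make_harmonised(c(1, 2, 3), c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 0)$b, 2)
  # equal weights reproduce the sample median (odd m)
  set.seed(3)
  x <- rnorm(9)
  expect_equal(mr_weighted_median(make_harmonised(x, rep(1, 9)),
                                  n_boot = 0)$b, median(x))
  # an instrument with most of the weight dominates
  h <- make_harmonised(c(0.2, 1, 1.8), c(0.01, 1, 1))
  expect_lt(abs(mr_weighted_median(h, n_boot = 0)$b - 0.2), 0.05)
  # bounded by the ratio range
  for (i in 1:10) {
    m <- sample(3:15, 1)
    x <- rnorm(m); s <- runif(m, 0.05, 1)
    b <- mr_weighted_median(make_harmonised(x, s), n_boot = 0)$b
    expect_gte(b, min(x)); expect_lte(b, max(x))
  }
  expect_error(mr_weighted_median(make_harmonised(1:2, c(1, 1))),
               "insufficient")
})

test_that("the weighted mode tracks the dominant cluster", {
  h <- make_harmonised(rep(0.42, 4), rep(0.1, 4))
  expect_equal(mr_weighted_mode(h, n_boot = 0)$b, 0.42)
  h <- make_harmonised(c(0.48, 0.5, 0.51, 0.53, 5), rep(0.2, 5))
  est <- mr_weighted_mode(h, n_boot = 0)$b
  expect_lt(abs(est - 0.5), 0.15)
  expect_error(mr_weighted_mode(make_harmonised(1:2, c(1, 1))),
               "insufficient")
})

test_that("bootstrap SEs are seed-reproducible and leave the RNG alone", {
  h <- make_harmonised(c(0.4, 0.5, 0.6, 0.9), c(0.1, 0.2, 0.15, 0.3))
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  a <- mr_weighted_median(h, n_boot = 200, seed = 7)
  expect_equal(rnorm(1), before)
  b <- mr_weighted_median(h, n_boot = 200, seed = 7)
  expect_equal(a$se, b$se)
  expect_gt(a$se, 0)
  c1 <- mr_weighted_mode(h, n_boot = 200, seed = 7)
  c2 <- mr_weighted_mode(h, n_boot = 200, seed = 7)
  expect_equal(c1$se, c2$se)
})

test_that("estimators are invariant to instrument order and orientation", {
  set.seed(8)
  m <- 12
  h <- make_harmonised(rnorm(m, 0.3, 0.2), runif(m, 0.05, 0.4),
                       beta_exposure = runif(m, 0.3, 1.5))
  flip <- sample(c(-1, 1), m, replace = TRUE)
  h2 <- h[sample(m), ]
  h2$beta_exposure <- h2$beta_exposure * flip
  h2$beta_outcome <- h2$beta_outcome * flip
  for (fun in list(function(x) mr_ivw(x)$b,
                   function(x) mr_egger(x)$b,
                   function(x) mr_weighted_median(x, n_boot = 0)$b,
                   function(x) mr_weighted_mode(x, n_boot = 0)$b)) {
    expect_equal(fun(h2), fun(h), tolerance = 1e-9)
  }
})

test_that("odds-ratio conversion uses the two-sided 95% multiplier", {
  ci <- to_odds_ratio(0, 0.1)
  expect_equal(ci$or, 1)
  expect_equal(ci$ci_low, exp(-1.959964 * 0.1))
  expect_equal(round(ci$ci_low, 3), 0.822)
  expect_equal(round(ci$ci_high, 3), 1.217)
  # degenerate SE collapses the interval onto the point estimate
  ci <- to_odds_ratio(log(2), 0)
  expect_equal(ci$ci_low, 2)
  expect_equal(ci$ci_high, 2)
  expect_error(to_odds_ratio(0, -0.1), "se")
})

test_that("mr_all assembles the four-method results table", {
  h <- make_harmonised(c(0.4, 0.5, 0.6, 0.7, 0.9),
                       c(0.1, 0.2, 0.1, 0.3, 0.2))
  res <- mr_all(h, seed = 1, n_boot = 100)
  expect_equal(res$method, c("IVW", "MR Egger", "Weighted median",
                             "Weighted mode"))
  expect_equal(res$nsnp, rep(5, 4))
  expect_true(all(res$or > 0))
  expect_true(all(res$or_lo95 < res$or & res$or < res$or_hi95))
  expect_true(is.na(res$intercept[1]) && !is.na(res$intercept[2]))
})
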