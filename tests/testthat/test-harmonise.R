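test_that("allele configurations classify by direct and complement match", {
  expect_equal(classify_alleles("T", "C", "T", "C"), "same")
  expect_equal(classify_alleles("T", "C", "C", "T"), "swapped")
  expect_equal(classify_alleles("T", "C", "A", "G"), "complement_same")
  expect_equal(classify_alleles("T", "C", "G", "A"), "complement_swapped")
  expect_equal(classify_alleles("A", "T", "A", "T"), "palindromic")
  expect_equal(classify_alleles("C", "G", "G", "C"), "palindromic")
  expect_equal(classify_alleles("A", "G", "A", "C"), "incompatible")
  expect_equal(classify_alleles("A", "T", "C", "G"), "incompatible")
  expect_error(classify_alleles("A", "G", "A", "AT"), "A/C/G/T")
})

pair <- function(exp_alleles, out_alleles, beta_exp = -0.056,
                 beta_out = 0.03, eaf_exp = NA, eaf_out = NA, ...) {
  exp <- make_assoc("rs1", beta_exp, 0.01, eaf = eaf_exp,
                    effect_allele = exp_alleles[1],
                    other_allele = exp_alleles[2])
  out <- make_assoc("rs1", beta_out, 0.02, eaf = eaf_out,
                    effect_allele = out_alleles[1],
                    other_allele = out_alleles[2])
  harmonise_pair(exp, out, ...)
}

test_that("swapped outcome alleles negate the beta and reflect the EAF", {
  rec <- pair(c("T", "C"), c("C", "T"), beta_out = 0.03, eaf_out = 0.78)
  expect_equal(rec$beta_outcome, -0.03)
  expect_equal(rec$eaf_outcome, 0.22)
  expect_equal(rec$action, "outcome_flipped")
  expect_false(rec$dropped)
  # a strand complement alone changes nothing numerically
  rec <- pair(c("T", "C"), c("A", "G"), beta_out = 0.03, eaf_out = 0.78)
  expect_equal(rec$beta_outcome, 0.03)
  expect_equal(rec$action, "strand_complemented")
})

test_that("palindromic variants resolve by frequency or drop as ambiguous", {
  rec <- pair(c("A", "T"), c("A", "T"), eaf_exp = 0.50, eaf_out = 0.49)
  expect_true(rec$dropped)
  expect_equal(rec$drop_reason, "palindromic, intermediate allele frequency")

  # concordant sides of 0.5 after allowing for the strand ambiguity: flip
  rec <- pair(c("A", "T"), c("T", "A"), beta_out = 0.03,
              eaf_exp = 0.10, eaf_out = 0.91)
  expect_false(rec$dropped)
  expect_equal(rec$beta_outcome, -0.03)
  expect_equal(rec$eaf_outcome, 0.09)
  expect_equal(rec$action, "palindromic_inferred")

  # same side of 0.5: orientation already agrees
  rec <- pair(c("A", "T"), c("A", "T"), beta_out = 0.03,
              eaf_exp = 0.10, eaf_out = 0.12)
  expect_equal(rec$beta_outcome, 0.03)

  # strict mode drops palindromes with a missing frequency ...
  rec <- pair(c("C", "G"), c("C", "G"), eaf_exp = 0.10, eaf_out = NA)
  expect_true(rec$dropped)
  # ... permissive mode assumes a shared strand
  rec <- pair(c("C", "G"), c("G", "C"), beta_out = 0.03,
              eaf_exp = 0.10, eaf_out = NA, strict = FALSE)
  expect_equal(rec$beta_outcome, -0.03)

  # the band is configurable
  rec <- pair(c("A", "T"), c("A", "T"), eaf_exp = 0.40, eaf_out = 0.41,
              ambiguity_band = 0.12)
  expect_true(rec$dropped)
})

test_that("incompatible alleles and rsid mismatches are handled", {
  rec <- pair(c("A", "G"), c("A", "C"))
  expect_true(rec$dropped)
  expect_equal(rec$drop_reason, "incompatible alleles")
  exp <- make_assoc("rs1", 0.1, 0.01)
  out <- make_assoc("rs2", 0.1, 0.01)
  expect_error(harmonise_pair(exp, out), "different variants")
})

test_that("harmonising an already-harmonised pair is the identity", {
  for (alleles in list(c("T", "C"), c("A", "T"))) {
    rec <- pair(alleles, rev(alleles), beta_out = 0.03,
                eaf_exp = 0.10, eaf_out = 0.91)
    out2 <- make_assoc("rs1", rec$beta_outcome, rec$se_outcome,
                       eaf = rec$eaf_outcome,
                       effect_allele = rec$effect_allele,
                       other_allele = rec$other_allele)
    exp <- make_assoc("rs1", rec$beta_exposure, rec$se_exposure,
                      eaf = 0.10, effect_allele = rec$effect_allele,
                      other_allele = rec$other_allele)
    rec2 <- harmonise_pair(exp, out2)
    expect_equal(rec2$beta_outcome, rec$beta_outcome)
    expect_equal(rec2$eaf_outcome, rec$eaf_outcome)
  }
})

test_that("swapping outcome alleles and negating its beta is a no-op", {
  out_a <- make_assoc("rs1", 0.03, 0.02, eaf = 0.78,
                      effect_allele = "C", other_allele = "T")
  out_b <- make_assoc("rs1", -0.03, 0.02, eaf = 0.22,
                      effect_allele = "T", other_allele = "C")
  exp <- make_assoc("rs1", -0.056, 0.01, eaf = 0.3,
                    effect_allele = "T", other_allele = "C")
  a <- harmonise_pair(exp, out_a)
  b <- harmonise_pair(exp, out_b)
  expect_equal(a$beta_outcome, b$beta_outcome)
  expect_equal(a$eaf_outcome, b$eaf_outcome)
})

test_that("set harmonisation matches by rsid, proxies, and audits attrition", {
  exposure <- rbind(make_assoc("rs1", 0.1, 0.01, eaf = 0.3),
                    make_assoc("rs2", -0.2, 0.01, eaf = 0.2,
                               effect_allele = "T", other_allele = "C"),
                    make_assoc("rs3", 0.15, 0.01, eaf = 0.25))
  outcome <- rbind(make_assoc("rs1", 0.05, 0.02, eaf = 0.3),
                   make_assoc("rsP", 0.02, 0.02, eaf = 0.2,
                              effect_allele = "T", other_allele = "C"))
  proxies <- data.frame(rsid = "rs2", proxy_rsid = "rsP", r2 = 0.9)
  h <- harmonise(exposure, outcome, proxies = proxies)
  expect_equal(nrow(h), 3)
  expect_equal(h$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(h$proxy_rsid, c(NA, "rsP", NA))
  expect_equal(h$drop_reason[3], "not found in outcome")
  att <- attr(h, "attrition")
  expect_equal(att$matched, 1)
  expect_equal(att$proxied, 1)
  expect_equal(att$kept, 2)
  # attrition counts sum to the instrument count
  expect_equal(att$kept + sum(h$dropped), att$input)
})

test_that("harmonising a study against itself keeps everything as-is", {
  sim <- simulate_two_sample(sim_config(m = 20, seed = 5,
                                        palindromic_fraction = 0))
  h <- harmonise(sim$exposure, sim$exposure)
  expect_true(all(!h$dropped))
  expect_true(all(h$action == "kept_as_is"))
  expect_equal(wald_ratios(h)$ratio, rep(1, 20))
})

test_that("harmonisation undoes the generator's representation scrambling", {
  sim <- simulate_two_sample(sim_config(m = 200, seed = 11, theta = -0.2,
                                        palindromic_fraction = 0.3))
  h <- harmonise(sim$exposure, sim$outcome)
  kept <- harmonised_kept(h)
  # the outcome file was scrambled with swaps and strand complements; after
  # harmonisation every retained beta must equal the generated truth-frame
  # value exactly
  truth_by <- sim$truth$snps
  swap <- truth_by$outcome_swapped[match(kept$rsid, truth_by$rsid)]
  raw <- sim$outcome$beta[match(kept$rsid, sim$outcome$rsid)]
  expect_equal(kept$beta_outcome, ifelse(swap, -raw, raw))
  # only palindromic variants can drop here, and every intermediate-EAF
  # palindrome must drop
  dropped <- h[h$dropped, ]
  pal <- truth_by$palindromic[match(h$rsid, truth_by$rsid)]
  expect_true(all(pal[h$dropped]))
  intermediate <- pal & abs(sim$exposure$eaf - 0.5) <= 0.08
  expect_true(all(h$dropped[intermediate]))
})
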