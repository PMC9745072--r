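# Builders for small summary-statistics and harmonised fixtures.

make_assoc <- function(rsid, beta, se, pval = NULL, eaf = NA_real_,
                       effect_allele = "A", other_allele = "G",
                       chrom = "1", pos = NA_real_, n = NA_real_,
                       trait = NA_character_) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             trait = trait, stringsAsFactors = FALSE)
}

# A harmonised set whose Wald ratios and ratio SEs are exactly `ratio` and
# `se` (unit exposure effect with negligible uncertainty).
make_harmonised <- function(ratio, se, rsid = sprintf("rs%03d", seq_along(ratio)),
                            beta_exposure = seq(0.6, 1.4,
                                                length.out = length(ratio))) {
  n <- length(ratio)
  data.frame(rsid = rsid, effect_allele = rep("A", n),
             other_allele = rep("G", n),
             beta_exposure = beta_exposure, se_exposure = rep(1e-6, n),
             eaf_exposure = rep(0.3, n),
             beta_outcome = ratio * beta_exposure,
             se_outcome = se * abs(beta_exposure),
             eaf_outcome = rep(0.3, n), action = rep("kept_as_is", n),
             proxy_rsid = rep(NA_character_, n), dropped = rep(FALSE, n),
             drop_reason = rep("", n), stringsAsFactors = FALSE)
}

write_sumstats_tsv <- function(dat, path = tempfile(fileext = ".tsv")) {
  utils::write.table(dat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

default_map <- function() {
  column_map(rsid = "rsid", chrom = "chrom", pos = "pos",
             effect_allele = "effect_allele", other_allele = "other_allele",
             eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
}

# Simulate, harmonise, and return the usable instrument rows.
sim_harmonised <- function(cfg) {
  sim <- simulate_two_sample(cfg)
  harmonised_kept(harmonise(sim$exposure, sim$outcome))
}
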