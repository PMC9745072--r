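# Synthetic paired exposure/outcome GWAS summary statistics with known
# causal truth.
#
# The generator works at the summary-statistic level: per-variant true
# effects gamma_j on the exposure are drawn, the outcome effect is
# theta * gamma_j plus an optional direct (pleiotropic) effect alpha_j,
# and observed betas are the true effects plus Normal sampling noise with
# the standardised-genotype standard error (2 p q n)^(-1/2).  Allele pairs
# (including palindromic A/T and C/G variants) are assigned and the
# outcome file's representation is randomly scrambled (allele swaps and
# strand complements), so harmonization is genuinely exercised.

NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                     c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
PAL_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Configuration for the two-sample GWAS simulator
#'
#' @param m Number of instruments (ignored when `ld_blocks` is given, which
#'   fixes `m = n_blocks * block_size`).
#' @param theta True causal effect (log odds ratio of outcome per log odds
#'   of exposure).
#' @param gamma_range Magnitude range of the true variant-exposure effects
#'   (drawn uniformly; default 0.03-0.2, the scale of common-variant
#'   log-OR effects for a complex binary trait).
#' @param gamma_sign `"random"` (default) or `"positive"`.  Directional
#'   pleiotropy scenarios use `"positive"` so that "directional" has a
#'   well-defined orientation relative to the exposure-increasing allele.
#' @param pleiotropy List describing the direct variant-outcome effects:
#'   `list(type = "none")` (default),
#'   `list(type = "balanced", sd = )` (zero-mean direct effects on every
#'   variant), or
#'   `list(type = "directional", mean = , sd = , frac = )` (a fraction
#'   `frac` of variants receives `Normal(mean, sd)` direct effects;
#'   independent of instrument strength, so InSIDE holds).
#' @param n_exp,n_out Effective sample sizes driving the exposure/outcome
#'   standard errors `se = (2 eaf (1-eaf) n)^(-1/2)`.  For binary-trait
#'   GWAS the case-fraction factor is absorbed into these, so the defaults
#'   (10,000 and 50,000) put instrument F statistics in the realistic
#'   10-100 range.
#' @param eaf_range Effect-allele frequency range (uniform draw).
#' @param palindromic_fraction Proportion of variants assigned A/T or C/G
#'   allele pairs (default 0.2).
#' @param eaf_noise_sd SD of the between-study allele-frequency
#'   perturbation (default 0.005).
#' @param ld_blocks Optional `list(n_blocks = , block_size = , r2 = )`:
#'   variants within a block share the same true exposure effect and
#'   chromosome/position neighbourhood, and a pairwise [ld_matrix()] with
#'   the given within-block r-squared is emitted for clumping tests.
#' @param seed Integer seed; a single seed reproduces the dataset exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m = 50, theta = 0, gamma_range = c(0.03, 0.2),
                       gamma_sign = c("random", "positive"),
                       pleiotropy = list(type = "none"),
                       n_exp = 10000, n_out = 50000,
                       eaf_range = c(0.05, 0.95),
                       palindromic_fraction = 0.2, eaf_noise_sd = 0.005,
                       ld_blocks = NULL, seed = 1) {
  gamma_sign <- match.arg(gamma_sign)
  stopifnot(m >= 1, length(gamma_range) == 2, all(gamma_range > 0),
            n_exp > 0, n_out > 0, length(eaf_range) == 2,
            eaf_noise_sd >= 0)
  assert_prob(palindromic_fraction, "palindromic_fraction")
  if (!is.list(pleiotropy) ||
      !pleiotropy$type %in% c("none", "balanced", "directional")) {
    stop("pleiotropy$type must be one of none, balanced, directional",
         call. = FALSE)
  }
  if (pleiotropy$type == "balanced" && is.null(pleiotropy$sd)) {
    stop("balanced pleiotropy needs `sd`", call. = FALSE)
  }
  if (pleiotropy$type == "directional" &&
      (is.null(pleiotropy$mean) || is.null(pleiotropy$sd))) {
    stop("directional pleiotropy needs `mean` and `sd`", call. = FALSE)
  }
  if (!is.null(ld_blocks)) {
    stopifnot(all(c("n_blocks", "block_size", "r2") %in% names(ld_blocks)))
    m <- ld_blocks$n_blocks * ld_blocks$block_size
  }
  structure(list(m = m, theta = theta, gamma_range = gamma_range,
                 gamma_sign = gamma_sign, pleiotropy = pleiotropy,
                 n_exp = n_exp, n_out = n_out, eaf_range = eaf_range,
                 palindromic_fraction = palindromic_fraction,
                 eaf_noise_sd = eaf_noise_sd, ld_blocks = ld_blocks,
                 seed = seed),
            class = "sim_config")
}

#' Named simulator scenarios
#'
#' Documented configurations covering the satisfaction/violation grid of
#' the instrumental-variable assumptions:
#'
#' * `"null"`: no causal effect, no pleiotropy (type-I-error studies);
#' * `"causal"`: protective causal effect `theta = log(0.752)` (the scale
#'   of the heart-failure/Alzheimer's IVW estimate), no pleiotropy;
#' * `"directional_pleiotropy"`: same causal effect, 30% of instruments
#'   (100 by default, so the intercept test is well powered) with
#'   `Normal(0.05, 0.02)` direct outcome effects oriented to the
#'   exposure-increasing allele (InSIDE holds);
#' * `"balanced_pleiotropy"`: same causal effect, zero-mean direct effects
#'   (sd 0.05) on every instrument;
#' * `"weak_instruments"`: true effects 0.005-0.03, putting most F
#'   statistics at or below the F > 10 screen;
#' * `"ld_structured"`: 10 blocks of 5 variants at within-block r-squared
#'   0.8, with the pairwise LD matrix emitted for clumping tests.
#'
#' @param name Scenario name.
#' @param ... Overrides forwarded to [sim_config()] (e.g. `m`, `seed`).
#' @return A `sim_config`.
#' @export
scenario_preset <- function(name, ...) {
  presets <- list(
    null = list(theta = 0, pleiotropy = list(type = "none"),
                palindromic_fraction = 0),
    causal = list(theta = log(0.752), pleiotropy = list(type = "none"),
                  palindromic_fraction = 0),
    directional_pleiotropy = list(
      m = 100, theta = log(0.752), gamma_sign = "positive",
      pleiotropy = list(type = "directional", mean = 0.05, sd = 0.02,
                        frac = 0.3),
      # Egger regression additionally assumes negligible uncertainty in the
      # variant-exposure effects (NOME); this diagnostic scenario therefore
      # uses very strong instruments
      n_exp = 1e6,
      palindromic_fraction = 0),
    balanced_pleiotropy = list(
      theta = log(0.752),
      pleiotropy = list(type = "balanced", sd = 0.05),
      palindromic_fraction = 0),
    weak_instruments = list(theta = 0, gamma_range = c(0.005, 0.03),
                            pleiotropy = list(type = "none"),
                            palindromic_fraction = 0),
    ld_structured = list(theta = 0, pleiotropy = list(type = "none"),
                         palindromic_fraction = 0,
                         ld_blocks = list(n_blocks = 10, block_size = 5,
                                          r2 = 0.8))
  )
  if (!name %in% names(presets)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  args <- utils::modifyList(presets[[name]], list(...))
  cfg <- do.call(sim_config, args)
  cfg$scenario <- name
  cfg
}

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' @param cfg A [sim_config()] or [scenario_preset()].
#' @return List with elements `exposure` and `outcome` (summary-statistics
#'   data.frames as produced by [read_sumstats()]), `truth` (the true
#'   `theta`, per-variant `gamma`/`alpha`, scenario label and seed), and
#'   `ld` (an [ld_matrix()] when `ld_blocks` was configured, else `NULL`).
#'   Fully reproducible from `cfg$seed`.
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$m
    rsid <- sprintf("rs%07d", seq_len(m))
    if (is.null(cfg$ld_blocks)) {
      block <- rep(NA_integer_, m)
      chrom <- as.character(rep_len(1:22, m))
      pos <- 1e6 + (seq_len(m) - 1) %/% 22 * 2e6
      gamma_mag <- stats::runif(m, cfg$gamma_range[1], cfg$gamma_range[2])
    } else {
      bs <- cfg$ld_blocks$block_size
      block <- rep(seq_len(cfg$ld_blocks$n_blocks), each = bs)
      chrom <- as.character(block)
      pos <- 1e6 + (seq_len(m) - (block - 1) * bs - 1) * 1000
      block_gamma <- stats::runif(cfg$ld_blocks$n_blocks,
                                  cfg$gamma_range[1], cfg$gamma_range[2])
      gamma_mag <- block_gamma[block]
    }
    sgn <- if (cfg$gamma_sign == "positive") rep(1, m)
           else sample(c(-1, 1), m, replace = TRUE)
    gamma <- gamma_mag * sgn
    eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])

    alpha <- rep(0, m)
    pl <- cfg$pleiotropy
    if (pl$type == "balanced") {
      alpha <- stats::rnorm(m, 0, pl$sd)
    } else if (pl$type == "directional") {
      frac <- pl$frac %||% 1
      idx <- sample(m, round(frac * m))
      alpha[idx] <- stats::rnorm(length(idx), pl$mean, pl$sd)
    }

    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_exp)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_out)
    beta_x <- stats::rnorm(m, gamma, se_x)
    beta_y <- stats::rnorm(m, cfg$theta * gamma + alpha, se_y)

    n_pal <- round(cfg$palindromic_fraction * m)
    is_pal <- seq_len(m) %in% sample(m, n_pal)
    pick <- function(pairs, k) pairs[sample(length(pairs), k, replace = TRUE)]
    alleles <- vector("list", m)
    alleles[is_pal] <- pick(PAL_PAIRS, sum(is_pal))
    alleles[!is_pal] <- pick(NONPAL_PAIRS, sum(!is_pal))
    a1 <- vapply(alleles, `[`, "", 1)
    a2 <- vapply(alleles, `[`, "", 2)

    eaf_out <- pmin(pmax(eaf + stats::rnorm(m, 0, cfg$eaf_noise_sd),
                         0.001), 0.999)
    # scramble the outcome file's representation: random allele swaps
    # (effect reported for the other allele) and strand complements
    swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
    comp <- sample(c(TRUE, FALSE), m, replace = TRUE)
    o1 <- ifelse(swap, a2, a1)
    o2 <- ifelse(swap, a1, a2)
    beta_y_rep <- ifelse(swap, -beta_y, beta_y)
    eaf_out_rep <- ifelse(swap, 1 - eaf_out, eaf_out)
    o1c <- ifelse(comp, COMPLEMENT[o1], o1)
    o2c <- ifelse(comp, COMPLEMENT[o2], o2)

    mk <- function(a1, a2, eaf, beta, se, n, trait) {
      data.frame(rsid = rsid, chrom = chrom, pos = pos,
                 effect_allele = a1, other_allele = a2, eaf = eaf,
                 beta = beta, se = se,
                 pval = two_sided_normal_p(beta / se), n = n,
                 trait = trait, stringsAsFactors = FALSE)
    }
    exposure <- mk(a1, a2, eaf, beta_x, se_x, cfg$n_exp,
                   "simulated exposure")
    outcome <- mk(o1c, o2c, eaf_out_rep, beta_y_rep, se_y, cfg$n_out,
                  "simulated outcome")

    ld <- NULL
    if (!is.null(cfg$ld_blocks)) {
      pairs <- do.call(rbind, lapply(split(seq_len(m), block), function(ix) {
        if (length(ix) < 2) return(NULL)
        cmb <- utils::combn(ix, 2)
        data.frame(rsid_a = rsid[cmb[1, ]], rsid_b = rsid[cmb[2, ]],
                   r2 = cfg$ld_blocks$r2, stringsAsFactors = FALSE)
      }))
      ld <- ld_matrix(pairs, rsids = rsid)
    }

    truth <- list(theta = cfg$theta,
                  scenario = cfg$scenario %||% "custom",
                  seed = cfg$seed,
                  snps = data.frame(rsid = rsid, gamma = gamma,
                                    alpha = alpha, eaf = eaf,
                                    palindromic = is_pal, block = block,
                                    outcome_swapped = swap,
                                    outcome_complemented = comp,
                                    stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome, truth = truth, ld = ld)
  })
}
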