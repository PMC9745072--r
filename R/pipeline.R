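# One-call end-to-end run: select -> harmonise -> estimate -> diagnose ->
# power, with result tables and a machine-readable run report.

#' Configuration for [run_pipeline()]
#'
#' @param exposure,outcome Summary-statistics inputs: either file paths
#'   (read with the corresponding column map) or data.frames already in
#'   canonical form.
#' @param exposure_map,outcome_map [column_map()]s used when the inputs are
#'   paths (default [gwas_catalog_map()]).
#' @param ld Optional LD input for clumping: an [ld_matrix()] or a path for
#'   [read_ld_pairs()].  Without it the clumping stage is skipped (the
#'   instruments are then assumed pre-pruned).
#' @param exclusions Optional exclusion list: data.frame/character vector
#'   or a path for [read_exclusion_list()].
#' @param proxies Optional proxy table (`rsid`, `proxy_rsid`, `r2`).
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param clump_kb,clump_r2 Clumping window (kb) and r-squared threshold
#'   (defaults 10,000 kb and 0.001).
#' @param proxy_r2 Minimum proxy r-squared (default 0.8).
#' @param ambiguity_band Palindromic ambiguity band (default 0.08).
#' @param q_p_min Cochran-Q p-value required by the subset stage
#'   (default 0.05).
#' @param subset_strategy `"greedy_q"`, `"exhaustive_small"`, or `NULL` to
#'   skip homogeneous-subset selection.
#' @param methods Estimators to run (see [mr_all()]).
#' @param n_boot,seed Bootstrap settings for the stochastic estimators.
#' @param power Optional `list(n_outcome = , case_fraction = , alpha = )`
#'   enabling the power stage (the causal effect used is the IVW
#'   estimate).
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as TSV plus `run_report.json`.
#' @return A `run_config` list.
#' @export
run_config <- function(exposure, outcome,
                       exposure_map = gwas_catalog_map(),
                       outcome_map = gwas_catalog_map(),
                       ld = NULL, exclusions = NULL, proxies = NULL,
                       p_threshold = 5e-8, clump_kb = 10000,
                       clump_r2 = 0.001, proxy_r2 = 0.8,
                       ambiguity_band = 0.08, q_p_min = 0.05,
                       subset_strategy = "greedy_q",
                       methods = c("ivw", "egger", "weighted_median",
                                   "weighted_mode"),
                       n_boot = 1000, seed = 1, power = NULL,
                       out_dir = NULL) {
  assert_prob(p_threshold, "p_threshold", open_left = TRUE)
  assert_prob(clump_r2, "clump_r2")
  assert_prob(proxy_r2, "proxy_r2")
  assert_prob(ambiguity_band, "ambiguity_band")
  assert_prob(q_p_min, "q_p_min")
  stopifnot(clump_kb > 0)
  structure(as.list(environment()), class = "run_config")
}

#' @noRd
resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the full two-sample MR pipeline
#'
#' Stages, in order: read inputs; significance filter; LD clumping (if LD
#' supplied); exclusion screening; harmonization (with proxy lookup);
#' instrument F statistics; the four causal estimators; heterogeneity
#' (IVW and Egger Cochran Q) and the Egger intercept test; leave-one-out,
#' single-SNP and funnel tables; homogeneous-subset selection with the MR
#' battery re-run on the subset; and an optional binary-outcome power
#' analysis.  Counts at every attrition point (candidates, clumped,
#' excluded, harmonised, analysed) are recorded so the narrowing of the
#' instrument set is auditable from the report alone.
#'
#' A stage failure stops the pipeline but the report still describes every
#' completed stage, with `status` recording where and why it stopped.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `instruments`, `harmonised`,
#'   `mr_results`, `heterogeneity`, `egger_intercept`, `loo`,
#'   `single_snp`, `funnel`, `subset`, `subset_mr`, `power`, and `report`
#'   (the JSON-ready run summary).  When `cfg$out_dir` is set the tables
#'   are also written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  res <- list()
  report <- list(
    thresholds = cfg[c("p_threshold", "clump_kb", "clump_r2", "proxy_r2",
                       "ambiguity_band", "q_p_min")],
    methods = cfg$methods, seed = cfg$seed, n_boot = cfg$n_boot,
    stages = list(), status = "success")
  stage <- function(name, code) {
    if (report$status != "success") return(NULL)
    tryCatch(code, error = function(e) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      report$status <<- paste0("failed at stage '", name, "': ",
                               conditionMessage(e))
      NULL
    })
  }

  stage("read", {
    res$exposure <- resolve_input(cfg$exposure, read_sumstats,
                                   map = cfg$exposure_map)
    res$outcome <- resolve_input(cfg$outcome, read_sumstats,
                                  map = cfg$outcome_map)
    report$stages$read <- list(
      status = "ok", exposure_rows = nrow(res$exposure),
      outcome_rows = nrow(res$outcome),
      exposure_dropped = attr(res$exposure, "n_dropped") %||% 0,
      outcome_dropped = attr(res$outcome, "n_dropped") %||% 0)
  })

  stage("select", {
    inst <- filter_genomewide(res$exposure, cfg$p_threshold)
    n_sig <- nrow(inst)
    removed_ld <- 0
    if (!is.null(cfg$ld)) {
      ld <- resolve_input(cfg$ld, read_ld_pairs)
      inst <- clump(inst, ld, window_kb = cfg$clump_kb,
                    r2_max = cfg$clump_r2)
      removed_ld <- nrow(attr(inst, "removed"))
    }
    excl_audit <- NULL
    if (!is.null(cfg$exclusions)) {
      excl <- resolve_input(cfg$exclusions, read_exclusion_list)
      inst <- apply_exclusions(inst, excl)
      excl_audit <- attr(inst, "audit")
    }
    inst$f_stat <- f_statistic(inst$beta, inst$se)
    inst$weak <- is_weak_instrument(inst$f_stat)
    res$instruments <- inst
    report$stages$select <- list(
      status = "ok", genomewide_significant = n_sig,
      removed_by_clumping = removed_ld,
      removed_by_exclusion_list = if (is.null(excl_audit)) 0
                                  else nrow(excl_audit),
      candidates = nrow(inst),
      weak_instruments = sum(inst$weak))
  })

  stage("harmonise", {
    h <- harmonise(res$instruments, res$outcome, proxies = cfg$proxies,
                   proxy_r2_min = cfg$proxy_r2,
                   ambiguity_band = cfg$ambiguity_band)
    res$harmonised <- h
    att <- attr(h, "attrition")
    report$stages$harmonise <- list(
      status = "ok", input = att$input, matched = att$matched,
      proxied = att$proxied, kept = att$kept,
      dropped_by_reason = as.list(att$dropped_by_reason))
    if (att$kept == 0) stop("no instruments retained after harmonization")
  })

  stage("mr", {
    res$mr_results <- mr_all(res$harmonised, methods = cfg$methods,
                              n_boot = cfg$n_boot, seed = cfg$seed)
    report$stages$mr <- list(status = "ok",
                              nsnp = max(res$mr_results$nsnp))
  })

  stage("diagnose", {
    m <- sum(!res$harmonised$dropped)
    het <- cochran_q(res$harmonised)
    if (m >= 3) het <- rbind(het, cochran_q(res$harmonised, "egger"))
    res$heterogeneity <- het
    if (m >= 3) res$egger_intercept <- egger_intercept_test(res$harmonised)
    res$loo <- leave_one_out(res$harmonised)
    res$single_snp <- single_snp_analysis(res$harmonised)
    res$funnel <- funnel_data(res$harmonised)
    report$stages$diagnose <- list(
      status = "ok", ivw_q_pval = het$pval[1],
      influential_loo = sum(res$loo$influential))
  })

  stage("subset", {
    if (is.null(cfg$subset_strategy)) {
      report$stages$subset <- list(status = "skipped")
    } else if (sum(!res$harmonised$dropped) < 3) {
      report$stages$subset <- list(status = "skipped",
                                    reason = "fewer than 3 instruments")
    } else {
      sel <- select_homogeneous_subset(res$harmonised,
                                       q_p_min = cfg$q_p_min,
                                       strategy = cfg$subset_strategy)
      res$subset <- sel
      if (nrow(sel$subset) >= 3) {
        res$subset_mr <- mr_all(sel$subset, methods = cfg$methods,
                                 n_boot = cfg$n_boot, seed = cfg$seed)
      }
      report$stages$subset <- list(
        status = "ok", strategy = sel$strategy, success = sel$success,
        kept = nrow(sel$subset), removed = sel$removed$rsid,
        q_pval = sel$q_pval)
    }
  })

  stage("power", {
    if (is.null(cfg$power)) {
      report$stages$power <- list(status = "skipped")
    } else {
      b <- res$mr_results$b[res$mr_results$method == "IVW"][1]
      res$power <- mr_power_analysis(
        res$instruments, n_outcome = cfg$power$n_outcome,
        case_fraction = cfg$power$case_fraction, b = b,
        alpha = cfg$power$alpha %||% 0.05)
      report$stages$power <- list(
        status = "ok", b = b,
        power = stats::setNames(as.list(res$power$power),
                                res$power$r2_method))
    }
  })

  res$report <- report
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  invisible(res)
}

#' @noRd
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(instruments = res$instruments, harmonized = res$harmonised,
               mr_results = res$mr_results,
               heterogeneity = res$heterogeneity, loo = res$loo,
               single_snp = res$single_snp, funnel = res$funnel,
               subset_mr = res$subset_mr, power = res$power)
  for (name in names(tabs)) {
    if (!is.null(tabs[[name]])) {
      write_results(tabs[[name]], file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  if (!is.null(res$subset)) {
    jsonlite::write_json(
      list(strategy = res$subset$strategy, success = res$subset$success,
           q_pval = res$subset$q_pval, kept = res$subset$subset$rsid,
           removed = res$subset$removed$rsid),
      file.path(out_dir, "subset.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
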