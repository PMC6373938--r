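#' Default run configuration
#'
#' Collects every tunable threshold of the full study replication with its
#' default: the scalability keep-threshold (.30), the Q3 offset (.2 above
#' the mean observed residual correlation), the DIF significance level and
#' magnitude cut (.05 Bonferroni, delta-R2 .035), the misfit level (.05
#' Bonferroni), quadrature settings, CAT lengths and the master seed.
#'
#' @param ... named overrides of any default.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    H_min = 0.30, q3_offset = 0.2, dif_alpha = 0.05, r2_cut = 0.035,
    misfit_alpha = 0.05, minsize = NULL,
    pa_method = "polychoric", n_reference = 20,
    n_nodes = 61, bounds = c(-6, 6),
    rescore_map = c(0L, 1L, 1L, 2L, 2L),
    cat_lengths = c(15, 10, 5), cat_n_simulees = 1000,
    theta_mean = -0.08, theta_var = 1.90,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full study replication
#'
#' Orchestrates the whole development pipeline on a baseline (and optional
#' retest) matrix: purification, final calibration and reliability, scoring
#' of both occasions with the final bank for test-retest agreement, and a
#' fixed-length adaptive-testing simulation over the final bank.
#'
#' @param baseline a raw [response_matrix()] (or a [simulation_design()],
#'   in which case baseline and retest data are simulated from it).
#' @param retest optional retest [response_matrix()] on the same raw
#'   categories.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the ledger (JSON lines),
#'   final bank (JSON), and a JSON results summary are written there.
#' @return A list of class `study_result`: `purification`, `fit`,
#'   `agreement` (or `NULL`), `cat`, `config`.
#' @export
run_full_study <- function(baseline, retest = NULL, config = run_config(),
                           out_dir = NULL) {
  if (inherits(baseline, "simulation_design")) {
    design <- baseline
    baseline <- simulate_responses(design)
    if (!is.null(design$retest)) retest <- simulate_retest(design, baseline)
  }
  stopifnot(inherits(baseline, "response_matrix"))
  pur <- run_purification_pipeline(
    baseline, rescore_map = config$rescore_map, H_min = config$H_min,
    q3_offset = config$q3_offset, dif_alpha = config$dif_alpha,
    misfit_alpha = config$misfit_alpha, minsize = config$minsize,
    pa_method = config$pa_method, n_reference = config$n_reference,
    seed = config$seed)
  fit <- pur$reports$final_fit
  agreement <- NULL
  if (!is.null(retest)) {
    final_ids <- pur$bank$item_ids
    rescored <- any(vapply(pur$ledger$entries,
                           function(e) e$action == "rescore", TRUE))
    t2m <- subset_items(
      if (rescored) rescore_items(retest, config$rescore_map) else retest,
      final_ids)
    t1 <- eap_score(pur$model, subset_items(pur$matrix, final_ids))
    t2 <- eap_score(pur$model, t2m)
    agreement <- test_retest(t1, t2)
  }
  lengths <- unique(c(n_items(pur$bank),
                      config$cat_lengths[config$cat_lengths <= n_items(pur$bank)]))
  cat_res <- simulate_cat_study(pur$bank, lengths = lengths,
                                n_simulees = config$cat_n_simulees,
                                theta_mean = config$theta_mean,
                                theta_var = config$theta_var,
                                n_nodes = config$n_nodes,
                                bounds = config$bounds,
                                seed = config$seed)
  res <- structure(list(purification = pur, fit = fit, agreement = agreement,
                        cat = cat_res, config = config),
                   class = "study_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ledger(pur$ledger, file.path(out_dir, "ledger.jsonl"))
    write_item_bank(pur$bank, file.path(out_dir, "final_bank.json"))
    summ <- list(
      seed = config$seed,
      n_final_items = n_items(pur$bank),
      model_fit = list(chi2 = fit$model_chi2, df = fit$model_df,
                       rmsea = fit$rmsea,
                       marginal_reliability = fit$marginal_reliability),
      agreement = if (!is.null(agreement))
        agreement[c("n_pairs", "pearson_r", "mean_diff", "loa_low",
                    "loa_high", "pct_within_loa")],
      cat_summary = cat_res$summary)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.study_result <- function(x, ...) {
  print(x$purification)
  print(x$fit)
  if (!is.null(x$agreement)) print(x$agreement)
  print(x$cat)
  invisible(x)
}
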