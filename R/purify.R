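#' Detect category threshold disordering
#'
#' An item's categories are properly ordered when every category is the
#' modal response somewhere on the theta continuum.  For the
#' adjacent-category partial credit model this is equivalent to strictly
#' ascending thresholds; both the analytic check and a fine-grid modal scan
#' are run and must agree.
#'
#' @param model a [pcm_model()] (or [item_bank()]).
#' @param grid_step spacing of the theta scan.
#' @return Data frame with `item_id`, `disordered`, and the offending
#'   categories (`never_modal`, comma-separated, empty when ordered).
#' @export
detect_threshold_disorder <- function(model, grid_step = 0.01) {
  bank <- as_bank(model)
  th <- seq(-8, 8, by = grid_step)
  out <- lapply(seq_len(n_items(bank)), function(i) {
    d <- bank$deltas[[i]]
    analytic <- any(diff(d) <= 0)
    if (length(d) == 1) analytic <- FALSE
    P <- pcm_probabilities(d, th)
    modal <- max.col(P, ties.method = "first") - 1L
    never <- setdiff(0:length(d), unique(modal))
    empirical <- length(never) > 0
    # the scan can only miss a modal region narrower than the grid step, so
    # the two checks must agree whenever thresholds are clearly separated
    if (analytic != empirical && min(abs(diff(d))) > 2 * grid_step)
      stop("threshold-disorder checks disagree for item ", bank$item_ids[i],
           " (grid too coarse?)")
    if (analytic && !empirical) never <- which(diff(d) <= 0)
    if (!analytic) { empirical <- FALSE; never <- integer(0) }
    data.frame(item_id = bank$item_ids[i], disordered = analytic,
               never_modal = paste(never, collapse = ","))
  })
  do.call(rbind, out)
}

#' Rescore (collapse) item categories
#'
#' Applies a non-decreasing raw-to-scored category map.  Maps may only
#' merge adjacent categories (the constructor enforces unit steps), the
#' semantic guard against collapsing non-neighbouring response options.
#' Missing responses stay missing.
#'
#' @param matrix a [response_matrix()].
#' @param scoring_map integer vector mapping raw category `k` (position
#'   `k + 1`) to its scored category; applied to every item.  Or a named
#'   list of such maps, one per item id.
#' @return The rescored [response_matrix()].
#' @examples
#' m <- response_matrix(matrix(0:4, 5, 1), max_cat = 4)
#' rescore_items(m, c(0L, 1L, 1L, 2L, 2L))$responses
#' @export
rescore_items <- function(matrix, scoring_map) {
  stopifnot(inherits(matrix, "response_matrix"))
  x <- matrix$responses
  maps <- if (is.list(scoring_map)) scoring_map
          else stats::setNames(rep(list(as.integer(scoring_map)),
                                   ncol(x)), matrix$item_ids)
  new_max <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    mp <- as.integer(maps[[matrix$item_ids[j]]])
    if (is.null(mp)) stop("no scoring map for item ", matrix$item_ids[j])
    if (mp[1] != 0L || any(diff(mp) < 0L) || any(diff(mp) > 1L))
      stop("scoring map must start at 0 and be non-decreasing in unit steps")
    v <- x[, j]
    bad <- which(!is.na(v) & (v < 0L | v > length(mp) - 1L))
    if (length(bad))
      stop(sprintf("raw category %d outside scoring map domain [0, %d] (item '%s')",
                   v[bad[1]], length(mp) - 1L, matrix$item_ids[j]))
    x[, j] <- mp[v + 1L]
    new_max[j] <- max(mp)
  }
  out <- response_matrix(x, matrix$person_ids, matrix$item_ids, matrix$group,
                         max_cat = new_max)
  attr(out, "theta") <- attr(matrix, "theta")
  out
}

#' Yen's Q3 local dependency statistics
#'
#' Residuals `x_pi - E[X_i | theta_p]` are computed at each person's EAP
#' estimate (after modal imputation of missing cells by default, so every
#' residual column is complete) and correlated across item pairs.  The
#' flagging threshold follows the published rule: 0.2 plus the mean
#' off-diagonal Q3 value.
#'
#' @param model a [pcm_model()] calibrated on `matrix`.
#' @param matrix a [response_matrix()] on the model's scored categories.
#' @param impute whether to impute missing cells first (`"modal"`) or use
#'   pairwise-complete residuals (`"pairwise"`).
#' @param offset added to the mean observed residual correlation to form
#'   the threshold.
#' @return A list of class `ld_report`: `q3` (symmetric matrix, `NA`
#'   diagonal), `threshold`, `dependent_pairs` (two-column character
#'   matrix), `uncomputable_pairs`.
#' @export
q3_local_dependency <- function(model, matrix, impute = c("modal", "pairwise"),
                                offset = 0.2) {
  impute <- match.arg(impute)
  stopifnot(inherits(model, "pcm_model"), inherits(matrix, "response_matrix"))
  if (impute == "modal") {
    matrix <- impute_missing(model, matrix, "modal")
  }
  x <- matrix$responses
  sc <- eap_score(model, matrix)
  J <- n_items(model$bank)
  E <- vapply(seq_len(J), function(j) {
    P <- pcm_probabilities(model$bank$deltas[[j]], sc$theta)
    as.vector(P %*% (seq_len(ncol(P)) - 1))
  }, numeric(nrow(x)))
  resid <- x - E
  q3 <- suppressWarnings(stats::cor(resid, use = "pairwise.complete.obs"))
  dimnames(q3) <- list(matrix$item_ids, matrix$item_ids)
  sds <- apply(resid, 2, stats::sd, na.rm = TRUE)
  uncomp <- which(outer(sds == 0 | is.na(sds), sds == 0 | is.na(sds), "|") &
                  upper.tri(q3), arr.ind = TRUE)
  diag(q3) <- NA
  off <- q3[upper.tri(q3)]
  threshold <- offset + mean(off, na.rm = TRUE)
  hits <- which(q3 > threshold & upper.tri(q3), arr.ind = TRUE)
  pairs <- cbind(matrix$item_ids[hits[, 1]], matrix$item_ids[hits[, 2]])
  structure(list(q3 = q3, threshold = threshold, offset = offset,
                 dependent_pairs = pairs,
                 uncomputable_pairs = if (length(uncomp))
                   cbind(matrix$item_ids[uncomp[, 1]],
                         matrix$item_ids[uncomp[, 2]]) else NULL),
            class = "ld_report")
}

## expected (prior-weighted) item information over the latent population
integrated_information <- function(model, item_id) {
  j <- match(item_id, model$bank$item_ids)
  sum(model$quad$weights *
        pcm_item_information(model$bank$deltas[[j]], model$quad$nodes))
}

#' Resolve local dependency by item removal
#'
#' First, items locally dependent with more than one partner are removed
#' iteratively (highest partner count first, ties broken by smaller
#' integrated information; partner counts are recomputed after each
#' removal).  Each surviving isolated pair then loses its less informative
#' member, information being integrated against the latent prior.
#'
#' @param report an [q3_local_dependency()] result.
#' @param model the [pcm_model()] the report was computed from.
#' @return Data frame `removal_plan` with `item_id`, `reason`,
#'   `statistic` (partner count or information deficit).
#' @export
resolve_local_dependency <- function(report, model) {
  stopifnot(inherits(report, "ld_report"), inherits(model, "pcm_model"))
  pairs <- report$dependent_pairs
  plan <- data.frame(item_id = character(), reason = character(),
                     statistic = numeric())
  if (is.null(pairs) || nrow(pairs) == 0) return(plan)
  pairs <- pairs[, 1:2, drop = FALSE]
  repeat {
    cnt <- table(c(pairs[, 1], pairs[, 2]))
    multi <- names(cnt)[cnt >= 2]
    if (!length(multi)) break
    top <- cnt[multi]
    cand <- names(top)[top == max(top)]
    if (length(cand) > 1) {
      infos <- vapply(cand, function(id) integrated_information(model, id), 1)
      cand <- cand[which.min(infos)]
    }
    plan <- rbind(plan, data.frame(item_id = cand, reason = "multiple_partners",
                                   statistic = as.numeric(max(top))))
    keep <- pairs[, 1] != cand & pairs[, 2] != cand
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0) break
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      infos <- c(integrated_information(model, pairs[r, 1]),
                 integrated_information(model, pairs[r, 2]))
      drop <- pairs[r, which.min(infos)]
      plan <- rbind(plan, data.frame(item_id = drop, reason = "isolated_pair",
                                     statistic = min(infos)))
    }
  }
  plan
}

#' Remove misfitting items one at a time
#'
#' Refits the model after every removal and drops the worst-fitting item
#' while its Bonferroni-adjusted item-fit p-value falls below `alpha`.
#'
#' @param matrix a [response_matrix()] on scored categories.
#' @param alpha family-wise significance level (Bonferroni-adjusted across
#'   the items present at each round).
#' @param n_strata strata for [fit_statistics()].
#' @param max_removals safety cap.
#' @return A list with the final `model`, `matrix`, and `removed` (data
#'   frame of item ids with their fit statistics).
#' @export
remove_misfitting_items <- function(matrix, alpha = 0.05, n_strata = 10,
                                    max_removals = Inf) {
  stopifnot(inherits(matrix, "response_matrix"))
  removed <- data.frame(item_id = character(), chi2 = numeric(),
                        df = numeric(), p = numeric())
  repeat {
    if (ncol(matrix$responses) < 2)
      stop("misfit removal would leave fewer than 2 items")
    model <- fit_pcm(matrix)
    if (alpha <= 0 || nrow(removed) >= max_removals) break
    fs <- fit_statistics(model, matrix, n_strata = n_strata)
    thr <- alpha / n_items(model$bank)
    worst <- which.min(fs$item_fit$p)
    if (fs$item_fit$p[worst] >= thr) break
    if (ncol(matrix$responses) <= 2)
      stop("misfit removal would leave fewer than 2 items")
    removed <- rbind(removed, data.frame(
      item_id = fs$item_fit$item_id[worst], chi2 = fs$item_fit$chi2[worst],
      df = fs$item_fit$df[worst], p = fs$item_fit$p[worst]))
    matrix <- subset_items(matrix,
                           setdiff(matrix$item_ids, fs$item_fit$item_id[worst]))
  }
  list(model = model, matrix = matrix, removed = removed)
}

#' Run the full item-purification pipeline
#'
#' Executes the study's stages in order on a raw polytomous matrix:
#' Mokken screening (scalability + monotonicity, failing items removed),
#' a parallel-analysis dimensionality gate, PCM calibration, category
#' threshold diagnosis with a single uniform rescoring solution, refit,
#' Q3 local-dependency removal, refit, DIF screening between groups,
#' refit, and misfit removal.  Every action is recorded in a
#' purification ledger.
#'
#' @param matrix a raw [response_matrix()].
#' @param rescore_map uniform collapsing map applied when any item shows
#'   threshold disorder (default merges the two agree-side and the two
#'   disagree-side categories: 0-1-1-2-2).
#' @param H_min scalability keep-threshold.
#' @param q3_offset offset of the Q3 flagging threshold.
#' @param dif_alpha,misfit_alpha family-wise significance levels.
#' @param minsize monotonicity rest-score group size (`NULL` = default).
#' @param pa_method correlation type for the dimensionality gate
#'   (`"polychoric"` or `"pearson"`); `NULL` skips the gate (for item sets
#'   whose dimensionality has already been established).
#' @param n_reference reference datasets for the gate.
#' @param dif whether to run the DIF stage (needs group labels).
#' @param seed RNG seed for the Monte-Carlo gate.
#' @return A list of class `purification_result`: final `model`, `matrix`,
#'   `bank`, `ledger`, and the per-stage reports.
#' @export
run_purification_pipeline <- function(matrix, rescore_map = c(0L, 1L, 1L, 2L, 2L),
                                      H_min = 0.30, q3_offset = 0.2,
                                      dif_alpha = 0.05, misfit_alpha = 0.05,
                                      minsize = NULL,
                                      pa_method = "polychoric",
                                      n_reference = 20,
                                      dif = !is.null(matrix$group),
                                      seed = 1) {
  stopifnot(inherits(matrix, "response_matrix"))
  led <- new_ledger()
  reports <- list()

  ## 1. Mokken screening
  mok <- mokken_screen(matrix, H_min = H_min, minsize = minsize)
  reports$mokken <- mok
  for (id in mok$flagged_items)
    led <- ledger_add(led, "mokken", id, "remove",
                      statistic = list(item_H = unname(mok$scalability$item_H[id]),
                                       reason = unname(mok$reason[id])),
                      rationale = "failed non-parametric screening")
  keep <- setdiff(matrix$item_ids, mok$flagged_items)
  if (length(keep) < 2) stop("Mokken screening removed too many items")
  matrix <- subset_items(matrix, keep)

  ## 2. dimensionality gate
  if (!is.null(pa_method)) {
    pa <- parallel_analysis(matrix, n_reference = n_reference,
                            method = pa_method, seed = seed)
    reports$parallel_analysis <- pa
    led <- ledger_add(led, "dimensionality", action = "note",
                      statistic = list(n_factors = pa$n_factors_retained,
                                       eig1 = pa$observed_eigenvalues[1],
                                       eig2 = pa$observed_eigenvalues[2]),
                      rationale = "parallel analysis")
    if (pa$n_factors_retained > 1)
      stop("parallel analysis retained ", pa$n_factors_retained,
           " components; the scale is not unidimensional")
  }

  ## 3. initial calibration and threshold diagnosis
  model <- fit_pcm(matrix)
  dis <- detect_threshold_disorder(model)
  reports$threshold_disorder <- dis
  if (any(dis$disordered)) {
    for (id in dis$item_id[dis$disordered])
      led <- ledger_add(led, "rescore", id, "flag",
                        rationale = "disordered category thresholds")
    matrix <- rescore_items(matrix, rescore_map)
    led <- ledger_add(led, "rescore", matrix$item_ids, "rescore",
                      statistic = list(map = paste(rescore_map, collapse = "-")),
                      rationale = "single uniform collapsing solution for all items")
    model <- fit_pcm(matrix)
  }

  ## 4. local dependency
  ld <- q3_local_dependency(model, matrix, offset = q3_offset)
  reports$local_dependency <- ld
  plan <- resolve_local_dependency(ld, model)
  led <- ledger_add(led, "local_dependency", action = "note",
                    statistic = list(n_pairs = nrow(ld$dependent_pairs),
                                     threshold = ld$threshold),
                    rationale = "Q3 screening")
  for (r in seq_len(nrow(plan)))
    led <- ledger_add(led, "local_dependency", plan$item_id[r], "remove",
                      statistic = list(reason = plan$reason[r],
                                       statistic = plan$statistic[r]),
                      rationale = "locally dependent")
  if (nrow(plan)) {
    matrix <- subset_items(matrix, setdiff(matrix$item_ids, plan$item_id))
    if (ncol(matrix$responses) < 2) stop("local dependency removal left < 2 items")
    model <- fit_pcm(matrix)
  }

  ## 5. DIF between service users and carers
  if (isTRUE(dif)) {
    grp <- dif_groups_from_metadata(matrix)
    difres <- detect_dif(matrix, grp, model, alpha = dif_alpha)
    reports$dif <- difres
    flagged <- difres$items$item_id[difres$items$flagged %in% TRUE]
    for (id in flagged)
      led <- ledger_add(led, "dif", id, "remove",
                        statistic = list(
                          r2_change = difres$items$mcfadden_r2_change[
                            difres$items$item_id == id]),
                        rationale = "differential item functioning")
    if (length(flagged)) {
      matrix <- subset_items(matrix, setdiff(matrix$item_ids, flagged))
      model <- fit_pcm(matrix)
    }
  }

  ## 6. item misfit
  mis <- remove_misfitting_items(matrix, alpha = misfit_alpha)
  reports$misfit <- mis$removed
  for (r in seq_len(nrow(mis$removed)))
    led <- ledger_add(led, "misfit", mis$removed$item_id[r], "remove",
                      statistic = list(chi2 = mis$removed$chi2[r],
                                       p = mis$removed$p[r]),
                      rationale = "item misfit after purification")
  model <- mis$model
  matrix <- mis$matrix

  fs <- fit_statistics(model, matrix)
  reports$final_fit <- fs
  led <- ledger_add(led, "fit", action = "note",
                    statistic = list(chi2 = fs$model_chi2, df = fs$model_df,
                                     rmsea = fs$rmsea,
                                     marginal_reliability = fs$marginal_reliability),
                    rationale = "final calibration")
  structure(list(model = model, matrix = matrix, bank = model$bank,
                 ledger = led, reports = reports),
            class = "purification_result")
}

#' @export
print.purification_result <- function(x, ...) {
  cat(sprintf("<purification_result> final bank of %d items (%d removed)\n",
              n_items(x$bank), length(ledger_removed(x$ledger))))
  print(x$ledger)
  invisible(x)
}
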