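#' Select the next adaptive-test item by posterior-weighted information
#'
#' The maximum posterior weighted information (MPWI) criterion integrates
#' each remaining item's information curve against the current theta
#' posterior on the quadrature grid and administers the argmax; ties break
#' deterministically by bank order.
#'
#' @param model a [pcm_model()].
#' @param posterior numeric vector of posterior weights on the model's
#'   quadrature nodes (need not be normalised).
#' @param remaining item ids still available.
#' @return The selected item id.
#' @export
select_next_item <- function(model, posterior, remaining) {
  stopifnot(inherits(model, "pcm_model"))
  if (!length(remaining)) stop("no items remaining")
  idx <- match(remaining, model$bank$item_ids)
  if (anyNA(idx)) stop("unknown item id(s): ",
                       paste(remaining[is.na(idx)], collapse = ", "))
  po <- posterior / sum(posterior)
  crit <- vapply(idx, function(j)
    sum(po * pcm_item_information(model$bank$deltas[[j]], model$quad$nodes)),
    1)
  remaining[which.max(crit)]  # which.max takes the first maximum: bank order
}

#' Administer one fixed-length adaptive test
#'
#' Starting from the prior (so the first item maximises prior-weighted
#' information, i.e. information near the population mean), the session
#' loops select / administer / EAP-update until `stop_at` items are used.
#'
#' @param model a [pcm_model()]; its quadrature prior is the scoring prior.
#' @param responses full integer response vector in bank order (the oracle
#'   the simulee would give to any administered item).
#' @param stop_at number of items to administer.
#' @return A list of class `cat_session`: `administered` (ordered ids),
#'   `interim_theta`, `interim_se`, `final` (one-row `theta_estimate`).
#' @export
run_cat <- function(model, responses, stop_at) {
  stopifnot(inherits(model, "pcm_model"))
  J <- n_items(model$bank)
  if (stop_at < 1 || stop_at > J) stop("stop_at must be in [1, bank size]")
  responses <- as.integer(responses)
  if (length(responses) != J) stop("need a full response vector in bank order")
  th <- model$quad$nodes
  logpost <- log(model$quad$weights)
  administered <- character(0)
  interim_theta <- interim_se <- numeric(0)
  remaining <- model$bank$item_ids
  for (s in seq_len(stop_at)) {
    po <- exp(logpost - max(logpost))
    sel <- select_next_item(model, po, remaining)
    j <- match(sel, model$bank$item_ids)
    if (is.na(responses[j]) || responses[j] < 0 ||
        responses[j] > length(model$bank$deltas[[j]]))
      stop("invalid response for item ", sel)
    logpost <- logpost + model$logP[[j]][, responses[j] + 1L]
    administered <- c(administered, sel)
    remaining <- setdiff(remaining, sel)
    po <- exp(logpost - max(logpost)); po <- po / sum(po)
    m <- sum(po * th)
    interim_theta <- c(interim_theta, m)
    interim_se <- c(interim_se, sqrt(max(sum(po * th^2) - m^2, 0)))
  }
  final <- data.frame(person_id = "p1",
                      theta = interim_theta[stop_at],
                      se = interim_se[stop_at], n_items_used = stop_at)
  class(final) <- c("theta_estimate", "data.frame")
  structure(list(administered = administered, interim_theta = interim_theta,
                 interim_se = interim_se, final = final),
            class = "cat_session")
}

#' Simulate a fixed-length adaptive-testing study
#'
#' Draws simulees from a normal trait distribution, generates complete
#' response vectors from the partial credit model, and administers
#' fixed-length MPWI/EAP adaptive tests at each requested length, reusing
#' the same responses so lengths are directly comparable.  Each length is
#' summarised by the mean, SD and range of the final standard errors
#' (posterior SDs) and the Pearson correlation of the final estimates with
#' full-bank EAP estimates.
#'
#' @param bank a calibrated [item_bank()].
#' @param lengths test lengths to simulate.
#' @param n_simulees number of simulated respondents.
#' @param theta_mean latent population mean.
#' @param theta_var latent population variance (the convention under which
#'   the population is reported as N(mean, 1.90)); set `var_is_sd = TRUE`
#'   to reinterpret it as an SD.
#' @param var_is_sd treat `theta_var` as an SD instead of a variance.
#' @param prior scoring prior: `"matched"` uses the simulee-generating
#'   distribution (the Firestar convention), `"standard"` uses N(0, 1).
#' @param n_nodes,bounds quadrature settings; the default 81 evenly spaced
#'   nodes on \[-4, 4\] follows the convention of the Firestar simulation
#'   tooling this module emulates.
#' @param seed RNG seed.
#' @return A list of class `cat_summary` with `summary` (one row per
#'   length: `n_items`, `mean_se`, `sd_se`, `se_min`, `se_max`,
#'   `corr_with_full_scale`) and `estimates` (per-simulee finals per
#'   length, plus `full` and `true_theta`).
#' @export
simulate_cat_study <- function(bank, lengths = c(19, 15, 10, 5),
                               n_simulees = 1000, theta_mean = -0.08,
                               theta_var = 1.90, var_is_sd = FALSE,
                               prior = c("matched", "standard"),
                               n_nodes = 81, bounds = c(-4, 4), seed = 7) {
  bank <- as_bank(bank)
  prior <- match.arg(prior)
  J <- n_items(bank)
  if (any(lengths < 1 | lengths > J)) stop("lengths must lie in [1, bank size]")
  gen_sd <- if (var_is_sd) theta_var else sqrt(theta_var)
  quad <- if (prior == "matched")
    quadrature_grid(n_nodes, bounds, theta_mean, gen_sd)
  else quadrature_grid(n_nodes, bounds, 0, 1)
  model <- pcm_model(bank, quad)
  set.seed(seed)
  theta <- stats::rnorm(n_simulees, theta_mean, gen_sd)
  x <- generate_pcm_responses(bank, theta)
  full <- eap_score(model, x)
  th <- quad$nodes
  info <- vapply(bank$deltas, function(d) pcm_item_information(d, th),
                 numeric(length(th)))
  logP <- model$logP
  est <- list()
  for (L in sort(lengths, decreasing = TRUE)) {
    if (L == J) {
      # a full-length session administers every item, so its final
      # posterior is the full-bank posterior
      est[[as.character(L)]] <- data.frame(theta = full$theta, se = full$se)
      next
    }
    res <- matrix(0, n_simulees, 2)
    for (p in seq_len(n_simulees)) {
      logpost <- log(quad$weights)
      admin <- integer(0)
      for (s in seq_len(L)) {
        po <- exp(logpost - max(logpost)); po <- po / sum(po)
        crit <- as.vector(po %*% info)
        crit[admin] <- -Inf
        j <- which.max(crit)
        admin <- c(admin, j)
        logpost <- logpost + logP[[j]][, x[p, j] + 1L]
      }
      # final estimate recomputed in bank order so that a full-length
      # session is bit-identical to full-bank EAP scoring
      logpost <- log(quad$weights)
      for (j in sort(admin)) logpost <- logpost + logP[[j]][, x[p, j] + 1L]
      po <- exp(logpost - max(logpost)); po <- po / sum(po)
      m <- sum(po * th)
      res[p, ] <- c(m, sqrt(max(sum(po * th^2) - m^2, 0)))
    }
    est[[as.character(L)]] <- data.frame(theta = res[, 1], se = res[, 2])
  }
  summ <- do.call(rbind, lapply(as.character(sort(lengths, decreasing = TRUE)),
    function(L) {
      e <- est[[L]]
      data.frame(n_items = as.integer(L), mean_se = mean(e$se),
                 sd_se = stats::sd(e$se), se_min = min(e$se),
                 se_max = max(e$se),
                 corr_with_full_scale = stats::cor(e$theta, full$theta))
    }))
  structure(list(summary = summ, estimates = est, full = full,
                 true_theta = theta, prior = prior,
                 theta_mean = theta_mean, gen_sd = gen_sd, seed = seed),
            class = "cat_summary")
}

#' @export
print.cat_summary <- function(x, ...) {
  cat(sprintf("<cat_summary> %d simulees ~ N(%g, sd %.3f), %s prior\n",
              nrow(x$estimates[[1]]), x$theta_mean, x$gen_sd, x$prior))
  print(transform(x$summary, mean_se = round(mean_se, 3),
                  sd_se = round(sd_se, 3), se_min = round(se_min, 3),
                  se_max = round(se_max, 3),
                  corr_with_full_scale = round(corr_with_full_scale, 3)),
        row.names = FALSE)
  invisible(x)
}
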