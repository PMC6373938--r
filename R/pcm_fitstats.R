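#' Item and model fit statistics for a calibrated PCM
#'
#' For each item, persons are stratified on the EAP estimate computed from
#' their *other* responses (leaving the item out removes the dependence of
#' the matching criterion on the response being tested, which otherwise
#' inflates the statistic).  Within each stratum the observed category
#' counts are compared with the posterior-predictive expectation, i.e. each
#' member's category probabilities integrated over their leave-one-out
#' theta posterior.  Strata whose smallest expected cell falls below
#' `min_expected` are merged with their neighbour.  The overall statistic
#' aggregates the item chi-squares (a first-order limited-information
#' discrepancy; the sparse full contingency table is never formed) and the
#' RMSEA is derived from it.
#'
#' @param model a [pcm_model()].
#' @param matrix the [response_matrix()] the model was calibrated on (scored
#'   categories must match the bank).
#' @param n_strata number of theta strata before merging.
#' @param min_expected smallest tolerated expected cell count.
#' @return A list of class `fit_report`: `item_fit` (data frame with `chi2`,
#'   `df`, `p` per item), `model_chi2`, `model_df`, `model_p`, `rmsea`,
#'   `marginal_reliability`, `n_strata_used`.
#' @export
fit_statistics <- function(model, matrix, n_strata = 10, min_expected = 5) {
  stopifnot(inherits(model, "pcm_model"), inherits(matrix, "response_matrix"))
  x <- matrix$responses
  J <- n_items(model$bank)
  th <- model$quad$nodes; Q <- length(th)
  # per-item log-likelihood contributions, so leave-one-out posteriors are
  # cheap: total minus the item's own term
  contrib <- lapply(seq_len(J), function(j) {
    C <- matrix(0, nrow(x), Q)
    obs <- which(!is.na(x[, j]))
    if (length(obs))
      C[obs, ] <- t(model$logP[[j]])[x[obs, j] + 1L, , drop = FALSE]
    C
  })
  total_ll <- matrix(rep(log(model$quad$weights), each = nrow(x)), nrow(x), Q)
  for (j in seq_len(J)) total_ll <- total_ll + contrib[[j]]
  item_chi2 <- item_df <- numeric(J)
  n_used <- integer(J)
  for (j in seq_len(J)) {
    m <- length(model$bank$deltas[[j]])
    obs_rows <- which(!is.na(x[, j]))
    ll <- total_ll[obs_rows, , drop = FALSE] - contrib[[j]][obs_rows, , drop = FALSE]
    po <- exp(ll - apply(ll, 1, max)); po <- po / rowSums(po)
    theta_loo <- as.vector(po %*% th)
    # posterior-predictive category probabilities for each person
    P <- po %*% pcm_probabilities(model$bank$deltas[[j]], th)
    br <- unique(stats::quantile(theta_loo,
                                 probs = seq(0, 1, length.out = n_strata + 1)))
    if (length(br) < 2) br <- range(theta_loo) + c(-1, 1)
    gg <- cut(theta_loo, breaks = br, include.lowest = TRUE, labels = FALSE)
    O <- t(vapply(sort(unique(gg)), function(s)
      tabulate(x[obs_rows, j][gg == s] + 1L, nbins = m + 1), numeric(m + 1)))
    E <- t(vapply(sort(unique(gg)), function(s)
      colSums(P[gg == s, , drop = FALSE]), numeric(m + 1)))
    # merge strata upwards until expected cells are large enough
    while (nrow(E) > 1 && min(E) < min_expected) {
      i <- which(E == min(E), arr.ind = TRUE)[1, 1]
      k <- if (i == nrow(E)) i - 1 else i
      O[k, ] <- O[k, ] + O[k + 1, ]; O <- O[-(k + 1), , drop = FALSE]
      E[k, ] <- E[k, ] + E[k + 1, ]; E <- E[-(k + 1), , drop = FALSE]
    }
    item_chi2[j] <- sum((O - E)^2 / pmax(E, 1e-10))
    item_df[j] <- max(nrow(E) - 1, 1) * m
    n_used[j] <- nrow(E)
  }
  item_p <- stats::pchisq(item_chi2, item_df, lower.tail = FALSE)
  model_chi2 <- sum(item_chi2)
  model_df <- sum(item_df)
  n <- nrow(x)
  rmsea <- sqrt(max(0, model_chi2 - model_df) / (model_df * n))
  rel <- marginal_reliability(model)
  structure(list(
    item_fit = data.frame(item_id = model$bank$item_ids, chi2 = item_chi2,
                          df = item_df, p = item_p, n_strata = n_used),
    model_chi2 = model_chi2, model_df = model_df,
    model_p = stats::pchisq(model_chi2, model_df, lower.tail = FALSE),
    rmsea = rmsea, marginal_reliability = rel, n = n),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> chi2 = %.2f, df = %d, p = %.3g, RMSEA = %.3f, marginal r = %.3f\n",
              x$model_chi2, x$model_df, x$model_p, x$rmsea,
              x$marginal_reliability))
  worst <- x$item_fit[order(x$item_fit$p), ][1, ]
  cat(sprintf("  worst item fit: %s (chi2 = %.2f, df = %d, p = %.3g)\n",
              worst$item_id, worst$chi2, worst$df, worst$p))
  invisible(x)
}

#' Marginal reliability of a calibrated bank
#'
#' Population-averaged reliability `(V - E[SE^2]) / V` over a normal latent
#' population with variance `V = pop_sd^2`.
#'
#' Two conventions for `SE` are offered.  `"eap"` (default) draws
#' `n_sim` simulees from the population, generates full response vectors
#' from the PCM and averages the EAP posterior variance — the reliability of
#' actual EAP scores.  `"information"` averages `1/I(theta)` over the
#' population by quadrature — the asymptotic (prior-free) version, which is
#' slightly lower for short scales.
#'
#' @param bank an [item_bank()] or [pcm_model()].
#' @param pop_mean,pop_sd latent population parameters.
#' @param method `"eap"` or `"information"`.
#' @param n_sim simulees for the EAP method.
#' @param n_nodes,bounds quadrature settings.
#' @param seed RNG seed for the EAP method.
#' @return Reliability in (0, 1).
#' @export
marginal_reliability <- function(bank, pop_mean = 0, pop_sd = 1,
                                 method = c("eap", "information"),
                                 n_sim = 20000, n_nodes = 61,
                                 bounds = c(-6, 6), seed = 101) {
  method <- match.arg(method)
  bank <- as_bank(bank)
  V <- pop_sd^2
  if (method == "information") {
    quad <- quadrature_grid(n_nodes, bounds, pop_mean, pop_sd)
    info <- test_information(bank, quad$nodes)$information
    return((V - sum(quad$weights / info)) / V)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  theta <- stats::rnorm(n_sim, pop_mean, pop_sd)
  x <- generate_pcm_responses(bank, theta)
  model <- pcm_model(bank, quadrature_grid(n_nodes, bounds, pop_mean, pop_sd))
  sc <- eap_score(model, x)
  (V - mean(sc$se^2)) / V
}

## raw PCM draws for a vector of thetas; returns n x J integer matrix
generate_pcm_responses <- function(bank, theta) {
  n <- length(theta)
  J <- n_items(bank)
  x <- matrix(NA_integer_, n, J,
              dimnames = list(NULL, bank$item_ids))
  u <- matrix(stats::runif(n * J), n, J)
  for (j in seq_len(J)) {
    P <- pcm_probabilities(bank$deltas[[j]], theta)
    cp <- t(apply(P, 1, cumsum))
    x[, j] <- rowSums(u[, j] > cp[, -ncol(cp), drop = FALSE])
  }
  x
}

#' Impute missing responses from the calibrated model
#'
#' Each missing cell is filled from the model category distribution at the
#' person's EAP estimate: the modal category by default (deterministic), or
#' a random draw.  Persons with no observed responses are scored at the
#' prior mean and flagged.
#'
#' @param model a [pcm_model()].
#' @param matrix a [response_matrix()] on the model's scored categories.
#' @param method `"modal"` or `"sample"`.
#' @param seed RNG seed used when `method = "sample"`.
#' @return A complete [response_matrix()]; attribute `imputed` holds the
#'   logical mask of filled cells, `no_response_persons` the flagged ids.
#' @export
impute_missing <- function(model, matrix, method = c("modal", "sample"),
                           seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "pcm_model"), inherits(matrix, "response_matrix"))
  x <- matrix$responses
  mask <- is.na(x)
  if (!any(mask)) {
    attr(matrix, "imputed") <- mask
    return(matrix)
  }
  sc <- eap_score(model, matrix)
  if (method == "sample") set.seed(seed)
  for (j in seq_len(ncol(x))) {
    rows <- which(mask[, j])
    if (!length(rows)) next
    P <- pcm_probabilities(model$bank$deltas[[j]], sc$theta[rows])
    x[rows, j] <- if (method == "modal") {
      max.col(P, ties.method = "first") - 1L
    } else {
      cp <- t(apply(P, 1, cumsum))
      rowSums(stats::runif(length(rows)) > cp[, -ncol(cp), drop = FALSE])
    }
  }
  out <- response_matrix(x, matrix$person_ids, matrix$item_ids, matrix$group,
                         max_cat = pmax(matrix$max_cat,
                                        vapply(model$bank$deltas, length, 1L)))
  attr(out, "imputed") <- mask
  attr(out, "no_response_persons") <-
    matrix$person_ids[sc$n_items_used == 0]
  out
}
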