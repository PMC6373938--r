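#' Partial credit model category probabilities
#'
#' For an item with ordered thresholds `deltas` (length m), the probability
#' of scored category k (0..m) at trait value theta is
#' `P(X = k | theta) = exp(sum_{h<=k}(theta - delta_h)) / sum_l exp(...)`,
#' with the empty sum equal to 0.  Computation is stabilised by subtracting
#' the row maximum before exponentiation.
#'
#' @param deltas numeric vector of category thresholds.
#' @param theta numeric vector of trait values.
#' @return A `length(theta)` x `(length(deltas) + 1)` matrix of
#'   probabilities; rows sum to 1.
#' @examples
#' pcm_probabilities(c(0, 0), 0)   # (1/3, 1/3, 1/3)
#' @export
pcm_probabilities <- function(deltas, theta) {
  deltas <- as.numeric(deltas)
  if (!all(is.finite(deltas))) stop("thresholds must be finite")
  csum <- c(0, cumsum(-deltas))
  k <- seq_along(csum) - 1
  lin <- outer(theta, k) + matrix(csum, length(theta), length(csum), byrow = TRUE)
  lin <- lin - apply(lin, 1, max)
  e <- exp(lin)
  e / rowSums(e)
}

#' Item information of a partial credit item
#'
#' Under the PCM (unit slope) the item information equals the conditional
#' category variance `Var(X | theta)`.
#'
#' @param deltas numeric thresholds.
#' @param theta numeric vector of trait values.
#' @return Numeric vector of information values.
#' @export
pcm_item_information <- function(deltas, theta) {
  P <- pcm_probabilities(deltas, theta)
  k <- seq_len(ncol(P)) - 1
  as.vector(P %*% k^2) - as.vector(P %*% k)^2
}

#' Test information and standard-error curve of a bank
#'
#' @param bank an [item_bank()] (or `pcm_model`).
#' @param theta numeric vector of trait values.
#' @return A data frame with `theta`, `information` (sum of item
#'   informations) and `se` (`1/sqrt(information)`).
#' @export
test_information <- function(bank, theta) {
  bank <- as_bank(bank)
  M <- vapply(bank$deltas, function(d) pcm_item_information(d, theta),
              numeric(length(theta)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(theta))
  info <- rowSums(M)
  data.frame(theta = theta, information = info, se = 1 / sqrt(info))
}

as_bank <- function(x) {
  if (inherits(x, "pcm_model")) x$bank
  else if (inherits(x, "item_bank")) x
  else stop("expected an item_bank or pcm_model")
}

#' Build a quadrature grid with normal prior weights
#'
#' @param n_nodes number of equally spaced nodes.
#' @param bounds grid end points on the theta metric.
#' @param mean,sd prior normal parameters.
#' @return List with `nodes` and `weights` (weights sum to 1).
#' @export
quadrature_grid <- function(n_nodes = 61, bounds = c(-6, 6), mean = 0, sd = 1) {
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- stats::dnorm(nodes, mean, sd)
  list(nodes = nodes, weights = w / sum(w), mean = mean, sd = sd)
}

#' Assemble a PCM model object from a calibrated bank
#'
#' @param bank an [item_bank()] holding threshold estimates.
#' @param quad quadrature grid from [quadrature_grid()]; the grid's prior is
#'   the scoring prior used by [eap_score()].
#' @param loglik optional marginal log-likelihood at convergence.
#' @return An object of class `pcm_model`.
#' @export
pcm_model <- function(bank, quad = quadrature_grid(), loglik = NA_real_) {
  stopifnot(inherits(bank, "item_bank"))
  # cache per-item log category probabilities on the grid
  logP <- lapply(bank$deltas, function(d) log(pcm_probabilities(d, quad$nodes)))
  structure(list(bank = bank, quad = quad, logP = logP, loglik = loglik),
            class = "pcm_model")
}

#' @export
print.pcm_model <- function(x, ...) {
  cat(sprintf("<pcm_model> %d items, %d quadrature nodes on [%g, %g], prior N(%g, %g)\n",
              n_items(x$bank), length(x$quad$nodes), min(x$quad$nodes),
              max(x$quad$nodes), x$quad$mean, x$quad$sd))
  if (is.finite(x$loglik)) cat(sprintf("  marginal logLik %.2f\n", x$loglik))
  invisible(x)
}

## log-posterior (unnormalised) over the grid for a matrix of responses;
## x is n x J integer with NA, logP the model's cached list
post_matrix <- function(model, x) {
  Q <- length(model$quad$nodes)
  n <- nrow(x)
  ll <- matrix(rep(log(model$quad$weights), each = n), n, Q)
  for (j in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, j]))
    if (!length(obs)) next
    ll[obs, ] <- ll[obs, ] + t(model$logP[[j]])[x[obs, j] + 1L, , drop = FALSE]
  }
  m <- apply(ll, 1, max)
  po <- exp(ll - m)
  list(post = po / rowSums(po), log_marg = m + log(rowSums(po)))
}

#' EAP trait estimates
#'
#' Bayesian expected-a-posteriori scoring on the model's quadrature grid.
#' With no observed responses the posterior is the prior, so the estimate is
#' the (grid-discretised) prior mean with the prior SD as its standard error.
#'
#' @param model a [pcm_model()].
#' @param responses a [response_matrix()], an integer matrix, or a single
#'   response vector (`NA` = not administered).  Items must be in bank order.
#' @return A data frame of class `theta_estimate` with `person_id`, `theta`,
#'   `se` (posterior SD) and `n_items_used`.
#' @export
eap_score <- function(model, responses) {
  stopifnot(inherits(model, "pcm_model"))
  if (inherits(responses, "response_matrix")) {
    pid <- responses$person_ids
    x <- responses$responses
  } else if (is.matrix(responses)) {
    x <- responses
    pid <- rownames(x) %||% paste0("p", seq_len(nrow(x)))
  } else {
    x <- matrix(as.integer(responses), nrow = 1)
    pid <- "p1"
  }
  if (ncol(x) != n_items(model$bank))
    stop("responses have ", ncol(x), " columns but the bank has ",
         n_items(model$bank), " items")
  maxk <- vapply(model$bank$deltas, length, 1L)
  for (j in seq_len(ncol(x))) {
    bad <- which(!is.na(x[, j]) & (x[, j] < 0 | x[, j] > maxk[j]))
    if (length(bad))
      stop(sprintf("response %d out of range [0, %d] for item '%s'",
                   x[bad[1], j], maxk[j], model$bank$item_ids[j]))
  }
  po <- post_matrix(model, x)$post
  th <- model$quad$nodes
  m1 <- as.vector(po %*% th)
  v <- as.vector(po %*% th^2) - m1^2
  out <- data.frame(person_id = pid, theta = m1, se = sqrt(pmax(v, 0)),
                    n_items_used = rowSums(!is.na(x)))
  class(out) <- c("theta_estimate", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate a partial credit model by marginal maximum likelihood
#'
#' EM estimation with a fixed standard-normal latent prior (the
#' identification convention) on an equally spaced quadrature grid.  Missing
#' responses contribute nothing to the likelihood.  Raw categories that are
#' unobserved in the data are merged into their lower neighbour before
#' estimation and the action is recorded in the returned `recode_log`.
#'
#' @param matrix a [response_matrix()].
#' @param n_nodes,bounds quadrature settings (default 61 nodes on \[-6, 6\]).
#' @param tol convergence tolerance on `max |delta_change|`.
#' @param max_iter maximum EM iterations.
#' @return A [pcm_model()] with elements `loglik_trace`, `converged`,
#'   `n_iter` and `recode_log` added.
#' @export
fit_pcm <- function(matrix, n_nodes = 61, bounds = c(-6, 6), tol = 1e-4,
                    max_iter = 500) {
  stopifnot(inherits(matrix, "response_matrix"))
  x <- matrix$responses
  J <- ncol(x)
  if (J < 2) stop("need at least 2 items to calibrate")
  recode_log <- list()
  maxk <- integer(J)
  for (j in seq_len(J)) {
    xj <- x[, j]
    obs <- sort(unique(xj[!is.na(xj)]))
    if (length(obs) < 2)
      stop("item '", matrix$item_ids[j], "' has fewer than 2 observed categories")
    full <- 0:max(obs)
    if (!identical(obs, full)) {
      # merge unobserved categories downwards so scored codes are contiguous
      map <- cumsum(full %in% obs) - 1L
      map[map < 0L] <- 0L
      x[, j] <- map[xj + 1L]
      recode_log[[matrix$item_ids[j]]] <-
        list(observed = obs, map = stats::setNames(map, full))
    }
    maxk[j] <- max(x[, j], na.rm = TRUE)
  }
  quad <- quadrature_grid(n_nodes, bounds, mean = 0, sd = 1)
  th <- quad$nodes; Q <- length(th)
  # starting values: equally spaced around 0
  deltas <- lapply(maxk, function(m) seq(-0.5, 0.5, length.out = m))
  ind <- lapply(seq_len(J), function(j) {
    lapply(0:maxk[j], function(k) which(x[, j] == k))  # persons per category
  })
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    model <- pcm_model(item_bank(matrix$item_ids, deltas), quad)
    pm <- post_matrix(model, x)
    ll <- sum(pm$log_marg)
    ll_trace <- c(ll_trace, ll)
    new_deltas <- deltas
    for (j in seq_len(J)) {
      # expected category counts at each node: r[q, k]
      r <- vapply(ind[[j]], function(rows)
        if (length(rows)) colSums(pm$post[rows, , drop = FALSE]) else numeric(Q),
        numeric(Q))
      nq <- rowSums(r)
      obj <- function(d) {
        lp <- log(pcm_probabilities(d, th))
        -sum(r * lp)
      }
      grad <- function(d) {
        P <- pcm_probabilities(d, th)
        m <- ncol(P) - 1
        g <- numeric(m)
        for (h in seq_len(m)) {
          p_ge <- rowSums(P[, (h + 1):(m + 1), drop = FALSE])
          o_ge <- rowSums(r[, (h + 1):(m + 1), drop = FALSE])
          g[h] <- sum(o_ge) - sum(nq * p_ge)
        }
        g
      }
      opt <- stats::optim(deltas[[j]], obj, grad, method = "BFGS",
                          control = list(maxit = 50, reltol = 1e-10))
      new_deltas[[j]] <- opt$par
    }
    delta_change <- max(abs(unlist(new_deltas) - unlist(deltas)))
    deltas <- new_deltas
    if (delta_change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "PCM calibration did not converge in %d iterations (last max |delta change| %.2g)",
      max_iter, delta_change))
    cond$last_model <- pcm_model(item_bank(matrix$item_ids, deltas), quad)
    stop(cond)
  }
  scoring <- lapply(seq_len(J), function(j) {
    id <- matrix$item_ids[j]
    if (id %in% names(recode_log)) as.integer(recode_log[[id]]$map) else 0:maxk[j]
  })
  bank <- item_bank(matrix$item_ids, deltas, labels = matrix$item_ids,
                    scoring_maps = scoring)
  model <- pcm_model(bank, quad, loglik = ll_trace[length(ll_trace)])
  model$loglik_trace <- ll_trace
  model$converged <- TRUE
  model$n_iter <- it
  model$recode_log <- recode_log
  model
}
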