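#' Loevinger scalability coefficients
#'
#' For each item pair, `H_ij = cov(X_i, X_j) / covmax(X_i, X_j)`, where
#' `covmax` is the covariance the pair would attain under the maximally
#' concordant joint distribution with the same marginals (equivalently, the
#' covariance after sorting both columns — the rearrangement bound).  Item
#' and scale coefficients are the corresponding ratios of summed covariances.
#' Pairwise-complete observations are used throughout.
#'
#' @param matrix a [response_matrix()].
#' @return A list of class `mokken_h`: `pair_H` (J x J, `NA` diagonal),
#'   `item_H` (named vector; `NA` where undefined), `scale_H`, and
#'   `zero_variance_items`.
#' @export
loevinger_coefficients <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  x <- matrix$responses
  J <- ncol(x)
  if (J < 2) stop("need at least 2 items")
  cov_o <- cov_m <- matrix(NA_real_, J, J,
                           dimnames = list(matrix$item_ids, matrix$item_ids))
  zero_var <- vapply(seq_len(J), function(j) {
    v <- x[!is.na(x[, j]), j]; length(unique(v)) < 2
  }, TRUE)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    if (sum(ok) < 3 || zero_var[i] || zero_var[j]) next
    xi <- x[ok, i]; xj <- x[ok, j]
    if (length(unique(xi)) < 2 || length(unique(xj)) < 2) next
    cov_o[i, j] <- cov_o[j, i] <- stats::cov(xi, xj)
    cov_m[i, j] <- cov_m[j, i] <- stats::cov(sort(xi), sort(xj))
  }
  pair_H <- cov_o / cov_m
  item_H <- vapply(seq_len(J), function(i) {
    num <- sum(cov_o[i, ], na.rm = TRUE)
    den <- sum(cov_m[i, ], na.rm = TRUE)
    if (zero_var[i] || den == 0 || all(is.na(cov_m[i, ]))) NA_real_ else num / den
  }, 1)
  names(item_H) <- matrix$item_ids
  den <- sum(cov_m[upper.tri(cov_m)], na.rm = TRUE)
  scale_H <- if (den > 0) sum(cov_o[upper.tri(cov_o)], na.rm = TRUE) / den
             else NA_real_
  structure(list(pair_H = pair_H, item_H = item_H, scale_H = scale_H,
                 zero_variance_items = matrix$item_ids[zero_var]),
            class = "mokken_h")
}

#' Check manifest monotonicity against the rest score
#'
#' Persons are partitioned into rest-score groups (the rest score for item i
#' being the mean response over the person's other observed items, so that
#' missingness does not bias the ordering), merging adjacent quantile groups
#' until each holds at least `minsize` persons.  For every item step
#' `P(X >= k)` and every ordered pair of groups, a violation is a decrease
#' of more than `minvi`; its significance is a one-sided two-proportion
#' z-test.  An item is flagged when it has at least one significant
#' violation at `alpha`.
#'
#' @param matrix a [response_matrix()].
#' @param minsize minimum rest-score group size; default `max(50, n/10)`.
#' @param minvi minimal decrease counted as a violation.
#' @param alpha significance level for flagging.
#' @return A list of class `mokken_monotonicity` with a per-item data frame
#'   (`n_active_pairs`, `n_violations`, `max_violation`, `n_significant`,
#'   `testable`) and `flagged_items`.
#' @export
check_monotonicity <- function(matrix, minsize = NULL, minvi = 0.03,
                               alpha = 0.05) {
  stopifnot(inherits(matrix, "response_matrix"))
  x <- matrix$responses
  n <- nrow(x); J <- ncol(x)
  if (is.null(minsize)) minsize <- max(50, floor(n / 10))
  res <- data.frame(item_id = matrix$item_ids, n_active_pairs = 0L,
                    n_violations = 0L, max_violation = 0,
                    n_significant = 0L, testable = TRUE)
  for (i in seq_len(J)) {
    obs <- which(!is.na(x[, i]))
    rest <- rowMeans(x[obs, -i, drop = FALSE], na.rm = TRUE)
    usable <- is.finite(rest)
    obs <- obs[usable]; rest <- rest[usable]
    n_grp_target <- max(2L, floor(length(obs) / minsize))
    if (length(obs) < 2 * minsize) {
      res$testable[i] <- FALSE
      next
    }
    br <- unique(stats::quantile(rest, probs = seq(0, 1, length.out = n_grp_target + 1)))
    if (length(br) < 3) { res$testable[i] <- FALSE; next }
    g <- cut(rest, br, include.lowest = TRUE, labels = FALSE)
    # merge any small groups into their neighbour
    repeat {
      sizes <- table(g)
      if (length(sizes) <= 2 || min(sizes) >= minsize) break
      sm <- as.integer(names(sizes)[which.min(sizes)])
      tgt <- if (sm == max(g)) sm - 1L else sm + 1L
      g[g == sm] <- tgt
      g <- as.integer(factor(g))
    }
    G <- max(g)
    if (G < 2) { res$testable[i] <- FALSE; next }
    maxk <- max(x[obs, i])
    for (k in seq_len(maxk)) {
      step <- as.integer(x[obs, i] >= k)
      ph <- as.vector(tapply(step, factor(g, levels = seq_len(G)), mean))
      ns <- tabulate(g, G)
      for (a in seq_len(G - 1)) for (b in (a + 1):G) {
        res$n_active_pairs[i] <- res$n_active_pairs[i] + 1L
        diff <- ph[a] - ph[b]
        if (diff > minvi) {
          res$n_violations[i] <- res$n_violations[i] + 1L
          res$max_violation[i] <- max(res$max_violation[i], diff)
          p_pool <- (ph[a] * ns[a] + ph[b] * ns[b]) / (ns[a] + ns[b])
          se <- sqrt(p_pool * (1 - p_pool) * (1 / ns[a] + 1 / ns[b]))
          if (se > 0 && stats::pnorm(diff / se, lower.tail = FALSE) < alpha)
            res$n_significant[i] <- res$n_significant[i] + 1L
        }
      }
    }
  }
  flagged <- res$item_id[res$n_significant > 0]
  structure(list(items = res, flagged_items = flagged,
                 minsize = minsize, minvi = minvi, alpha = alpha),
            class = "mokken_monotonicity")
}

#' Mokken screening of a response matrix
#'
#' Combines [loevinger_coefficients()] and [check_monotonicity()] and flags
#' items that fail either the scalability keep-threshold (`item H < H_min`)
#' or the monotonicity check.
#'
#' @param matrix a [response_matrix()].
#' @param H_min keep-threshold on the item scalability coefficient.
#' @param ... passed to [check_monotonicity()].
#' @return A list of class `mokken_result` with `scalability`,
#'   `monotonicity`, and `flagged_items` (with a `reason` attribute).
#' @export
mokken_screen <- function(matrix, H_min = 0.30, ...) {
  h <- loevinger_coefficients(matrix)
  mono <- check_monotonicity(matrix, ...)
  low_H <- names(h$item_H)[!is.na(h$item_H) & h$item_H < H_min]
  flagged <- union(low_H, mono$flagged_items)
  reason <- vapply(flagged, function(id) paste(c(
    if (id %in% low_H) "low_scalability",
    if (id %in% mono$flagged_items) "nonmonotone"), collapse = "+"), "")
  structure(list(scalability = h, monotonicity = mono, H_min = H_min,
                 flagged_items = flagged, reason = reason),
            class = "mokken_result")
}

#' Parallel principal component analysis for dimensionality
#'
#' Eigenvalues of the observed inter-item correlation matrix (polychoric by
#' default, Pearson on request or as a per-pair fallback for degenerate
#' tables) are compared with mean eigenvalues from `n_reference` random
#' datasets of identical dimensions whose items are drawn independently from
#' the observed marginal category frequencies.  Components are retained
#' while the observed eigenvalue exceeds the reference at the same rank.
#'
#' @param matrix a [response_matrix()].
#' @param n_reference number of Monte-Carlo reference datasets.
#' @param method `"polychoric"` or `"pearson"`.
#' @param seed RNG seed for the reference datasets.
#' @return A list of class `parallel_analysis` with `observed_eigenvalues`,
#'   `reference_eigenvalues`, `n_factors_retained`, `smoothed`.
#' @export
parallel_analysis <- function(matrix, n_reference = 20,
                              method = c("polychoric", "pearson"), seed = 1) {
  stopifnot(inherits(matrix, "response_matrix"))
  method <- match.arg(method)
  x <- matrix$responses
  R <- correlation_matrix(x, method)
  obs <- sort(eigen(R$mat, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  set.seed(seed)
  J <- ncol(x); n <- nrow(x)
  ref <- matrix(0, n_reference, J)
  for (r in seq_len(n_reference)) {
    xr <- vapply(seq_len(J), function(j) {
      v <- x[!is.na(x[, j]), j]
      sample(v, n, replace = TRUE)
    }, integer(n))
    ref[r, ] <- sort(eigen(correlation_matrix(xr, method)$mat,
                           symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  ref_mean <- colMeans(ref)
  keep <- 0L
  for (k in seq_len(J)) {
    if (obs[k] > ref_mean[k]) keep <- keep + 1L else break
  }
  structure(list(observed_eigenvalues = obs, reference_eigenvalues = ref_mean,
                 n_factors_retained = keep, method = method,
                 smoothed = R$smoothed),
            class = "parallel_analysis")
}

## correlation matrix with optional polychoric estimation and PD smoothing
correlation_matrix <- function(x, method) {
  J <- ncol(x)
  smoothed <- FALSE
  if (method == "pearson") {
    R <- stats::cor(x, use = "pairwise.complete.obs")
    R[is.na(R)] <- 0; diag(R) <- 1
  } else {
    R <- diag(J)
    for (i in seq_len(J - 1)) for (j in (i + 1):J) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      r <- polychoric_corr(x[ok, i], x[ok, j])
      R[i, j] <- R[j, i] <- r
    }
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    # nearest-PD smoothing: clip eigenvalues, restore unit diagonal
    v <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    D <- 1 / sqrt(diag(R))
    R <- diag(D) %*% R %*% diag(D)
    smoothed <- TRUE
  }
  list(mat = R, smoothed = smoothed)
}
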