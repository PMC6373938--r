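#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimator: thresholds are fixed at the normal quantiles of the
#' marginal cumulative proportions, then the latent correlation maximises
#' the bivariate-normal likelihood of the contingency table.  Degenerate
#' tables (an empty margin, or a perfect diagonal) fall back to the Pearson
#' correlation of the category codes.
#'
#' @param x,y integer category vectors of equal length (no missing values).
#' @return The estimated latent correlation in (-1, 1).
#' @export
polychoric_corr <- function(x, y) {
  tab <- table(factor(x), factor(y))
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  n <- sum(tab)
  tx <- stats::qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  ty <- stats::qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]
  if (!all(is.finite(tx)) || !all(is.finite(ty)))
    return(stats::cor(as.numeric(x), as.numeric(y)))
  negll <- function(rho) {
    pr <- cell_probs_bvn(tx, ty, rho)
    -sum(tab * log(pmax(pr, 1e-12)))
  }
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-4)
  opt$minimum
}

## rectangle probabilities of the standard bivariate normal for all cells
## defined by threshold vectors tx, ty; the CDF at every finite (a, b)
## corner is computed in one vectorised Gauss-Legendre pass
cell_probs_bvn <- function(tx, ty, rho) {
  gl <- legendre_cache(32)
  lo <- -8.5
  s <- sqrt(max(1 - rho^2, 1e-12))
  na <- length(tx); nb <- length(ty)
  # nodes/weights for each finite x-threshold
  half <- (tx - lo) / 2
  Z <- outer(half, gl$x) + (tx + lo) / 2          # na x K
  W <- outer(half, gl$w) * stats::dnorm(Z)        # na x K
  Fin <- vapply(seq_len(nb), function(j)
    rowSums(W * stats::pnorm((ty[j] - rho * Z) / s)), numeric(na))
  Fin <- matrix(Fin, na, nb)
  ax <- c(-Inf, tx, Inf); ay <- c(-Inf, ty, Inf)
  Fmat <- matrix(0, na + 2, nb + 2)
  Fmat[2:(na + 1), 2:(nb + 1)] <- Fin
  Fmat[na + 2, 2:(nb + 1)] <- stats::pnorm(ty)    # a = +Inf
  Fmat[2:(na + 1), nb + 2] <- stats::pnorm(tx)    # b = +Inf
  Fmat[na + 2, nb + 2] <- 1
  nr <- na + 1; nc <- nb + 1
  Fmat[2:(nr + 1), 2:(nc + 1)] - Fmat[1:nr, 2:(nc + 1)] -
    Fmat[2:(nr + 1), 1:nc] + Fmat[1:nr, 1:nc]
}

legendre_cache <- local({
  store <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(store[[key]])) store[[key]] <<- legendre_nodes(n)
    store[[key]]
  }
})

## bivariate standard normal CDF P(Z1 <= a, Z2 <= b) with correlation rho,
## by Gauss-Legendre integration of phi(z) * Phi((b - rho z)/sqrt(1-rho^2))
pbvn <- local({
  gl <- NULL
  function(a, b, rho) {
    if (is.infinite(a) && a < 0) return(0)
    if (is.infinite(b) && b < 0) return(0)
    if (is.infinite(a)) return(stats::pnorm(b))
    if (is.infinite(b)) return(stats::pnorm(a))
    if (abs(rho) >= 1 - 1e-12) {
      return(if (rho > 0) stats::pnorm(min(a, b))
             else max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
    }
    if (is.null(gl)) gl <<- legendre_nodes(48)
    lo <- -8.5
    if (a <= lo) return(0)
    z <- (a - lo) / 2 * gl$x + (a + lo) / 2
    w <- (a - lo) / 2 * gl$w
    s <- sqrt(1 - rho^2)
    sum(w * stats::dnorm(z) * stats::pnorm((b - rho * z) / s))
  }
})

## Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
legendre_nodes <- function(n) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  Tm <- diag(0, n)
  Tm[cbind(i, i + 1)] <- beta
  Tm[cbind(i + 1, i)] <- beta
  e <- eigen(Tm, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}
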