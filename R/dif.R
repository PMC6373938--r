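#' Derive the DIF contrast from person metadata
#'
#' Builds the service-user versus carer contrast: persons labelled as both
#' or unreported are excluded (counted in the `excluded` attribute).
#'
#' @param matrix a [response_matrix()] with group metadata.
#' @param levels the two labels to contrast.
#' @return Factor of length `n_persons` with two levels and `NA` for
#'   excluded persons; attribute `excluded` counts them.
#' @export
dif_groups_from_metadata <- function(matrix,
                                     levels = c("service_user", "carer")) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (is.null(matrix$group)) stop("matrix carries no group metadata")
  g <- factor(ifelse(matrix$group %in% levels, matrix$group, NA),
              levels = levels)
  if (length(stats::na.omit(unique(g))) < 2)
    stop("fewer than 2 usable groups in metadata")
  attr(g, "excluded") <- sum(is.na(g))
  g
}

## fit the three nested cumulative-logit models for one item; returns NULL
## on separation/convergence failure
dif_item_models <- function(y, theta, group) {
  ok <- !is.na(y) & !is.na(group)
  y <- droplevels(factor(y[ok], ordered = TRUE))
  th <- theta[ok]; g <- droplevels(group[ok])
  if (nlevels(y) < 2 || nlevels(g) < 2) return(NULL)
  fit <- function(f, d) tryCatch(
    suppressWarnings(MASS::polr(f, data = d, Hess = FALSE)),
    error = function(e) NULL)
  d <- data.frame(y = y, th = th, g = g)
  m0 <- fit(y ~ th, d)
  m1 <- fit(y ~ th + g, d)
  m2 <- fit(y ~ th * g, d)
  mnull <- fit(y ~ 1, d)
  if (is.null(m0) || is.null(m1) || is.null(m2) || is.null(mnull)) return(NULL)
  ll <- vapply(list(mnull, m0, m1, m2), function(m) as.numeric(stats::logLik(m)), 1)
  if (any(!is.finite(ll))) return(NULL)
  list(ll_null = ll[1], ll0 = ll[2], ll1 = ll[3], ll2 = ll[4])
}

#' Hybrid ordinal-regression / IRT differential item functioning
#'
#' For each item, nested proportional-odds models of the response on the
#' matching criterion (the EAP trait estimate) are compared: M0 `y ~ theta`,
#' M1 adds the group main effect (uniform DIF), M2 adds the interaction
#' (non-uniform DIF).  Total DIF is the likelihood-ratio test of M2 against
#' M0 (2 df), Bonferroni-corrected across items; its magnitude is the
#' McFadden pseudo-R-squared change.  An item is flagged only when the
#' corrected test is significant *and* the magnitude exceeds `r2_cut`.
#' Purification iterates: the matching criterion is re-estimated from the
#' non-flagged items until the flagged set stabilises.
#'
#' @param matrix a [response_matrix()] on the model's scored categories.
#' @param group_labels two-level factor from [dif_groups_from_metadata()]
#'   (`NA` = excluded person).
#' @param model the calibrated [pcm_model()].
#' @param alpha family-wise significance level (Bonferroni across items).
#' @param r2_cut magnitude cut-off for meaningful DIF.
#' @param max_rounds purification iteration cap.
#' @return A list of class `dif_result`: `items` data frame
#'   (`lr_chi2_uniform`, `lr_chi2_total`, `p_uniform`, `p_total`,
#'   `mcfadden_r2_change`, `flagged`, `unstable`), `n_rounds`,
#'   `n_excluded`.
#' @export
detect_dif <- function(matrix, group_labels, model, alpha = 0.05,
                       r2_cut = 0.035, max_rounds = 10) {
  stopifnot(inherits(matrix, "response_matrix"), inherits(model, "pcm_model"))
  x <- matrix$responses
  J <- ncol(x)
  group_labels <- factor(group_labels)
  if (nlevels(group_labels) != 2)
    stop("DIF contrast requires exactly 2 groups")
  flagged_prev <- character(0)
  rounds <- 0
  items <- NULL
  repeat {
    rounds <- rounds + 1
    anchor <- setdiff(matrix$item_ids, flagged_prev)
    if (length(anchor) < 2) anchor <- matrix$item_ids  # refuse to purify away the scale
    xa <- x
    xa[, !(matrix$item_ids %in% anchor)] <- NA_integer_
    theta <- eap_score(model, xa)$theta
    items <- do.call(rbind, lapply(seq_len(J), function(j) {
      mres <- dif_item_models(x[, j], theta, group_labels)
      if (is.null(mres))
        return(data.frame(item_id = matrix$item_ids[j],
                          lr_chi2_uniform = NA, lr_chi2_total = NA,
                          p_uniform = NA, p_total = NA,
                          mcfadden_r2_change = NA, flagged = NA,
                          unstable = TRUE))
      lr_u <- 2 * (mres$ll1 - mres$ll0)
      lr_t <- 2 * (mres$ll2 - mres$ll0)
      r2 <- (1 - mres$ll2 / mres$ll_null) - (1 - mres$ll0 / mres$ll_null)
      data.frame(item_id = matrix$item_ids[j],
                 lr_chi2_uniform = lr_u, lr_chi2_total = lr_t,
                 p_uniform = stats::pchisq(max(lr_u, 0), 1, lower.tail = FALSE),
                 p_total = stats::pchisq(max(lr_t, 0), 2, lower.tail = FALSE),
                 mcfadden_r2_change = r2, flagged = FALSE, unstable = FALSE)
    }))
    thr <- alpha / J
    items$flagged <- !items$unstable & items$p_total < thr &
      items$mcfadden_r2_change > r2_cut
    flagged_now <- items$item_id[items$flagged %in% TRUE]
    if (setequal(flagged_now, flagged_prev) || rounds >= max_rounds) break
    flagged_prev <- flagged_now
  }
  structure(list(items = items, n_rounds = rounds,
                 n_excluded = sum(is.na(group_labels)),
                 alpha = alpha, r2_cut = r2_cut,
                 groups = levels(group_labels)),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, ...) {
  nf <- sum(x$items$flagged %in% TRUE)
  cat(sprintf("<dif_result> %s vs %s: %d of %d items flagged (%d rounds)\n",
              x$groups[1], x$groups[2], nf, nrow(x$items), x$n_rounds))
  if (nf) print(x$items[x$items$flagged %in% TRUE,
                        c("item_id", "lr_chi2_total", "p_total",
                          "mcfadden_r2_change")])
  invisible(x)
}
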