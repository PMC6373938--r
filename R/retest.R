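#' Test-retest agreement of paired trait estimates
#'
#' Pairs the two occasions on person id, reports the Pearson correlation
#' with its two-sided p-value, and the Bland-Altman limits of agreement of
#' the baseline-minus-followup differences (`mean_diff +/- 1.96 sd_diff`),
#' with the percentage of pairs falling inside them.
#'
#' @param theta_t1,theta_t2 `theta_estimate` data frames from
#'   [eap_score()] (or any data frames with `person_id` and `theta`).
#' @param loa_multiplier width of the limits in SD units.
#' @return A list of class `agreement_result`: `n_pairs`, `pearson_r`,
#'   `p_value`, `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pct_within_loa`, `pairs` (per-pair table with `within_loa`).
#' @examples
#' t1 <- data.frame(person_id = letters[1:5], theta = c(1, 2, 0, -1, .5))
#' t2 <- data.frame(person_id = letters[1:5], theta = c(1.1, 1.8, .3, -.9, .6))
#' test_retest(t1, t2)$pearson_r
#' @export
test_retest <- function(theta_t1, theta_t2, loa_multiplier = 1.96) {
  id <- intersect(theta_t1$person_id, theta_t2$person_id)
  if (length(id) < 3) stop("need at least 3 matched pairs")
  a <- theta_t1$theta[match(id, theta_t1$person_id)]
  b <- theta_t2$theta[match(id, theta_t2$person_id)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(a, b)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  lo <- md - loa_multiplier * sdd
  hi <- md + loa_multiplier * sdd
  within <- d >= lo & d <= hi
  structure(list(n_pairs = length(id), pearson_r = r, p_value = p,
                 mean_diff = md, sd_diff = sdd, loa_low = lo, loa_high = hi,
                 pct_within_loa = 100 * mean(within),
                 pairs = data.frame(person_id = id, t1 = a, t2 = b,
                                    diff = d, within_loa = within)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d, r = %.3f (p = %.3g)\n",
              x$n_pairs, x$pearson_r, x$p_value))
  cat(sprintf("  Bland-Altman: mean diff %.3f, LoA [%.3f, %.3f], %.1f%% within\n",
              x$mean_diff, x$loa_low, x$loa_high, x$pct_within_loa))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x an `agreement_result`.
#' @param ... passed to [plot()].
#' @export
plot_bland_altman <- function(x, ...) {
  stopifnot(inherits(x, "agreement_result"))
  m <- (x$pairs$t1 + x$pairs$t2) / 2
  plot(m, x$pairs$diff, xlab = "Mean of occasions",
       ylab = "Baseline - followup", ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}
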