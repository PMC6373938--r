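test_that("category probabilities follow the partial credit formula", {
  expect_equal(as.vector(pcm_probabilities(c(0, 0), 0)), rep(1 / 3, 3))
  # printed first-row thresholds: middle category modal between them
  p <- as.vector(pcm_probabilities(c(-1.20, 0.12), 0))
  expect_equal(p, oracle_pcm_probs(c(-1.20, 0.12), 0))
  expect_equal(which.max(p), 2L)
  # limits and normalisation over random draws
  set.seed(1)
  for (i in 1:1000) {
    d <- sort(runif(sample(1:4, 1), -3, 3))
    th <- runif(1, -5, 5)
    p <- as.vector(pcm_probabilities(d, th))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1)
  }
  expect_gt(pcm_probabilities(c(-1.2, 0.12), 30)[1, 3], 1 - 1e-8)
})

test_that("item information equals the conditional variance and the
           finite-difference curvature of the log-likelihood", {
  d <- c(-1.1, 0.4)
  for (th in c(-2, -0.5, 0, 1, 2.5)) {
    info <- pcm_item_information(d, th)
    # oracle: -E[d2/dtheta2 log P_X(theta)] by central differences
    h <- 1e-4
    curv <- 0
    for (k in 0:2) {
      lp <- function(t) log(oracle_pcm_probs(d, t)[k + 1])
      curv <- curv - oracle_pcm_probs(d, th)[k + 1] *
        (lp(th + h) - 2 * lp(th) + lp(th - h)) / h^2
    }
    expect_equal(info, curv, tolerance = 1e-4)
  }
  # symmetric item: information peaks at zero
  th <- seq(-3, 3, 0.25)
  info <- pcm_item_information(c(0, 0), th)
  expect_equal(which.max(info), which(th == 0))
  expect_true(all(diff(info[th >= 0]) < 0))
})

test_that("test information is additive over items", {
  bank <- equip_ph_bank()
  full <- test_information(bank, 0)$information
  sub <- test_information(subset_bank(bank, 1:10), 0)$information
  expect_lt(sub, full)
  expect_equal(full,
               sum(vapply(bank$deltas, pcm_item_information, 1, theta = 0)))
})

test_that("EAP scoring returns the prior for empty response patterns and
           respects likelihood monotonicity", {
  model <- pcm_model(equip_ph_bank())
  empty <- eap_score(model, rep(NA_integer_, 19))
  expect_equal(empty$theta, 0, tolerance = 1e-8)
  expect_lte(empty$se, 1)          # grid-discretised prior SD
  expect_equal(empty$se, 1, tolerance = 0.01)
  expect_equal(empty$n_items_used, 0L)

  allmax <- eap_score(model, rep(2L, 19))
  expect_gt(allmax$theta, 1.51)    # beyond the largest threshold

  expect_error(eap_score(model, c(rep(2L, 18), 5L)), "out of range")

  dense <- pcm_model(equip_ph_bank(), quadrature_grid(121))
  expect_equal(eap_score(dense, rep(2L, 19))$theta, allmax$theta,
               tolerance = 1e-3)
})

test_that("EAP is non-decreasing in the total score (Rasch sufficiency)", {
  model <- pcm_model(toy_bank())
  pats <- expand.grid(0:2, 0:2, 0:2)
  th <- apply(pats, 1, function(p) eap_score(model, as.integer(p))$theta)
  tot <- rowSums(pats)
  # sufficiency: patterns with the same total get the same estimate,
  # and the estimate increases with the total
  spread <- tapply(th, tot, function(v) diff(range(v)))
  expect_true(all(spread < 1e-10))
  expect_true(all(diff(tapply(th, tot, mean)) > 0))
})

test_that("EM calibration recovers generating thresholds and increases the
           likelihood monotonically", {
  gb <- scored_bank()
  d <- simulation_design(gb, n_persons = 2000, theta_mean = 0, theta_sd = 1,
                         missing_rate = 0, seed = 11)
  m <- simulate_responses(d)
  model <- fit_pcm(m)
  expect_true(model$converged)
  expect_true(all(diff(model$loglik_trace) > -1e-6))
  est <- unlist(model$bank$deltas)
  tru <- unlist(gb$deltas)
  expect_lt(sqrt(mean((est - tru)^2)), 0.15)

  # balanced dichotomous items centre at zero
  set.seed(5)
  th <- rnorm(4000)
  x <- cbind(as.integer(th + rnorm(4000) > 0), as.integer(th + rnorm(4000) > 0))
  mod2 <- fit_pcm(response_matrix(x, max_cat = 1))
  expect_lt(max(abs(unlist(mod2$bank$deltas))), 0.1)
})

test_that("calibration bias in thresholds shrinks with sample size", {
  gb <- subset_bank(scored_bank(), 1:8)
  bias <- vapply(c(500, 2000), function(n) {
    m <- simulate_responses(simulation_design(gb, n_persons = n,
                                              theta_mean = 0, theta_sd = 1,
                                              missing_rate = 0, seed = 77))
    mean(abs(unlist(fit_pcm(m)$bank$deltas) - unlist(gb$deltas)))
  }, 1)
  expect_lt(bias[2], bias[1])
})

test_that("unobserved categories are merged and logged during calibration", {
  set.seed(8)
  th <- rnorm(400)
  x <- draw_responses(toy_bank(), th)$responses
  x[, 2][x[, 2] == 1L] <- 2L    # category 1 never observed for item b
  model <- fit_pcm(response_matrix(x))
  expect_true("i2" %in% names(model$recode_log) ||
              "b" %in% names(model$recode_log))
  expect_length(model$bank$deltas[[2]], 1L)  # collapsed to dichotomous
})

test_that("marginal reliability grows with bank size and matches conventions", {
  bank <- equip_ph_bank()
  rels <- vapply(c(5, 10, 19), function(k)
    marginal_reliability(subset_bank(bank, 1:k), method = "information"), 1)
  expect_true(all(diff(rels) > 0))
  expect_lt(marginal_reliability(subset_bank(bank, 1:2), method = "information"),
            rels[3])
  # the EAP convention sits slightly above the information convention
  expect_gt(marginal_reliability(bank, n_sim = 5000),
            marginal_reliability(bank, method = "information"))
})

test_that("item fit is calibrated under the generating model", {
  gb <- scored_bank()
  frac <- vapply(1:5, function(s) {
    m <- simulate_responses(simulation_design(gb, n_persons = 400,
                                              theta_mean = 0, theta_sd = 1,
                                              missing_rate = 0, seed = 40 + s))
    fs <- fit_statistics(fit_pcm(m), m)
    mean(fs$item_fit$p < 0.05)
  }, 1)
  expect_lt(mean(frac), 0.15)
  expect_true(all(frac <= 0.25))
})

test_that("imputation respects the model and beats the marginal mode", {
  gb <- scored_bank()
  d <- simulation_design(gb, n_persons = 500, theta_mean = 0, theta_sd = 1.2,
                         missing_rate = 0, seed = 55)
  complete <- simulate_responses(d)
  model <- fit_pcm(complete)
  expect_identical(impute_missing(model, complete)$responses,
                   complete$responses)

  # person at the ceiling imputes at/near the top category
  x1 <- complete$responses[1, , drop = FALSE]
  x1[1, ] <- 2L; x1[1, 5] <- NA_integer_
  imp1 <- impute_missing(model, response_matrix(x1, item_ids = gb$item_ids))
  expect_equal(imp1$responses[1, 5], 2L)

  set.seed(56)
  mask <- matrix(runif(500 * 19) < 0.16, 500, 19)
  x <- complete$responses; x[mask] <- NA_integer_
  imp <- impute_missing(model, response_matrix(x, item_ids = gb$item_ids))
  acc <- mean(imp$responses[mask] == complete$responses[mask])
  marg_mode <- apply(complete$responses, 2, function(v)
    as.integer(names(which.max(table(v)))))
  base <- mean(matrix(marg_mode, 500, 19, byrow = TRUE)[mask] ==
               complete$responses[mask])
  expect_gt(acc, base)
})
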