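test_that("Loevinger coefficients are 1 for a perfect Guttman scale", {
  # items are step functions of a common score: deterministic cumulative scale
  s <- rep(0:6, each = 10)
  x <- cbind(pmin(pmax(s - 1, 0), 2), pmin(pmax(s - 3, 0), 2),
             pmin(s, 4))
  m <- response_matrix(x)
  h <- loevinger_coefficients(m)
  expect_equal(unname(h$item_H), rep(1, 3))
  expect_equal(h$scale_H, 1)
  expect_true(all(h$pair_H[upper.tri(h$pair_H)] == 1))
})

test_that("independent items scale at H near zero", {
  set.seed(4)
  x <- matrix(sample(0:4, 2 * 10000, replace = TRUE), ncol = 2)
  h <- loevinger_coefficients(response_matrix(x))
  expect_lt(abs(h$pair_H[1, 2]), 0.05)
})

test_that("pairwise H matches a brute-force maximal-concordance oracle", {
  x <- cbind(c(0L, 1L, 0L, 1L, 1L), c(1L, 0L, 0L, 1L, 1L))
  h <- loevinger_coefficients(response_matrix(x, max_cat = 1))
  # oracle: build the maximally concordant 2x2 table from the marginals
  n <- 5; p1 <- mean(x[, 1]); p2 <- mean(x[, 2])
  n11 <- min(sum(x[, 1]), sum(x[, 2]))        # pack the high-high cell
  exy_max <- n11 / n
  cov_max <- (exy_max - p1 * p2) * n / (n - 1)
  cov_obs <- cov(x[, 1], x[, 2])
  expect_equal(h$pair_H[1, 2], cov_obs / cov_max)
})

test_that("zero-variance items are reported as undefined, not dropped", {
  x <- cbind(rep(2L, 50), sample(0:2, 50, replace = TRUE),
             sample(0:2, 50, replace = TRUE))
  h <- loevinger_coefficients(response_matrix(x))
  expect_true(is.na(h$item_H[1]))
  expect_equal(h$zero_variance_items, "i1")
  expect_false(is.na(h$item_H[2]))
})

test_that("H coefficients are invariant to item and person order", {
  d <- simulation_design(scored_bank(), n_persons = 300, missing_rate = 0.1,
                         seed = 6)
  m <- simulate_responses(d)
  h1 <- loevinger_coefficients(m)
  perm_items <- rev(seq_len(19)); perm_persons <- sample(300)
  h2 <- loevinger_coefficients(subset_items(m, perm_items, perm_persons))
  expect_equal(h2$scale_H, h1$scale_H)
  expect_equal(h2$item_H[names(h1$item_H)], h1$item_H)
})

test_that("monotone items pass and reversed items fail the restscore check", {
  set.seed(11)
  th <- rnorm(500, 0, 1.2)
  m <- simulate_responses(simulation_design(scored_bank(), n_persons = 500,
                                            theta_mean = 0, theta_sd = 1.2,
                                            missing_rate = 0, seed = 11))
  mono <- check_monotonicity(m)
  expect_equal(sum(mono$items$n_significant), 0L)
  expect_length(mono$flagged_items, 0L)

  x <- m$responses
  x[, 8] <- 2L - x[, 8]
  mono2 <- check_monotonicity(response_matrix(x, item_ids = m$item_ids))
  expect_true("item8" %in% mono2$flagged_items)
  expect_gt(mono2$items$n_violations[8], 0L)
})

test_that("too few persons make an item untestable rather than wrong", {
  m <- simulate_responses(simulation_design(toy_bank(), n_persons = 40,
                                            missing_rate = 0, seed = 2))
  mono <- check_monotonicity(m, minsize = 50)
  expect_true(all(!mono$items$testable))
  expect_length(mono$flagged_items, 0L)
})

test_that("polychoric correlation recovers a known latent correlation", {
  set.seed(3)
  n <- 20000
  z1 <- rnorm(n); z2 <- 0.55 * z1 + sqrt(1 - 0.55^2) * rnorm(n)
  x <- cut(z1, c(-Inf, -0.8, 0.1, 0.9, Inf), labels = FALSE) - 1
  y <- cut(z2, c(-Inf, -0.4, 0.6, Inf), labels = FALSE) - 1
  expect_equal(polychoric_corr(x, y), 0.55, tolerance = 0.02)
})

test_that("parallel analysis retains one component for unidimensional data", {
  hits <- 0L
  for (s in 1:5) {
    m <- simulate_responses(simulation_design(scored_bank(), n_persons = 1000,
                                              theta_mean = 0, theta_sd = 1.2,
                                              missing_rate = 0, seed = 30 + s))
    pa <- parallel_analysis(m, n_reference = 10, method = "pearson",
                            seed = 30 + s)
    hits <- hits + (pa$n_factors_retained == 1L)
  }
  expect_gte(hits, 4L)
})

test_that("parallel analysis finds nothing in pure noise and is
           row-duplication invariant", {
  set.seed(13)
  x <- matrix(sample(0:4, 200 * 10, replace = TRUE), 200, 10)
  pa <- parallel_analysis(response_matrix(x), n_reference = 10,
                          method = "pearson", seed = 13)
  expect_lte(pa$n_factors_retained, 1L)
  # duplicating every person leaves the correlation spectrum unchanged
  pa2 <- parallel_analysis(response_matrix(rbind(x, x)), n_reference = 5,
                           method = "pearson", seed = 13)
  expect_equal(pa2$observed_eigenvalues, pa$observed_eigenvalues,
               tolerance = 1e-10)
})

test_that("mokken screening flags low-H and non-monotone items together", {
  d <- simulation_design(
    scored_bank(), n_persons = 800, theta_mean = 0, theta_sd = 1.3,
    missing_rate = 0,
    pathologies = list(
      list(type = "low_scalability", item_ids = "item4", magnitude = 0.8),
      list(type = "nonmonotone", item_ids = "item9", magnitude = 1)),
    seed = 17)
  m <- simulate_responses(d)
  mk <- mokken_screen(m)
  expect_true(all(c("item4", "item9") %in% mk$flagged_items))
  expect_match(mk$reason[["item4"]], "low_scalability")
})
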