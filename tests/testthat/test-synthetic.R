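test_that("generated category frequencies match the PCM distribution", {
  b <- item_bank("x", list(c(0, 0)))
  d <- simulation_design(b, n_persons = 30000, theta_mean = 0,
                         theta_sd = 1e-9, missing_rate = 0, seed = 9)
  m <- simulate_responses(d)
  freq <- tabulate(m$responses + 1L, 3) / 30000
  se <- sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  # chi-square goodness of fit against the closed form at a fixed theta
  b2 <- item_bank("y", list(c(-1.2, 0.12)))
  d2 <- simulation_design(b2, n_persons = 50000, theta_mean = 0.7,
                          theta_sd = 1e-9, missing_rate = 0, seed = 10)
  m2 <- simulate_responses(d2)
  p_true <- oracle_pcm_probs(c(-1.2, 0.12), 0.7)
  obs <- tabulate(m2$responses + 1L, 3)
  expect_gt(chisq.test(obs, p = p_true)$p.value, 0.01)
})

test_that("missingness is applied at the design rate and seeds reproduce", {
  d <- study_design(seed = 3)
  m <- simulate_responses(d)
  n_cells <- prod(dim(m))
  ci <- qbinom(c(0.005, 0.995), n_cells, 0.16) / n_cells
  expect_gt(missing_fraction(m), ci[1])
  expect_lt(missing_fraction(m), ci[2])
  expect_equal(dim(m), c(267L, 67L))
  m2 <- simulate_responses(d)
  expect_identical(m$responses, m2$responses)
  expect_identical(attr(m, "theta"), attr(m2, "theta"))
})

test_that("local dependency injection copies at the given strength", {
  b <- scored_bank()
  d <- simulation_design(b, n_persons = 400, missing_rate = 0, seed = 5)
  m <- simulate_responses(d)
  same <- inject_local_dependency(m, c("item1", "item2"), 1)
  expect_identical(same$responses[, "item1"], same$responses[, "item2"])
  unchanged <- inject_local_dependency(m, c("item1", "item2"), 0)
  expect_identical(unchanged$responses, m$responses)
  expect_error(inject_local_dependency(m, c("item1", "nope"), 0.5),
               "not found")
})

test_that("dif injection shifts one group's thresholds only", {
  d <- simulation_design(scored_bank(), n_persons = 6000, missing_rate = 0,
                         group_probs = c(service_user = 0.5, carer = 0.5),
                         seed = 21)
  expect_error(inject_dif(d, "nope", 0.5), "not found")
  d0 <- inject_dif(d, "item5", 0)
  m0 <- simulate_responses(d0)
  # zero shift: groups exchangeable for the item
  su <- m0$group == "service_user"
  expect_lt(abs(mean(m0$responses[su, "item5"]) -
                mean(m0$responses[!su, "item5"])), 0.12)
  d1 <- inject_dif(d, "item5", 1.5)
  m1 <- simulate_responses(d1)
  su <- m1$group == "service_user"
  # carers face harder thresholds -> lower expected score at equal theta
  expect_gt(mean(m1$responses[su, "item5"]) -
            mean(m1$responses[!su, "item5"]), 0.2)
})

test_that("retest thetas follow the designed correlation structure", {
  b <- scored_bank()
  d <- simulation_design(b, n_persons = 5000, missing_rate = 0,
                         retest = list(n_retest = 5000, theta_correlation = 1),
                         seed = 8)
  m <- simulate_responses(d)
  r <- simulate_retest(d, m)
  expect_equal(cor(attr(m, "theta"), attr(r, "theta")), 1, tolerance = 1e-12)
  expect_true(all(r$person_ids %in% m$person_ids))

  d2 <- simulation_design(b, n_persons = 5000, missing_rate = 0,
                          retest = list(n_retest = 5000,
                                        theta_correlation = 0.6),
                          seed = 8)
  r2 <- simulate_retest(d2, m)
  expect_lt(abs(cor(attr(m, "theta"), attr(r2, "theta")) - 0.6), 0.05)
  expect_error(
    simulation_design(b, n_persons = 50,
                      retest = list(n_retest = 60, theta_correlation = 0.7)),
    "exceeds")
})
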