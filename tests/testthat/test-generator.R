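test_that("simulation is deterministic given config + seed", {
  cfg <- small_config()
  a <- simulate_dataset(cfg, seed = 7)
  b <- simulate_dataset(cfg, seed = 7)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$eta, b$truth$eta)
  c <- simulate_dataset(cfg, seed = 8)
  expect_false(identical(a$table, c$table))
})

test_that("person baselines match configured distributions", {
  cfg <- generator_config(n_persons = 10000)
  set.seed(1)
  p <- simulate_persons(cfg)
  expect_equal(mean(p$age), 69.18, tolerance = 0.01)
  expect_equal(mean(p$gender == "female"), 0.664, tolerance = 0.03)
  expect_true(all(p$age >= 53 & p$age <= 86))
  expect_true(all(p$physical_functioning >= 0 & p$physical_functioning <= 100))
  # unit-scale random-intercept deviates have SD 1 within MC error
  expect_equal(sd(p$eta_negative_affect), 1, tolerance = 0.02)
})

test_that("AARC variance components follow the ICC algebra", {
  # wp_sd = 0 -> no within-person variance
  cfg <- generator_config(n_persons = 50,
                          aarc = list(gains = list(bp_mean = 15, bp_sd = 2,
                                                   wp_sd = 0),
                                      losses = list(bp_mean = 10, bp_sd = 2,
                                                    wp_sd = 0)))
  set.seed(2)
  a <- simulate_aarc(cfg)
  wp_var <- tapply(a$aarc_gains, a$person_id, var)
  expect_true(all(wp_var < 1e-20))

  # bp_sd^2 = 3 wp_sd^2 -> within share 25%; moment check at 2,000 persons
  cfg <- generator_config(n_persons = 2000)
  set.seed(3)
  a <- simulate_aarc(cfg)
  g <- a$person_id
  msw <- mean(tapply(a$aarc_gains, g, var))
  msb <- var(tapply(a$aarc_gains, g, mean)) - msw / cfg$n_days
  expect_equal(100 * msw / (msw + msb), 25, tolerance = 2)
  msw_l <- mean(tapply(a$aarc_losses, g, var))
  msb_l <- var(tapply(a$aarc_losses, g, mean)) - msw_l / cfg$n_days
  expect_equal(100 * msw_l / (msw_l + msb_l), 23, tolerance = 2)
  expect_lt(attr(a, "clip_rate"), 0.10)
})

test_that("stressor model is calibrated to sparse daily events", {
  cfg <- generator_config(n_persons = 2000)
  set.seed(4)
  s <- simulate_stressors(cfg)
  events <- rowSums(s[, paste0("s", 1:5)])
  expect_gt(mean(events), 0.46)
  expect_lt(mean(events), 0.72)
  expect_true(all(s$stress_severity >= 0 & s$stress_severity <= 25))
  # exposure probability zero -> all indices zero
  cfg0 <- generator_config(n_persons = 20,
                           stressors = list(exposure_prob = 0,
                                            severity_probs = rep(0.2, 5)))
  set.seed(5)
  s0 <- simulate_stressors(cfg0)
  expect_true(all(s0$stress_severity == 0))
})

test_that("missingness keeps every person and the expected row count", {
  cfg <- generator_config()
  set.seed(6)
  grid <- expand.grid(person_id = sprintf("p%03d", 1:152), day_index = 0:9)
  kept <- apply_missingness(grid, 0.833)
  expect_true(all(table(kept$person_id) >= 1))
  expect_equal(nrow(kept), 0.833 * 1520, tolerance = 0.05)
  expect_identical(nrow(apply_missingness(grid, 1)), nrow(grid))
})

test_that("skew-normal residuals are mean-parameterized", {
  set.seed(7)
  eps <- rskewnorm(1e6, mean = 0, sd = 0.45, alpha = 4)
  expect_equal(mean(eps), 0, tolerance = 0.002)
  expect_equal(sd(eps), 0.45, tolerance = 0.002)
  expect_gt(mean(((eps - mean(eps)) / sd(eps))^3), 0.5)  # right-skewed
})

test_that("simulated outcomes respect censoring and reduce to Gaussian", {
  # alpha = 0, no censoring bounds -> plain Gaussian mixed-model data
  cfg <- small_config()
  set.seed(8)
  sim <- simulate_dataset(cfg, seed = 9)
  tp <- true_parameters("vitality", alpha = 0,
                        bounds_raw = c(NA, NA), scale_range = c(-Inf, Inf),
                        outcome_mean = 0, outcome_sd = 1)
  tab <- simulate_outcome(as.data.frame(sim$table), tp,
                          eta = setNames(rep(0, 40),
                                         unique(sim$table$person_id)))
  lat <- attr(tab, "latent")
  expect_equal(sd(lat), sqrt(tp$sigma^2 + var(attr(tab, "latent") - lat)),
               tolerance = 1)  # finite values present
  expect_true(all(attr(tab, "censor_code") == 0))

  # censor codes flag exactly the rows at the bounds
  cc <- sim$truth$censor_codes$vitality
  v <- sim$table$vitality
  expect_true(all(v[cc == -1L] == 1))
  expect_true(all(v[cc == 1L] == 7))
  expect_true(all(v[cc == 0L] > 1 & v[cc == 0L] < 7))
})

test_that("full default run satisfies all table invariants", {
  sim <- simulate_dataset(generator_config(n_persons = 60), seed = 10)
  expect_silent(validate_diary_table(sim$table))
  expect_true(all(diff(order(sim$table$person_id, sim$table$day_index)) == 1))
})
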