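test_that("the sampler recovers Gaussian mixed-model parameters", {
  # alpha = 0, no censoring: a plain two-level Gaussian regression
  cfg <- small_config(n_persons = 50, n_days = 6, seed = 201)
  cfg$outcomes <- list(vitality = true_parameters(
    "vitality", alpha = 0, tau = 0.5, sigma = 0.7,
    bounds_raw = c(NA, NA), outcome_mean = 4, outcome_sd = 0.5))
  sim <- simulate_dataset(cfg, seed = 202)
  fr <- build_model_frame(sim$table, design_spec("vitality",
                                                 bounds_raw = c(NA, NA)))
  expect_true(all(fr$censor == 0L))
  fit <- fit_hierarchical(fr, chains = 2, warmup = 400, iter = 400,
                          seed = 203, check = "none")
  d <- fit$diagnostics
  truth <- sim$truth$outcomes$vitality
  idx <- match(names(truth$beta), d$parameter)
  z <- (d$mean[idx] - truth$beta) / d$sd[idx]
  expect_true(all(abs(z) < 3.5))
  expect_lt(abs(d$mean[d$parameter == "tau"] - truth$tau) /
              d$sd[d$parameter == "tau"], 3.5)
  expect_lt(abs(d$mean[d$parameter == "sigma"] - truth$sigma) /
              d$sd[d$parameter == "sigma"], 3.5)
})

test_that("with no data the posterior reproduces the coefficient prior", {
  # empty outcome vector: the sampler should draw from the priors
  fr <- structure(list(
    y = numeric(0), censor = integer(0),
    X = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("b1", "b2"))),
    person = integer(0), person_ids = "p1",
    scaling = data.frame(), bounds_z = c(-Inf, Inf),
    family = "censored_normal", outcome = "none",
    spec = list(roles = c(b1 = "covariate", b2 = "covariate")),
    n_dropped = 0), class = "model_frame")
  fit <- fit_hierarchical(fr, chains = 2, warmup = 400, iter = 1000,
                          seed = 5, check = "none")
  b <- posterior_draws(fit, c("b1", "b2"))
  expect_equal(mean(b), 0, tolerance = 0.08)
  expect_equal(sd(as.vector(b)), 1, tolerance = 0.08)
})

test_that("fits are reproducible from the seed", {
  fr <- build_model_frame(small_table(), design_spec("vitality"))
  f1 <- fit_hierarchical(fr, chains = 2, warmup = 150, iter = 100,
                         seed = 99, check = "none")
  f2 <- fit_hierarchical(fr, chains = 2, warmup = 150, iter = 100,
                         seed = 99, check = "none")
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_hierarchical(fr, chains = 2, warmup = 150, iter = 100,
                         seed = 100, check = "none")
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the convergence gate names offending parameters", {
  fr <- build_model_frame(small_table(), design_spec("vitality"))
  expect_error(
    fit_hierarchical(fr, chains = 2, warmup = 60, iter = 40, seed = 1,
                     check = "error"),
    "convergence criteria")
})

test_that("variance-components model recovers known ICC structure", {
  # tau = sigma -> 50% within-person share
  set.seed(301)
  J <- 300; n <- 8
  u <- rnorm(J, 0, 1)
  tab <- data.frame(person_id = rep(sprintf("q%03d", 1:J), each = n),
                    value = rep(u, each = n) + rnorm(J * n, 0, 1))
  icc <- variance_components_icc(tab, "value", seed = 302)
  expect_equal(icc$wp_share, 50, tolerance = 2)

  # agreement with the method-of-moments ANOVA estimator on balanced data
  msw <- mean(tapply(tab$value, tab$person_id, var))
  msb <- var(tapply(tab$value, tab$person_id, mean)) - msw / n
  mom <- 100 * msw / (msw + msb)
  expect_equal(icc$wp_share, mom, tolerance = 3)

  # generator defaults: gains calibrated to a 25% within share
  sim <- simulate_dataset(generator_config(n_persons = 400), seed = 303)
  icc_g <- variance_components_icc(sim$table, "aarc_gains", seed = 304)
  expect_equal(icc_g$wp_share, 25, tolerance = 3)
})

test_that("posterior intervals cover the truth at the nominal rate", {
  # 20 replicate recovery fits at reduced size, honest i.i.d. residuals
  hits <- 0; total <- 0
  pars <- c("bp_losses", "wp_stress", "tau", "sigma")
  for (r in 1:20) {
    cfg <- small_config(n_persons = 30, n_days = 5, seed = 400 + r)
    cfg$balance_residuals <- FALSE
    cfg$outcomes <- list(vitality = true_parameters(
      "vitality", alpha = 0, tau = 0.5, sigma = 0.8,
      bounds_raw = c(NA, NA), outcome_mean = 4, outcome_sd = 0.5))
    sim <- simulate_dataset(cfg, seed = 500 + r)
    fr <- build_model_frame(sim$table,
                            design_spec("vitality", bounds_raw = c(NA, NA)))
    fit <- fit_hierarchical(fr, chains = 1, warmup = 250, iter = 250,
                            seed = 600 + r, check = "none")
    truth <- sim$truth$outcomes$vitality
    tv <- c(truth$beta["bp_losses"], truth$beta["wp_stress"],
            tau = truth$tau, sigma = truth$sigma)
    for (k in seq_along(pars)) {
      h <- hdi(posterior_draws(fit, pars[k])[, 1])
      hits <- hits + (tv[k] >= h["low"] && tv[k] <= h["high"])
      total <- total + 1
    }
  }
  coverage <- hits / total
  # binomial(80, 0.95): observed coverage should not fall below ~0.85
  expect_gte(coverage, 0.85)
})
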