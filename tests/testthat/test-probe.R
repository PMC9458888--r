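test_that("reactivity slopes follow the interaction algebra", {
  fit <- cached_fit()
  need <- c("wp_stress", "wp_gains:wp_stress", "wp_losses:wp_stress",
            "wp_gains:wp_losses:wp_stress")
  dr <- posterior_draws(fit, need)

  # cell draws recomputed from raw coefficient draws match to 1e-12
  for (cell in list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))) {
    s <- reactivity_slope(fit, cell[1], cell[2], unit = "one")
    manual <- dr[, 1] + dr[, 2] * cell[1] + dr[, 3] * cell[2] +
      dr[, 4] * cell[1] * cell[2]
    expect_equal(s, manual, tolerance = 1e-12)
  }

  # point-estimate arithmetic on a reference coefficient vector:
  # b_s 0.20, b_gs -0.02, b_ls 0.00, b_gls -0.03
  b <- c(0.20, -0.02, 0.00, -0.03)
  cell <- function(g, l) b[1] + b[2] * g + b[3] * l + b[4] * g * l
  expect_equal(cell(+1, +1), 0.15)
  expect_equal(cell(-1, +1), 0.25)
  # ordering: low-gains / high-losses cell is the largest
  grid <- expand.grid(g = c(-1, 1), l = c(-1, 1))
  vals <- mapply(cell, grid$g, grid$l)
  expect_equal(which.max(vals), which(grid$g == -1 & grid$l == 1))
})

test_that("difference-of-differences equals 4 x the three-way coefficient", {
  fit <- cached_fit()
  sd_draws <- slope_differences(fit, unit = "one")
  b3 <- posterior_draws(fit, "wp_gains:wp_losses:wp_stress")[, 1]
  expect_equal(sd_draws$diff_of_diffs, 4 * b3, tolerance = 1e-12)
  # reference arithmetic: 4 x (-0.03) = -0.12
  expect_equal(4 * (-0.03), -0.12)
  # with column-SD units the identity scales by the two moderator SDs
  sd2 <- slope_differences(fit, unit = "column_sd")
  sc <- diaryreact:::moderator_scale(fit, "column_sd")
  expect_equal(sd2$diff_of_diffs,
               4 * sc[["wp_gains"]] * sc[["wp_losses"]] * b3,
               tolerance = 1e-12)
})

test_that("slope grid summarises each cell of the probe design", {
  fit <- cached_fit()
  sg <- slope_grid(fit)
  expect_equal(nrow(sg), 4)
  expect_true(all(sg$hdi_low <= sg$est & sg$est <= sg$hdi_high))
})

test_that("quadratic curves reduce to known shapes", {
  sim <- simulate_dataset(small_config(), seed = 51)
  fr <- build_model_frame(sim$table,
                          design_spec("vitality", quadratic_stress = TRUE))
  fit <- fit_hierarchical(fr, chains = 2, warmup = 300, iter = 300,
                          seed = 3, check = "none")
  qc <- quadratic_curve(fit, l = 0, stress_grid = c(-1, 0, 1), unit = "one")
  dr <- posterior_draws(fit, c("wp_stress", "wp_stress2", "wp_losses",
                               "wp_losses:wp_stress",
                               "wp_losses:wp_stress2"))
  # at l = 0 the curve is b_s s + b_s2 s^2 per draw
  expect_equal(qc$est[2], 0)
  expect_equal(qc$est[3], mean(dr[, 1] + dr[, 2]), tolerance = 1e-10)
  # curve difference between l = +/-1 at s = 0 equals 2 b_l per draw
  hi <- quadratic_curve(fit, +1, stress_grid = 0, unit = "one")
  lo <- quadratic_curve(fit, -1, stress_grid = 0, unit = "one")
  expect_equal(hi$est - lo$est, 2 * mean(dr[, 3]), tolerance = 1e-10)
  # all quadratic terms zero -> the curve is linear in s
  b <- c(s = 0.4, s2 = 0, l = 0.1, ls = -0.2, ls2 = 0)
  s <- seq(-2, 2, 0.5)
  eta <- b["s"] * s + b["s2"] * s^2 + b["l"] + b["ls"] * s + b["ls2"] * s^2
  expect_equal(diff(eta, differences = 2), rep(0, length(s) - 2))
})

test_that("PSIS-LOO agrees with exact LOO on a tiny conjugate problem", {
  # normal mean with known variance: exact leave-one-out predictive
  # density available in closed form
  set.seed(61)
  n <- 20
  sigma <- 1
  y <- rnorm(n, 0.4, sigma)
  prior_sd <- 2
  post <- function(yv) {
    prec <- length(yv) / sigma^2 + 1 / prior_sd^2
    list(mean = sum(yv) / sigma^2 / prec, sd = sqrt(1 / prec))
  }
  exact <- vapply(1:n, function(i) {
    p <- post(y[-i])
    dnorm(y[i], p$mean, sqrt(p$sd^2 + sigma^2), log = TRUE)
  }, numeric(1))
  # posterior draws from the full-data posterior
  pfull <- post(y)
  S <- 4000
  mu_draws <- rnorm(S, pfull$mean, pfull$sd)
  log_lik <- vapply(1:n, function(i) dnorm(y[i], mu_draws, sigma,
                                           log = TRUE),
                    numeric(S))
  res <- elpd_loo(log_lik)
  expect_equal(res$elpd, sum(exact), tolerance = 0.5)
  expect_equal(res$n, n)
  expect_equal(sum(res$pointwise), res$elpd)

  # matches naive importance sampling when the tails are benign
  naive <- vapply(1:n, function(i) {
    lw <- -log_lik[, i]
    lw <- lw - max(lw)
    diaryreact:::logsumexp(log_lik[, i] + lw) - diaryreact:::logsumexp(lw)
  }, numeric(1))
  expect_lt(max(abs(res$pointwise - naive)), 0.1)

  # loo elpd never beats the in-sample fit
  in_sample <- sum(vapply(1:n, function(i)
    diaryreact:::logsumexp(log_lik[, i]) - log(S), numeric(1)))
  expect_lt(res$elpd, in_sample)
})

test_that("elpd differences are antisymmetric and handle degeneracy", {
  # identical likelihood across draws: elpd equals any draw's log lik
  ll <- matrix(rep(c(-1.2, -0.8, -2), each = 50), nrow = 50)
  res <- elpd_loo(ll)
  expect_equal(res$elpd, sum(ll[1, ]))
  expect_equal(res$se, sqrt(3 * var(ll[1, ])))

  a <- elpd_result(c(-3, -4, -5))
  b <- elpd_result(c(-3.5, -4.5, -4.8))
  d <- elpd_difference(a, b)
  expect_equal(d$difference, b$elpd - a$elpd)
  d_rev <- elpd_difference(b, a)
  expect_equal(d_rev$difference, -d$difference)
  # identical models
  d0 <- elpd_difference(a, a)
  expect_equal(d0$difference, 0)
  expect_equal(d0$se, 0)
  expect_error(elpd_difference(a, elpd_result(c(-1, -2))), "different")
})

test_that("pointwise log likelihood sums match the censored loglik per draw", {
  fit <- cached_fit()
  ll <- pointwise_loglik(fit)
  expect_true(all(is.finite(ll)))
  fr <- fit$frame
  dr <- posterior_draws(fit, fit$parameters)
  p <- ncol(fr$X)
  set.seed(71)
  for (s in sample(nrow(dr), 5)) {
    beta <- dr[s, seq_len(p)]
    u <- dr[s, "tau"] * dr[s, paste0("eta[", fr$person_ids, "]")]
    mu <- as.vector(fr$X %*% beta) + u[fr$person]
    direct <- censored_loglik(fr$y, fr$censor, mu, dr[s, "sigma"], 0,
                              fr$bounds_z)
    expect_equal(sum(ll[s, ]), direct, tolerance = 1e-8)
  }
})
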