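test_that("skew normal with alpha = 0 reduces exactly to the normal", {
  x <- seq(-4, 4, length.out = 20)
  expect_equal(dskewnorm(x, 0.5, 1.3, 0, log = TRUE),
               dnorm(x, 0.5, 1.3, log = TRUE), tolerance = 1e-12)
  expect_equal(pskewnorm(x, 0.5, 1.3, 0), pnorm(x, 0.5, 1.3),
               tolerance = 1e-12)
})

test_that("skew normal density integrates to one and has the stated mean", {
  for (a in c(-3, 1, 4)) {
    expect_equal(integrate(dskewnorm, -Inf, Inf, mean = 0, sd = 1,
                           alpha = a, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
    expect_equal(integrate(function(x) x * dskewnorm(x, 0.7, 1, a),
                           -Inf, Inf, rel.tol = 1e-10)$value, 0.7,
                 tolerance = 1e-6)
  }
})

test_that("skew normal CDF matches quadrature and sampling", {
  # against direct integration of the density
  for (q in c(-1.5, 0, 0.8)) {
    expect_equal(pskewnorm(q, 0, 1, 4),
                 integrate(dskewnorm, -Inf, q, mean = 0, sd = 1, alpha = 4,
                           rel.tol = 1e-11)$value, tolerance = 1e-9)
  }
  # monotone, with correct limits
  qs <- seq(-6, 6, length.out = 200)
  Fv <- pskewnorm(qs, 0, 1, 4)
  expect_true(all(diff(Fv) >= -1e-12))  # monotone up to tail round-off
  expect_equal(pskewnorm(-50, 0, 1, 4), 0, tolerance = 1e-12)
  expect_equal(pskewnorm(50, 0, 1, 4), 1, tolerance = 1e-12)
  # against the empirical CDF of many draws
  set.seed(14)
  x <- rskewnorm(1e6, 0, 1, 4)
  grid <- seq(-2, 3, by = 0.25)
  emp <- ecdf(x)(grid)
  expect_lt(max(abs(emp - pskewnorm(grid, 0, 1, 4))), 1e-3 * 3)
})

test_that("Owen's T matches its closed-form special cases", {
  a <- c(0.1, 0.5, 1)
  expect_equal(owen_t(0, a), atan(a) / (2 * pi), tolerance = 1e-12)
  h <- c(-2, -0.3, 0.4, 1.7)
  expect_equal(owen_t(h, 1), pnorm(h) * (1 - pnorm(h)) / 2, tolerance = 1e-12)
  # sign and symmetry identities
  expect_equal(owen_t(1.1, -2.5), -owen_t(1.1, 2.5), tolerance = 1e-15)
  expect_equal(owen_t(-1.1, 2.5), owen_t(1.1, 2.5), tolerance = 1e-15)
  # |a| > 1 reduction consistency vs numeric integral
  f <- function(h, a) integrate(function(x) exp(-h^2 * (1 + x^2) / 2) /
                                  (1 + x^2), 0, a,
                                rel.tol = 1e-12)$value / (2 * pi)
  expect_equal(owen_t(0.7, 3.2), f(0.7, 3.2), tolerance = 1e-11)
  expect_equal(owen_t(2.1, 7), f(2.1, 7), tolerance = 1e-11)
})

test_that("censored log likelihood composes density and CDF mass", {
  set.seed(2)
  y <- rnorm(50)
  # no censoring: equals the plain log-density sum
  expect_equal(censored_loglik(y, rep(0L, 50), 0.2, 1.1, 4),
               sum(dskewnorm(y, 0.2, 1.1, 4, log = TRUE)))
  # all left-censored, normal family: n * log Phi((L - mu) / sigma)
  n <- 20
  expect_equal(
    censored_loglik(rep(-1, n), rep(-1L, n), 0.3, 0.9, 0,
                    bounds = c(-1, Inf)),
    n * pnorm(-1, 0.3, 0.9, log.p = TRUE))
  # censoring probability matches Monte-Carlo frequency
  set.seed(8)
  draws <- rskewnorm(1e6, 0, 1, 4)
  p_mc <- mean(draws <= -0.8)
  expect_equal(exp(censored_loglik(-0.8, -1L, 0, 1, 4,
                                   bounds = c(-0.8, Inf))),
               p_mc, tolerance = 1e-3 * 5)
  # uncensored value outside the bounds is rejected
  expect_error(censored_loglik(c(-2, 0), c(0L, 0L), 0, 1, 0,
                               bounds = c(-1, Inf)), "outside")
})

test_that("compiled log posterior agrees with the R-side composition", {
  sim <- simulate_dataset(small_config(), seed = 31)
  for (design in c("negative_affect", "vitality")) {
    fr <- build_model_frame(sim$table, design_spec(design))
    skew <- fr$family == "censored_skew_normal"
    p <- ncol(fr$X); J <- length(fr$person_ids)
    set.seed(4)
    params <- list(beta = rnorm(p, 0, 0.2), sigma = 0.7, tau = 0.5,
                   alpha = if (skew) 2 else 0, eta = rnorm(J, 0, 0.5))
    lp <- log_posterior(params, fr)
    mu <- as.vector(fr$X %*% params$beta) + params$tau * params$eta[fr$person]
    ll <- censored_loglik(fr$y, fr$censor, mu, params$sigma, params$alpha,
                          fr$bounds_z)
    prior <- sum(dnorm(params$beta, log = TRUE)) +
      diaryreact:::halft_lpdf_r(params$sigma, 3, 2.5) + log(params$sigma) +
      diaryreact:::halft_lpdf_r(params$tau, 3, 2.5) + log(params$tau) +
      (if (skew) dnorm(params$alpha, 0, 4, log = TRUE) else 0) +
      sum(dnorm(params$eta, log = TRUE))
    expect_equal(lp, ll + prior, tolerance = 1e-8)
  }
})

test_that("skew and normal families give identical posteriors at alpha 0", {
  sim <- simulate_dataset(small_config(), seed = 32)
  fr <- build_model_frame(sim$table, design_spec("vitality"))
  p <- ncol(fr$X); J <- length(fr$person_ids)
  set.seed(5)
  params <- list(beta = rnorm(p, 0, 0.2), sigma = 0.8, tau = 0.4,
                 alpha = 0, eta = rnorm(J, 0, 0.5))
  lp_normal <- log_posterior(params, fr)
  fr_skew <- fr
  fr_skew$family <- "censored_skew_normal"
  lp_skew <- log_posterior(params, fr_skew)
  # identical up to the alpha prior constant at alpha = 0
  expect_equal(lp_skew - dnorm(0, 0, 4, log = TRUE), lp_normal,
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  sim <- simulate_dataset(small_config(n_persons = 12, n_days = 4),
                          seed = 33)
  fr <- build_model_frame(sim$table, design_spec("negative_affect"))
  p <- ncol(fr$X); J <- length(fr$person_ids)
  set.seed(6)
  theta <- rnorm(p + 3 + J, 0, 0.3)
  f <- function(th) {
    diaryreact:::cpp_lp_grad(th, fr$X, fr$y, as.integer(fr$censor),
                             as.integer(fr$person - 1L), J,
                             fr$bounds_z[1], fr$bounds_z[2], TRUE,
                             1, 3, 2.5, 4, TRUE)
  }
  g <- f(theta)$grad
  num <- vapply(seq_along(theta), function(i) {
    h <- 1e-5
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (f(tp)$lp - f(tm)$lp) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - g) / (1 + abs(num))), 1e-6)
})

test_that("censoring bounds at infinity recover the uncensored model", {
  sim <- simulate_dataset(small_config(), seed = 34)
  fr <- build_model_frame(sim$table, design_spec("vitality"))
  fr_open <- fr
  fr_open$bounds_z <- c(-Inf, Inf)
  fr_open$censor <- rep(0L, length(fr$y))
  p <- ncol(fr$X); J <- length(fr$person_ids)
  params <- list(beta = rep(0.1, p), sigma = 0.7, tau = 0.5, alpha = 0,
                 eta = rep(0.1, J))
  ll_open <- censored_loglik(fr$y, fr_open$censor, 0.1, 0.7, 0,
                             c(-Inf, Inf))
  expect_equal(ll_open, sum(dnorm(fr$y, 0.1, 0.7, log = TRUE)))
  expect_true(is.finite(log_posterior(params, fr_open)))
})
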