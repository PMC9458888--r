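# No-U-Turn sampler with dual-averaging step-size adaptation and a
# diagonal mass matrix estimated during warmup. `lp_grad` is a function
# theta -> list(lp, grad). Used by fit_hierarchical() and the
# variance-components model; kept generic and dependency-free.

nuts_chain <- function(lp_grad, init, n_warmup, n_iter,
                       adapt_delta = 0.8, max_treedepth = 10) {
  d <- length(init)
  inv_mass <- rep(1, d)
  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initial value")

  leapfrog <- function(th, r, gr, eps) {
    r <- r + 0.5 * eps * gr$grad
    th <- th + eps * (inv_mass * r)
    gr <- lp_grad(th)
    r <- r + 0.5 * eps * gr$grad
    list(theta = th, r = r, gr = gr)
  }
  joint <- function(gr, r) gr$lp - 0.5 * sum(r^2 * inv_mass)

  find_eps <- function(theta, gr) {
    eps <- 0.1
    r <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- joint(gr, r)
    st <- leapfrog(theta, r, gr, eps)
    dh <- if (is.finite(st$gr$lp)) joint(st$gr, st$r) - h0 else -Inf
    a <- if (dh > log(0.5)) 1 else -1
    for (k in 1:50) {
      eps <- eps * 2^a
      st <- leapfrog(theta, r, gr, eps)
      dh <- if (is.finite(st$gr$lp)) joint(st$gr, st$r) - h0 else -Inf
      if (a == 1 && dh <= log(0.5)) break
      if (a == -1 && dh > log(0.5)) break
    }
    eps
  }

  divergences <- 0L
  max_depth_hits <- 0L

  build_tree <- function(th, r, gr, logu, v, j, eps, h0) {
    if (j == 0L) {
      st <- leapfrog(th, r, gr, v * eps)
      jt <- if (is.finite(st$gr$lp)) joint(st$gr, st$r) else -Inf
      div <- (jt - h0) < -1000
      if (div) divergences <<- divergences + 1L
      list(minus = st, plus = st, prop = st,
           n = as.integer(logu <= jt), s = !div,
           alpha = min(1, exp(min(0, jt - h0))), nalpha = 1)
    } else {
      t1 <- build_tree(th, r, gr, logu, v, j - 1L, eps, h0)
      if (!t1$s) return(t1)
      if (v == -1) {
        t2 <- build_tree(t1$minus$theta, t1$minus$r, t1$minus$gr,
                         logu, v, j - 1L, eps, h0)
        t1$minus <- t2$minus
      } else {
        t2 <- build_tree(t1$plus$theta, t1$plus$r, t1$plus$gr,
                         logu, v, j - 1L, eps, h0)
        t1$plus <- t2$plus
      }
      ntot <- t1$n + t2$n
      if (t2$n > 0 && stats::runif(1) < t2$n / max(ntot, 1)) t1$prop <- t2$prop
      dth <- t1$plus$theta - t1$minus$theta
      s <- t2$s &&
        sum(dth * (inv_mass * t1$minus$r)) >= 0 &&
        sum(dth * (inv_mass * t1$plus$r)) >= 0
      list(minus = t1$minus, plus = t1$plus, prop = t1$prop,
           n = ntot, s = s,
           alpha = t1$alpha + t2$alpha, nalpha = t1$nalpha + t2$nalpha)
    }
  }

  # dual-averaging state
  eps <- find_eps(theta, cur)
  da <- list(mu = log(10 * eps), bar = 1, h = 0, count = 0,
             gamma = 0.05, t0 = 10, kappa = 0.75)
  da_update <- function(da, accept) {
    da$count <- da$count + 1
    w <- 1 / (da$count + da$t0)
    da$h <- (1 - w) * da$h + w * (adapt_delta - accept)
    log_eps <- da$mu - sqrt(da$count) / da$gamma * da$h
    wb <- da$count^(-da$kappa)
    da$bar <- exp((1 - wb) * log(da$bar) + wb * log_eps)
    list(da = da, eps = exp(log_eps))
  }

  # warmup schedule: step-size-only buffers around variance-estimation
  # windows, with the metric updated at window ends (Stan-like, simplified)
  w1 <- max(5L, floor(0.15 * n_warmup))
  w3 <- max(5L, floor(0.10 * n_warmup))
  metric_ends <- unique(pmax(w1 + 1L,
    floor(c(0.45, 0.75) * n_warmup)))
  metric_ends <- metric_ends[metric_ends < n_warmup - w3]
  win_start <- w1 + 1L
  acc <- list(m = numeric(d), s = numeric(d), k = 0L)

  draws <- matrix(NA_real_, n_iter, d)
  n_total <- n_warmup + n_iter
  for (it in seq_len(n_total)) {
    r0 <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- joint(cur, r0)
    logu <- h0 + log(stats::runif(1))
    minus <- list(theta = theta, r = r0, gr = cur)
    plus <- minus
    prop <- list(theta = theta, gr = cur)
    j <- 0L; n <- 1L; s <- TRUE
    alpha_stat <- 1; nalpha_stat <- 1
    while (s) {
      v <- sample(c(-1, 1), 1)
      if (v == -1) {
        t <- build_tree(minus$theta, minus$r, minus$gr, logu, v, j, eps, h0)
        minus <- t$minus
      } else {
        t <- build_tree(plus$theta, plus$r, plus$gr, logu, v, j, eps, h0)
        plus <- t$plus
      }
      if (t$s && t$n > 0 && stats::runif(1) < min(1, t$n / n)) {
        prop <- t$prop
      }
      n <- n + t$n
      dth <- plus$theta - minus$theta
      s <- t$s &&
        sum(dth * (inv_mass * minus$r)) >= 0 &&
        sum(dth * (inv_mass * plus$r)) >= 0
      alpha_stat <- t$alpha; nalpha_stat <- t$nalpha
      j <- j + 1L
      if (j >= max_treedepth) {
        if (it > n_warmup) max_depth_hits <- max_depth_hits + 1L
        break
      }
    }
    theta <- prop$theta
    cur <- prop$gr

    if (it <= n_warmup) {
      upd <- da_update(da, alpha_stat / nalpha_stat)
      da <- upd$da
      eps <- upd$eps
      if (it >= win_start && it <= max(metric_ends, 0L)) {
        # Welford accumulation for the variance estimate
        acc$k <- acc$k + 1L
        dlt <- theta - acc$m
        acc$m <- acc$m + dlt / acc$k
        acc$s <- acc$s + dlt * (theta - acc$m)
      }
      if (it %in% metric_ends && acc$k > 4L) {
        v_est <- acc$s / (acc$k - 1)
        inv_mass <- v_est * acc$k / (acc$k + 5) + 1e-3 * 5 / (acc$k + 5)
        acc <- list(m = numeric(d), s = numeric(d), k = 0L)
        eps <- find_eps(theta, cur)
        da <- list(mu = log(10 * eps), bar = 1, h = 0, count = 0,
                   gamma = 0.05, t0 = 10, kappa = 0.75)
      }
      if (it == n_warmup) eps <- da$bar
    } else {
      draws[it - n_warmup, ] <- theta
    }
  }
  list(draws = draws, eps = eps, inv_mass = inv_mass,
       divergences = divergences, max_depth_hits = max_depth_hits)
}

# Run several chains sequentially with derived sub-seeds; init_fun(chain)
# must return an initial unconstrained vector.
nuts_sample <- function(lp_grad, init_fun, chains, n_warmup, n_iter, seed,
                        adapt_delta = 0.8, max_treedepth = 10) {
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)
  out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    out[[ch]] <- nuts_chain(lp_grad, init_fun(ch), n_warmup, n_iter,
                            adapt_delta, max_treedepth)
  }
  out
}
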