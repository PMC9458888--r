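#' Within-person variance share from a variance-components model
#'
#' Fits the intercept-only two-level model (random person intercept, no
#' predictors) to a long-form variable and reports the posterior mean of
#' the within-person variance share `100 * sigma^2 / (sigma^2 + tau^2)`,
#' the complement of the intraclass correlation, in percent.
#'
#' The variable is standardized internally (the share is invariant to
#' affine rescaling) and the Gaussian random intercepts are integrated
#' out analytically, so the sampler only explores `(mu, log sigma,
#' log tau)` using per-person sufficient statistics; this keeps the fit
#' fast even for thousands of persons. Priors match the main model:
#' Normal(0, 1) on the intercept and half-t(3, 2.5) on both SDs.
#'
#' @param table long-form data frame with `person_id` and the outcome
#'   column (e.g. a [diary_table()]).
#' @param outcome name of the column to decompose.
#' @param chains,warmup,iter,seed sampler settings.
#' @return list of class `icc_fit`: `wp_share` (posterior mean, %),
#'   `draws` (data frame of mu/sigma/tau/share draws), and diagnostics.
#' @export
variance_components_icc <- function(table, outcome, chains = 2,
                                    warmup = 400, iter = 400, seed = 1) {
  x <- table[[outcome]]
  pid <- table$person_id[!is.na(x)]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no data for outcome '", outcome, "'")
  if (max(table(pid)) < 2) {
    stop("need repeated occasions for at least one person", call. = FALSE)
  }
  z <- standardize_long(x)$z
  nj <- as.vector(table(pid)[unique(pid)])
  ybar <- as.vector(tapply(z, factor(pid, levels = unique(pid)), mean))
  ss <- as.vector(tapply(z, factor(pid, levels = unique(pid)),
                         function(v) sum((v - mean(v))^2)))
  pr <- dr_priors()
  lp_grad <- function(theta) {
    mu <- theta[1]; s2 <- exp(2 * theta[2]); t2 <- exp(2 * theta[3])
    v <- s2 + nj * t2
    e <- ybar - mu
    lp <- sum(-0.5 * ((nj - 1) * log(s2) + log(v) + nj * log(2 * pi)) -
                ss / (2 * s2) - nj * e^2 / (2 * v))
    dmu <- sum(nj * e / v)
    ds2 <- sum(-0.5 * ((nj - 1) / s2 + 1 / v) + ss / (2 * s2^2) +
                 nj * e^2 / (2 * v^2))
    dt2 <- sum(-0.5 * nj / v + nj^2 * e^2 / (2 * v^2))
    sigma <- sqrt(s2); tau <- sqrt(t2)
    lp <- lp + stats::dnorm(mu, 0, pr$beta_sd, log = TRUE) +
      halft_lpdf_r(sigma, pr$sd_df, pr$sd_scale) + theta[2] +
      halft_lpdf_r(tau, pr$sd_df, pr$sd_scale) + theta[3]
    g <- c(dmu - mu / pr$beta_sd^2,
           ds2 * 2 * s2 + halft_dlpdf_r(sigma, pr$sd_df, pr$sd_scale) * sigma + 1,
           dt2 * 2 * t2 + halft_dlpdf_r(tau, pr$sd_df, pr$sd_scale) * tau + 1)
    list(lp = lp, grad = g)
  }
  init_fun <- function(ch) c(stats::rnorm(1, 0, 0.1),
                             log(0.7) + stats::rnorm(1, 0, 0.1),
                             log(0.7) + stats::rnorm(1, 0, 0.1))
  res <- nuts_sample(lp_grad, init_fun, chains, warmup, iter, seed)
  draws <- do.call(rbind, lapply(res, function(r) r$draws))
  out <- data.frame(mu = draws[, 1], sigma = exp(draws[, 2]),
                    tau = exp(draws[, 3]))
  out$wp_share <- 100 * out$sigma^2 / (out$sigma^2 + out$tau^2)
  arr <- array(NA_real_, c(iter, chains, 4),
               dimnames = list(NULL, NULL, c("mu", "sigma", "tau",
                                             "wp_share")))
  for (ch in seq_len(chains)) {
    arr[, ch, 1] <- res[[ch]]$draws[, 1]
    arr[, ch, 2] <- exp(res[[ch]]$draws[, 2])
    arr[, ch, 3] <- exp(res[[ch]]$draws[, 3])
    arr[, ch, 4] <- 100 * arr[, ch, 2]^2 / (arr[, ch, 2]^2 + arr[, ch, 3]^2)
  }
  structure(list(wp_share = mean(out$wp_share), draws = out,
                 diagnostics = diagnostics_table(arr)),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("<icc_fit> within-person variance share: %.1f%%\n", x$wp_share))
  invisible(x)
}

# half-t prior helpers shared with the compiled path
halft_lpdf_r <- function(x, df, s) {
  log(2) + lgamma((df + 1) / 2) - lgamma(df / 2) -
    0.5 * log(df * pi * s^2) - (df + 1) / 2 * log1p(x^2 / (df * s^2))
}
halft_dlpdf_r <- function(x, df, s) -(df + 1) * x / (df * s^2 + x^2)
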