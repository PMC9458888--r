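# Approximate leave-one-out expected log predictive density (elpd) via
# Pareto-smoothed importance sampling, with the generalized-Pareto tail
# fit of Zhang & Stephens (2009).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# profile-likelihood GPD fit to exceedances x > 0; returns shape k and
# scale sigma (location fixed at 0)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / prior_bs / x[ceiling(n / 4 + 0.5)]
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  ls <- n * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(ls - ls[j])), numeric(1))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  sigma <- k / b
  # weakly informative shrinkage of the shape toward 0.5
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

# smooth the largest importance weights of one observation; lw on the
# log scale, already max-normalized
psis_smooth <- function(lw) {
  s <- length(lw)
  m <- min(ceiling(0.2 * s), s - 1)
  if (m < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(s - m + 1):s]
  cutoff <- lw[ord[s - m]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exc <= 0) || length(unique(exc)) < 2) {
    return(list(lw = lw, k = NA_real_))
  }
  fit <- gpd_fit(exc[exc > 0])
  k <- fit$k
  # replace tail by expected order statistics of the fitted GPD
  p <- (seq_len(m) - 0.5) / m
  q <- if (abs(k) < 1e-12) -fit$sigma * log1p(-p) else
    fit$sigma * ((1 - p)^(-k) - 1) / k
  smoothed <- log(exp(cutoff) + q)
  lw[tail_ids[order(exc)]] <- smoothed[order(order(exc))]
  lw <- pmin(lw, 0)  # truncate at the raw maximum (weights normalized to max 0)
  list(lw = lw, k = k)
}

#' PSIS leave-one-out expected log predictive density
#'
#' Estimates the leave-one-out elpd from a draws x observations
#' log-likelihood matrix: per observation, importance ratios
#' `1 / lik` are tail-smoothed by a generalized-Pareto fit to the
#' largest 20% of weights, and the pointwise elpd is the log of the
#' smoothed-weight average of the likelihood. The Pareto shape
#' diagnostic `k` is reported per observation; values above 0.7 flag
#' unreliable smoothing.
#'
#' @param log_lik draws x observations matrix of pointwise
#'   log-likelihood values (finite).
#' @return list of class `elpd_result`: `elpd`, `se`, `pointwise`,
#'   `pareto_k`, `n`.
#' @export
elpd_loo <- function(log_lik) {
  if (!all(is.finite(log_lik))) stop("non-finite log-likelihood entries",
                                     call. = FALSE)
  S <- nrow(log_lik); n <- ncol(log_lik)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    sm <- psis_smooth(lw)
    pointwise[i] <- logsumexp(ll + sm$lw) - logsumexp(sm$lw)
    pareto_k[i] <- sm$k
  }
  bad <- sum(!is.na(pareto_k) & pareto_k > 0.7)
  if (bad > 0) {
    warning(sprintf("%d observation(s) with Pareto k > 0.7; elpd may be unreliable",
                    bad), call. = FALSE)
  }
  structure(list(elpd = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k, n = n),
            class = "elpd_result")
}

#' Build an elpd result from precomputed pointwise values
#'
#' @param pointwise numeric vector of per-observation elpd contributions.
#' @return `elpd_result` (with `NA` Pareto diagnostics).
#' @export
elpd_result <- function(pointwise) {
  n <- length(pointwise)
  structure(list(elpd = sum(pointwise),
                 se = if (n > 1) sqrt(n * stats::var(pointwise)) else NA_real_,
                 pointwise = pointwise,
                 pareto_k = rep(NA_real_, n), n = n),
            class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  cat(sprintf("<elpd_result> elpd = %.1f (SE %.1f), n = %d\n",
              x$elpd, x$se, x$n))
  invisible(x)
}

#' Difference in elpd between two models
#'
#' Oriented as challenger minus reference: positive values favour the
#' challenger. The SE uses the pointwise differences,
#' `sqrt(n * var(pointwise_b - pointwise_a))`.
#'
#' @param reference,challenger `elpd_result` objects (or numeric
#'   pointwise vectors) computed on the same observations.
#' @return list `difference`, `se`, `pointwise`.
#' @export
elpd_difference <- function(reference, challenger) {
  pa <- if (inherits(reference, "elpd_result")) reference$pointwise else reference
  pb <- if (inherits(challenger, "elpd_result")) challenger$pointwise else challenger
  if (length(pa) != length(pb)) {
    stop("models were evaluated on different numbers of observations",
         call. = FALSE)
  }
  d <- pb - pa
  n <- length(d)
  list(difference = sum(d),
       se = if (n > 1) sqrt(n * stats::var(d)) else NA_real_,
       pointwise = d)
}
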