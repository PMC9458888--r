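# Convergence diagnostics: split R-hat and bulk/tail effective sample
# size on rank-normalized draws (the now-standard formulation). Input is
# an iterations x chains matrix.

split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(x) {
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 3 || stats::var(as.vector(x)) == 0) return(NA_real_)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  w <- mean(s2)
  b <- n * stats::var(mu)
  if (w == 0) return(NA_real_)
  sqrt((w * (n - 1) / n + b / n) / w)
}

#' Split R-hat of a single parameter
#'
#' Maximum of the rank-normalized split R-hat computed on the draws and
#' on their folded (absolute-deviation-from-median) transform, so both
#' location and scale disagreements between chains are detected.
#'
#' @param x iterations x chains matrix of posterior draws.
#' @return scalar R-hat (1 = perfect mixing).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  bulk <- rhat_basic(rank_normalize(x))
  folded <- rhat_basic(rank_normalize(abs(x - stats::median(x))))
  max(bulk, folded)
}

# combined-chain ESS via Geyer's initial monotone positive sequence;
# x must already be split into half chains
ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 3) return(NA_real_)
  s2 <- apply(x, 2, stats::var)
  if (any(s2 == 0) || stats::var(as.vector(x)) == 0) return(NA_real_)
  w <- mean(s2)
  var_plus <- w * (n - 1) / n + (if (m > 1) stats::var(colMeans(x)) else 0)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  # per-chain autocovariances via FFT
  acov <- sapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    nfft <- stats::nextn(2 * n)
    f <- stats::fft(c(v, rep(0, nfft - n)))
    a <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:n] / nfft
    a / a[1] * s2[j] * (n - 1) / n
  })
  if (is.null(dim(acov))) acov <- matrix(acov, ncol = m)
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  if (anyNA(rho)) return(NA_real_)
  # Geyer: sum consecutive autocorrelation pairs while positive, then
  # enforce monotone decrease
  k <- 1
  pair_sums <- c()
  while (k + 1 <= n) {
    p <- rho[k] + rho[k + 1]
    if (p < 0) break
    pair_sums <- c(pair_sums, p)
    k <- k + 2
  }
  if (length(pair_sums) > 0) pair_sums <- cummin(pair_sums)
  tau_hat <- -1 + 2 * sum(pair_sums)
  tau_hat <- max(tau_hat, 1 / log10(n * m + 10))
  min(n * m / tau_hat, n * m * log10(n * m))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains; measures sampling efficiency
#' for posterior-centre summaries such as the mean and median.
#'
#' @inheritParams split_rhat
#' @return scalar ESS.
#' @export
ess_bulk <- function(x) {
  ess_basic(rank_normalize(split_chains(as.matrix(x))))
}

#' Tail effective sample size
#'
#' Minimum ESS of the 5% and 95% quantile-indicator transforms; measures
#' efficiency for interval endpoints such as HDI bounds.
#'
#' @inheritParams split_rhat
#' @return scalar ESS.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  e <- vapply(q, function(qq) {
    ind <- matrix(as.numeric(x <= qq), nrow(x), ncol(x))
    if (stats::var(as.vector(ind)) == 0) return(NA_real_)
    ess_basic(split_chains(ind))
  }, numeric(1))
  if (all(is.na(e))) NA_real_ else min(e, na.rm = TRUE)
}

# diagnostics table for an iterations x chains x params array
diagnostics_table <- function(draws) {
  pars <- dimnames(draws)[[3]]
  out <- data.frame(
    parameter = pars,
    mean = apply(draws, 3, mean),
    sd = apply(draws, 3, stats::sd),
    rhat = apply(draws, 3, split_rhat),
    ess_bulk = apply(draws, 3, ess_bulk),
    ess_tail = apply(draws, 3, ess_tail),
    row.names = NULL)
  out
}
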