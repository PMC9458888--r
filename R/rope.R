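#' Highest density interval of posterior draws
#'
#' Shortest contiguous interval containing the requested posterior mass:
#' the draws are sorted and every window of `ceiling(mass * n)`
#' consecutive order statistics is examined; the narrowest one is
#' returned. If the empirical density inside the chosen interval dips
#' below 1% of its maximum the distribution may be multimodal and a
#' single interval is a poor summary; a warning is issued.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param mass interval probability mass (default 0.95).
#' @return named numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HDI", call. = FALSE)
  stopifnot(mass > 0, mass <= 1)
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(low = x[1], high = x[n]))
  widths <- x[(k):n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  out <- c(low = x[i], high = x[i + k - 1])
  # crude multimodality screen on the interval's interior density; the
  # 1% threshold avoids false alarms on strongly skewed unimodal samples
  if (out[2] > out[1]) {
    d <- stats::density(draws, from = out[1], to = out[2], n = 128)
    if (min(d$y) < 0.01 * max(d$y)) {
      warning("density dips inside the HDI; the posterior may be multimodal",
              call. = FALSE)
    }
  }
  out
}

#' ROPE half-width specification
#'
#' @param half_width region of practical equivalence half-width; the
#'   conventional width for standardized effects is 0.05, with 0.025 as
#'   a less conservative variant used for interaction terms.
#' @return list of class `rope_spec`.
#' @export
rope_spec <- function(half_width = 0.05) {
  stopifnot(half_width > 0)
  structure(list(half_width = half_width), class = "rope_spec")
}

#' Dual ROPE + HDI categorical decision for one coefficient
#'
#' Compares the 95% HDI of the posterior draws against the region of
#' practical equivalence `[-w, w]`: the alternative hypothesis is
#' supported when the HDI falls entirely outside the ROPE, the null when
#' it falls entirely inside, and the verdict is undecided otherwise.
#' Also reports the empirical proportions of draws below / within /
#' above the ROPE, the probability of a meaningful effect
#' (`p_meaningful`: mass beyond the ROPE on the side of the posterior
#' median) and of a null effect (`p_null`: mass inside the ROPE).
#'
#' @param draws numeric vector of posterior draws.
#' @param rope a [rope_spec()] (or numeric half-width).
#' @param mass HDI mass.
#' @return list of class `rope_decision`.
#' @export
rope_classify <- function(draws, rope = rope_spec(0.05), mass = 0.95) {
  if (is.numeric(rope)) rope <- rope_spec(rope)
  w <- rope$half_width
  h <- hdi(draws, mass)
  below <- mean(draws < -w)
  above <- mean(draws > w)
  within <- 1 - below - above
  verdict <- if (h["low"] > w || h["high"] < -w) {
    "supports_alternative"
  } else if (h["low"] >= -w && h["high"] <= w) {
    "supports_null"
  } else {
    "undecided"
  }
  med <- stats::median(draws)
  p_meaningful <- if (med >= 0) above else below
  structure(list(hdi_low = unname(h["low"]), hdi_high = unname(h["high"]),
                 below = below, within = within, above = above,
                 verdict = verdict, p_meaningful = p_meaningful,
                 p_null = within, direction = sign(med),
                 half_width = w, mass = mass),
            class = "rope_decision")
}

#' @export
print.rope_decision <- function(x, ...) {
  cat(sprintf(paste0("<rope_decision> ROPE +/-%.3g: HDI [%.3f, %.3f]; ",
                     "below/within/above = %.2f/%.2f/%.2f; %s ",
                     "(P_meaningful = %.2f, P_null = %.2f)\n"),
              x$half_width, x$hdi_low, x$hdi_high, x$below, x$within,
              x$above, x$verdict, x$p_meaningful, x$p_null))
  invisible(x)
}

#' Coefficient summary table with dual-ROPE columns
#'
#' One row per coefficient (plus the random-intercept SD): posterior
#' mean (`est`), posterior SD (`error`), 95% HDI bounds, and
#' below/within/above ROPE proportions. Mirroring the reporting
#' convention for this design, ROPE proportions are filled only for the
#' substantive coefficients: BP/WP main effects at the conventional
#' half-width, interaction terms at both half-widths; covariate rows are
#' left blank. Proportions are computed on the full pooled draws and
#' only rounded at printing.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param rope_widths length-2 numeric: conventional and relaxed ROPE
#'   half-widths.
#' @param coefficients subset of coefficients (default: all, in design
#'   order, plus `tau`).
#' @param mass HDI mass.
#' @return data frame of class `rope_summary`.
#' @export
summary_table <- function(fit, rope_widths = c(0.05, 0.025),
                          coefficients = NULL, mass = 0.95) {
  spec <- fit$frame$spec
  coefs <- coefficients %||% c(colnames(fit$frame$X), "tau")
  unknown <- setdiff(coefs, c(colnames(fit$frame$X), "tau", "sigma", "alpha"))
  if (length(unknown) > 0) {
    stop("unknown coefficients: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dr <- posterior_draws(fit, coefs)
  rows <- lapply(coefs, function(nm) {
    x <- dr[, nm]
    h <- hdi(x, mass)
    role <- if (nm %in% names(spec$roles)) spec$roles[[nm]] else "variance"
    row <- data.frame(predictor = nm, role = role,
                      est = mean(x), error = stats::sd(x),
                      hdi_low = unname(h["low"]), hdi_high = unname(h["high"]))
    for (i in seq_along(rope_widths)) {
      suffix <- gsub("^0\\.", "", format(rope_widths[i]))
      use <- (role %in% c("bp", "wp") && i == 1L) || role == "interaction"
      if (use) {
        rc <- rope_classify(x, rope_widths[i], mass)
        vals <- c(rc$below, rc$within, rc$above)
      } else {
        vals <- rep(NA_real_, 3)
      }
      row[[paste0("below_", suffix)]] <- vals[1]
      row[[paste0("within_", suffix)]] <- vals[2]
      row[[paste0("above_", suffix)]] <- vals[3]
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rope_summary", "data.frame")
  attr(out, "rope_widths") <- rope_widths
  out
}

#' @export
print.rope_summary <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Export posterior densities with ROPE bounds for plotting
#'
#' Tidy "slope-on-a-ROPE" data: a kernel density estimate of each
#' coefficient's pooled posterior plus the ROPE half-widths, one row per
#' grid point, suitable for plotting posterior distributions against the
#' equivalence region.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param coefficients coefficient names.
#' @param rope_widths ROPE half-widths recorded alongside.
#' @param n_grid density grid size.
#' @return data frame `coefficient, value, density, rope_05, rope_025`.
#' @export
rope_plot_data <- function(fit, coefficients,
                           rope_widths = c(0.05, 0.025), n_grid = 256) {
  dr <- posterior_draws(fit, coefficients)
  out <- lapply(coefficients, function(nm) {
    d <- stats::density(dr[, nm], n = n_grid)
    data.frame(coefficient = nm, value = d$x, density = d$y,
               rope_conventional = rope_widths[1],
               rope_relaxed = rope_widths[2])
  })
  do.call(rbind, out)
}
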