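#' Posterior draws of the stress-reactivity slope at moderator levels
#'
#' The reactivity slope is the within-person stress-severity coefficient
#' evaluated at chosen levels of WP AARC-gains (`g`) and WP AARC-losses
#' (`l`): per posterior draw,
#' `slope = b_s + b_gs * g + b_ls * l + b_gls * g * l`.
#' Levels are given in SD units; by default one unit means one SD of the
#' corresponding WP design column (which is below 1 because the WP
#' deviations of a long-form-standardized variable carry only part of
#' its variance). Set `unit = "one"` to interpret levels directly on the
#' standardized-variable scale.
#'
#' @param fit a [fit_hierarchical()] result for a design containing the
#'   three-way WP interaction.
#' @param g,l moderator levels in SD units (scalars).
#' @param unit `"column_sd"` (default) or `"one"`.
#' @return numeric vector of slope draws.
#' @export
reactivity_slope <- function(fit, g, l, unit = c("column_sd", "one")) {
  unit <- match.arg(unit)
  need <- c("wp_stress", "wp_gains:wp_stress", "wp_losses:wp_stress",
            "wp_gains:wp_losses:wp_stress")
  if (!all(need %in% colnames(fit$frame$X))) {
    stop("fit does not contain the WP stress interaction terms",
         call. = FALSE)
  }
  s <- moderator_scale(fit, unit)
  dr <- posterior_draws(fit, need)
  gg <- g * s["wp_gains"]; ll <- l * s["wp_losses"]
  dr[, "wp_stress"] + dr[, "wp_gains:wp_stress"] * gg +
    dr[, "wp_losses:wp_stress"] * ll +
    dr[, "wp_gains:wp_losses:wp_stress"] * gg * ll
}

moderator_scale <- function(fit, unit) {
  if (unit == "one") {
    c(wp_gains = 1, wp_losses = 1, wp_stress = 1)
  } else {
    c(wp_gains = stats::sd(fit$frame$X[, "wp_gains"]),
      wp_losses = stats::sd(fit$frame$X[, "wp_losses"]),
      wp_stress = stats::sd(fit$frame$X[, "wp_stress"]))
  }
}

#' Reactivity-slope differences and the difference-of-differences
#'
#' Probes the three-way WP interaction on the +/-1 SD grid: for each
#' level of WP AARC-losses, the difference between the reactivity slopes
#' at high and low WP AARC-gains; and the difference between those two
#' differences, which equals `4 * g * l * b_gls` per draw (with `g`,
#' `l` the SD units used) and is the effect-size summary of the
#' three-way interaction.
#'
#' @inheritParams reactivity_slope
#' @return data frame of draws: `diff_low_losses`, `diff_high_losses`
#'   (high-gains minus low-gains slope at losses -1 / +1 SD) and
#'   `diff_of_diffs`.
#' @export
slope_differences <- function(fit, unit = c("column_sd", "one")) {
  unit <- match.arg(unit)
  ll <- reactivity_slope(fit, -1, -1, unit)
  hl <- reactivity_slope(fit, +1, -1, unit)
  lh <- reactivity_slope(fit, -1, +1, unit)
  hh <- reactivity_slope(fit, +1, +1, unit)
  d_low <- hl - ll    # high - low gains, at low losses
  d_high <- hh - lh   # high - low gains, at high losses
  data.frame(diff_low_losses = d_low, diff_high_losses = d_high,
             diff_of_diffs = d_high - d_low)
}

#' Grid of reactivity-slope posterior summaries
#'
#' Posterior mean and HDI of the reactivity slope in each cell of the
#' low/high (-1 / +1 SD) WP AARC-gains x WP AARC-losses grid.
#'
#' @inheritParams reactivity_slope
#' @param levels moderator levels in SD units.
#' @param mass HDI mass.
#' @return data frame `gains, losses, est, hdi_low, hdi_high`.
#' @export
slope_grid <- function(fit, levels = c(-1, 1),
                       unit = c("column_sd", "one"), mass = 0.95) {
  unit <- match.arg(unit)
  grid <- expand.grid(gains = levels, losses = levels)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- reactivity_slope(fit, grid$gains[i], grid$losses[i], unit)
    h <- hdi(x, mass)
    data.frame(gains = grid$gains[i], losses = grid$losses[i],
               est = mean(x), hdi_low = unname(h["low"]),
               hdi_high = unname(h["high"]))
  })
  do.call(rbind, rows)
}

#' Expected-outcome curve over WP stress under the quadratic design
#'
#' For a fit of the quadratic-stress design, evaluates per draw the
#' model-implied outcome component driven by WP stress at a given level
#' of WP AARC-losses (other predictors at 0):
#' `eta(s) = b_s s + b_s2 s^2 + b_l l + b_ls l s + b_ls2 l s^2`,
#' over a grid of `s` values, returning the posterior mean and HDI band.
#'
#' @inheritParams reactivity_slope
#' @param l WP AARC-losses level in SD units.
#' @param stress_grid grid of WP stress values in SD units.
#' @param mass HDI mass.
#' @return data frame `stress, est, hdi_low, hdi_high`.
#' @export
quadratic_curve <- function(fit, l, stress_grid = seq(-2, 2, length.out = 41),
                            unit = c("column_sd", "one"), mass = 0.95) {
  unit <- match.arg(unit)
  need <- c("wp_stress", "wp_stress2", "wp_losses", "wp_losses:wp_stress",
            "wp_losses:wp_stress2")
  if (!all(need %in% colnames(fit$frame$X))) {
    stop("fit does not contain the quadratic WP stress terms", call. = FALSE)
  }
  sc <- moderator_scale(fit, unit)
  dr <- posterior_draws(fit, need)
  ll <- l * sc["wp_losses"]
  rows <- lapply(stress_grid, function(s0) {
    s <- s0 * sc["wp_stress"]
    eta <- dr[, "wp_stress"] * s + dr[, "wp_stress2"] * s^2 +
      dr[, "wp_losses"] * ll + dr[, "wp_losses:wp_stress"] * ll * s +
      dr[, "wp_losses:wp_stress2"] * ll * s^2
    h <- hdi(eta, mass)
    data.frame(stress = s0, est = mean(eta), hdi_low = unname(h["low"]),
               hdi_high = unname(h["high"]))
  })
  do.call(rbind, rows)
}
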