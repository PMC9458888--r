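#' Canonical predictor set
#'
#' Column names, in fixed reporting order, of the two-level design:
#' intercept; person-level covariates (age, gender, education, labor
#' force, physical functioning); time covariates (day in study, its
#' square, weekend); between-person (BP) person-means and within-person
#' (WP) daily deviations of AARC-gains, AARC-losses and stress severity;
#' the WP two-way products and the WP three-way product. The quadratic
#' variant appends BP/WP squared stress and WP AARC x squared-stress
#' products.
#'
#' @param quadratic_stress add quadratic stress-severity terms?
#' @return character vector of predictor names.
#' @export
design_predictors <- function(quadratic_stress = FALSE) {
  base <- c("intercept", "age", "female", "tertiary_educated",
            "not_in_labor_force", "physical_functioning",
            "day", "day2", "weekend",
            "bp_gains", "bp_losses", "bp_stress",
            "wp_gains", "wp_losses", "wp_stress",
            "wp_gains:wp_losses", "wp_gains:wp_stress", "wp_losses:wp_stress",
            "wp_gains:wp_losses:wp_stress")
  if (!quadratic_stress) return(base)
  c(base, "bp_stress2", "wp_stress2", "wp_gains:wp_stress2",
    "wp_losses:wp_stress2")
}

#' Design specification for one outcome model
#'
#' Fixes the outcome, its likelihood family and raw censoring bounds,
#' the predictor list with roles (used by the ROPE summary to decide
#' which coefficients get ROPE columns), and the binary coding
#' convention. Negative affect uses a left-censored skew-normal family
#' (floor at 1 on the raw 1-5 scale); vitality a left-and-right censored
#' normal. Vitality censors at the full 1-7 scale bounds by default;
#' pass `bounds_raw = c(1, 5)` for the narrower variant. Affect balance
#' (positive minus negative affect, range -4 to 4) is modelled as a
#' censored skew-normal like negative affect.
#'
#' @param outcome one of `"negative_affect"`, `"vitality"`,
#'   `"affect_balance"`.
#' @param quadratic_stress include quadratic stress terms?
#' @param bounds_raw optional override of the raw censoring bounds
#'   (`NA` = no censoring on that side).
#' @param binary_coding `"pm1"` codes binary predictors -1/+1 (the
#'   analysis convention); `"01"` keeps 0/1 dummies.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(outcome = c("negative_affect", "vitality",
                                    "affect_balance"),
                        quadratic_stress = FALSE,
                        bounds_raw = NULL,
                        binary_coding = c("pm1", "01")) {
  outcome <- match.arg(outcome)
  binary_coding <- match.arg(binary_coding)
  fam <- switch(outcome,
                negative_affect = list(family = "censored_skew_normal",
                                       bounds_raw = c(1, NA)),
                vitality = list(family = "censored_normal",
                                bounds_raw = c(1, 7)),
                affect_balance = list(family = "censored_skew_normal",
                                      bounds_raw = c(-4, NA)))
  if (!is.null(bounds_raw)) fam$bounds_raw <- bounds_raw
  preds <- design_predictors(quadratic_stress)
  role <- rep("covariate", length(preds))
  names(role) <- preds
  role["intercept"] <- "intercept"
  role[c("bp_gains", "bp_losses", "bp_stress")] <- "bp"
  role[c("wp_gains", "wp_losses", "wp_stress")] <- "wp"
  role[grepl(":", preds)] <- "interaction"
  if (quadratic_stress) role[c("bp_stress2", "wp_stress2")] <- "interaction"
  spec <- list(outcome = outcome, family = fam$family,
               bounds_raw = fam$bounds_raw, predictors = preds,
               roles = role, quadratic_stress = quadratic_stress,
               binary_coding = binary_coding)
  class(spec) <- "design_spec"
  spec
}

#' Split a long-form variable into person-mean and daily deviation
#'
#' The between-person (BP) component of `x` is each person's mean over
#' their available occasions, repeated on every row; the within-person
#' (WP) component is the occasion-specific deviation from that mean, so
#' `bp + wp` reconstructs `x` exactly and WP sums to zero within person.
#'
#' @param x numeric vector (may contain `NA`; a person's mean uses their
#'   non-missing occasions).
#' @param person_index vector identifying the person of each row.
#' @return list with numeric vectors `bp` and `wp`.
#' @export
person_disaggregate <- function(x, person_index) {
  stopifnot(length(x) == length(person_index))
  pm <- tapply(x, person_index, mean, na.rm = TRUE)
  if (any(is.nan(pm))) {
    warning("persons with no non-missing values excluded from disaggregation",
            call. = FALSE)
    pm[is.nan(pm)] <- NA_real_
  }
  bp <- as.vector(pm[as.character(person_index)])
  list(bp = bp, wp = x - bp)
}

#' Standardize a long-form variable
#'
#' Centers and scales by the pooled long-form sample mean and SD
#' (denominator n - 1), recording the moments so the transform can be
#' applied to new data or inverted.
#'
#' @param x numeric vector (non-missing entries define the moments).
#' @param center,scale optional pre-computed moments.
#' @return list `z, mean, sd`.
#' @export
standardize_long <- function(x, center = NULL, scale = NULL) {
  m <- center %||% mean(x, na.rm = TRUE)
  s <- scale %||% stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop("zero variance: cannot standardize", call. = FALSE)
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Code a two-level predictor as -1/+1
#'
#' The first level (reference) maps to -1 and the second to +1 (or 0/1
#' under the dummy convention). The level mapping is recorded as an
#' attribute.
#'
#' @param x vector with exactly two distinct values.
#' @param levels optional explicit level order `(reference, other)`.
#' @param coding `"pm1"` or `"01"`.
#' @return numeric vector with attribute `levels`.
#' @export
code_binary <- function(x, levels = NULL, coding = c("pm1", "01")) {
  coding <- match.arg(coding)
  lv <- levels %||% sort(unique(x[!is.na(x)]))
  if (length(lv) != 2L) {
    stop("binary coding needs exactly two levels, got ",
         length(lv), call. = FALSE)
  }
  hi <- if (coding == "pm1") c(-1, 1) else c(0, 1)
  out <- ifelse(is.na(x), NA_real_, ifelse(x == lv[1], hi[1], hi[2]))
  attr(out, "levels") <- stats::setNames(hi, as.character(lv))
  out
}

#' Raw day-in-study time covariates
#'
#' Day is coded 0-9; its square is computed on that raw scale (each
#' column is standardized later, separately).
#'
#' @param day_index integer day codes.
#' @return data frame with columns `day`, `day2`.
#' @export
build_time_covariates <- function(day_index) {
  data.frame(day = as.numeric(day_index), day2 = as.numeric(day_index)^2)
}

#' Map raw censoring bounds onto the standardized outcome scale
#'
#' @param raw_bounds length-2 numeric (lower, upper); `NA` = open side.
#' @param center,scale the outcome's standardization moments.
#' @return length-2 numeric standardized bounds (`-Inf`/`Inf` for open
#'   sides).
#' @export
transform_bounds <- function(raw_bounds, center, scale) {
  lo <- if (is.na(raw_bounds[1])) -Inf else (raw_bounds[1] - center) / scale
  hi <- if (is.na(raw_bounds[2])) Inf else (raw_bounds[2] - center) / scale
  if (lo >= hi) stop("degenerate bounds after standardization", call. = FALSE)
  c(lo, hi)
}

# Predictor-side pipeline shared by analysis and the data generator:
# listwise-delete occasions missing any predictor component, standardize
# continuous variables long-form, disaggregate the standardized daily
# predictors into BP + WP, form WP products (not re-standardized), code
# binaries. Returns the design matrix plus bookkeeping.
build_design_matrix <- function(table, spec) {
  pred_vars <- c("age", "gender", "tertiary_educated", "in_labor_force",
                 "physical_functioning", "day_index", "is_weekend",
                 "aarc_gains", "aarc_losses", "stress_severity")
  keep <- stats::complete.cases(table[, pred_vars])
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("no complete occasions left", call. = FALSE)
  person <- match(tab$person_id, unique(tab$person_id))
  person_ids <- unique(tab$person_id)

  scaling <- list()
  zc <- function(name, x) {
    s <- standardize_long(x)
    scaling[[name]] <<- c(mean = s$mean, sd = s$sd)
    s$z
  }
  tc <- build_time_covariates(tab$day_index)
  z_gains <- zc("aarc_gains", tab$aarc_gains)
  z_losses <- zc("aarc_losses", tab$aarc_losses)
  z_stress <- zc("stress_severity", tab$stress_severity)
  dg <- person_disaggregate(z_gains, tab$person_id)
  dl <- person_disaggregate(z_losses, tab$person_id)
  ds <- person_disaggregate(z_stress, tab$person_id)

  pm1 <- spec$binary_coding
  cols <- list(
    intercept = rep(1, nrow(tab)),
    age = zc("age", tab$age),
    female = code_binary(tab$gender, levels = c("male", "female"), coding = pm1),
    tertiary_educated = code_binary(tab$tertiary_educated, levels = c(0, 1),
                                    coding = pm1),
    not_in_labor_force = code_binary(tab$in_labor_force, levels = c(1, 0),
                                     coding = pm1),
    physical_functioning = zc("physical_functioning", tab$physical_functioning),
    day = zc("day", tc$day),
    day2 = zc("day2", tc$day2),
    weekend = code_binary(tab$is_weekend, levels = c(0, 1), coding = pm1),
    bp_gains = dg$bp, bp_losses = dl$bp, bp_stress = ds$bp,
    wp_gains = dg$wp, wp_losses = dl$wp, wp_stress = ds$wp)
  cols[["wp_gains:wp_losses"]] <- dg$wp * dl$wp
  cols[["wp_gains:wp_stress"]] <- dg$wp * ds$wp
  cols[["wp_losses:wp_stress"]] <- dl$wp * ds$wp
  cols[["wp_gains:wp_losses:wp_stress"]] <- dg$wp * dl$wp * ds$wp
  if (spec$quadratic_stress) {
    cols[["bp_stress2"]] <- ds$bp^2
    cols[["wp_stress2"]] <- ds$wp^2
    cols[["wp_gains:wp_stress2"]] <- dg$wp * ds$wp^2
    cols[["wp_losses:wp_stress2"]] <- dl$wp * ds$wp^2
  }
  X <- do.call(cbind, cols[spec$predictors])
  colnames(X) <- spec$predictors
  list(X = X, person = person, person_ids = person_ids,
       scaling = scaling, rows = which(keep), table = tab)
}

#' Build the model frame an outcome design is fit on
#'
#' Turns a [diary_table()] into the exact inputs of the two-level
#' censored regression: occasions missing any model variable are
#' listwise-deleted (per occasion, not per person); continuous variables
#' are standardized on the pooled long-form sample; the standardized
#' daily predictors are disaggregated into person-mean (BP) and daily
#' deviation (WP) columns (components are not re-standardized, so WP
#' columns have SD below 1); WP products are formed from the
#' standardized components; binary predictors are coded -1/+1; and
#' outcome values exactly at a raw censoring bound are flagged as
#' censored, with the bounds mapped onto the standardized outcome scale.
#'
#' @param table a [diary_table()] (or compatible data frame). For the
#'   `affect_balance` design the outcome column is derived as
#'   `positive_affect - negative_affect`.
#' @param spec a [design_spec()].
#' @return list of class `model_frame`: standardized outcome `y`, censor
#'   codes (-1 left, 0 none, +1 right), design matrix `X`, person index,
#'   standardization records, standardized `bounds_z`, and counts of
#'   deleted rows.
#' @export
build_model_frame <- function(table, spec) {
  tab <- as.data.frame(table)
  if (spec$outcome == "affect_balance") {
    tab$affect_balance <- tab$positive_affect - tab$negative_affect
  }
  if (!spec$outcome %in% names(tab)) {
    stop("outcome column '", spec$outcome, "' not found", call. = FALSE)
  }
  n_start <- nrow(tab)
  tab <- tab[!is.na(tab[[spec$outcome]]), , drop = FALSE]
  dm <- build_design_matrix(tab, spec)
  tab <- dm$table
  y_raw <- tab[[spec$outcome]]
  s <- standardize_long(y_raw)
  scaling <- dm$scaling
  scaling[[spec$outcome]] <- c(mean = s$mean, sd = s$sd)
  bounds_z <- transform_bounds(spec$bounds_raw, s$mean, s$sd)
  censor <- integer(length(y_raw))
  if (!is.na(spec$bounds_raw[1])) censor[y_raw <= spec$bounds_raw[1]] <- -1L
  if (!is.na(spec$bounds_raw[2])) censor[y_raw >= spec$bounds_raw[2]] <- 1L
  scl <- do.call(rbind, lapply(names(scaling), function(nm) {
    data.frame(variable = nm, mean = scaling[[nm]]["mean"],
               sd = scaling[[nm]]["sd"], row.names = NULL)
  }))
  frame <- list(y = s$z, censor = censor, X = dm$X,
                person = dm$person, person_ids = dm$person_ids,
                scaling = scl, bounds_z = bounds_z,
                family = spec$family, outcome = spec$outcome, spec = spec,
                n_dropped = n_start - nrow(tab))
  class(frame) <- "model_frame"
  frame
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf(paste0("<model_frame> outcome '%s' (%s): %d occasions, ",
                     "%d persons, %d predictors; %d left / %d right censored; ",
                     "%d incomplete occasions dropped\n"),
              x$outcome, x$family, length(x$y), length(x$person_ids),
              ncol(x$X), sum(x$censor == -1L), sum(x$censor == 1L),
              x$n_dropped))
  invisible(x)
}

#' Export a model frame as a plain CSV
#'
#' One row per modelled occasion: person id, standardized outcome,
#' censor code, and every design-matrix column, for cross-implementation
#' checks.
#'
#' @param frame a [build_model_frame()] result.
#' @param path file path.
#' @export
write_model_frame_csv <- function(frame, path) {
  out <- data.frame(person_id = frame$person_ids[frame$person],
                    y = frame$y, censor_code = frame$censor,
                    frame$X, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
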