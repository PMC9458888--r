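#' Long-form daily-diary table
#'
#' The universal interchange object of the package: one row per completed
#' person-day, holding scored daily scales (AARC gains/losses, negative
#' and positive affect, vitality, stressor endorsements/severities and
#' the summed severity index) joined to person-level baseline covariates
#' repeated on every row. Missing occasions are simply absent; there are
#' no placeholder rows.
#'
#' @param x data frame with the documented long-form columns (see
#'   [diary_columns()]).
#' @return `x`, ordered by (`person_id`, `day_index`) and classed
#'   `diary_table`.
#' @export
diary_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(diary_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("diary table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[order(x$person_id, x$day_index), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("diary_table", "data.frame")
  validate_diary_table(x)
  x
}

#' Documented long-form column set
#'
#' @return character vector of required column names, in canonical order.
#' @export
diary_columns <- function() {
  c("person_id", "day_index", "is_weekend",
    "aarc_gains", "aarc_losses",
    "negative_affect", "positive_affect", "vitality",
    "stress_severity",
    paste0("s", 1:5), paste0("sev", 1:5),
    "age", "gender", "tertiary_educated", "in_labor_force",
    "physical_functioning")
}

#' Validate diary-table invariants
#'
#' Checks uniqueness of (person, day) pairs, score bounds, agreement of
#' the stress-severity index with its components, and constancy of
#' baseline covariates within person. Daily scale scores may be `NA`
#' (scale not completed on that occasion); baseline fields may not.
#'
#' @param x a [diary_table()].
#' @return `x` invisibly; errors describe the first violated invariant.
#' @export
validate_diary_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(x[, c("person_id", "day_index")])) {
    stop("duplicate (person_id, day_index) pairs", call. = FALSE)
  }
  if (any(x$day_index != round(x$day_index)) || any(x$day_index < 0)) {
    stop("day_index must be a non-negative integer", call. = FALSE)
  }
  in_bounds <- function(v, lo, hi) all(is.na(v) | (v >= lo & v <= hi))
  bounds <- list(aarc_gains = c(5, 25), aarc_losses = c(5, 25),
                 negative_affect = c(1, 5), positive_affect = c(1, 5),
                 vitality = c(1, 7), stress_severity = c(0, 25),
                 physical_functioning = c(0, 100))
  for (nm in names(bounds)) {
    if (!in_bounds(x[[nm]], bounds[[nm]][1], bounds[[nm]][2])) {
      stop(sprintf("%s outside its scale bounds [%g, %g]",
                   nm, bounds[[nm]][1], bounds[[nm]][2]), call. = FALSE)
    }
  }
  if (any(!is.na(x$age) & x$age < 0)) stop("negative age", call. = FALSE)
  if (!all(x$gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'", call. = FALSE)
  }
  # stress index must equal the sum of endorsed severities where present
  endo <- as.matrix(x[, paste0("s", 1:5)])
  sev  <- as.matrix(x[, paste0("sev", 1:5)])
  have <- !is.na(x$stress_severity)
  if (any(have)) {
    if (any(!is.na(sev[have, , drop = FALSE]) & !(endo[have, , drop = FALSE] %in% 1))) {
      stop("severity present for an unendorsed stressor", call. = FALSE)
    }
    recomputed <- rowSums(ifelse(endo[have, , drop = FALSE] == 1,
                                 ifelse(is.na(sev[have, , drop = FALSE]), 0,
                                        sev[have, , drop = FALSE]), 0))
    if (any(abs(recomputed - x$stress_severity[have]) > 1e-9)) {
      stop("stress_severity does not equal the sum of endorsed severities",
           call. = FALSE)
    }
  }
  # baseline covariates constant within person
  for (nm in c("age", "gender", "tertiary_educated", "in_labor_force",
               "physical_functioning")) {
    n_distinct <- tapply(x[[nm]], x$person_id, function(v) length(unique(v)))
    if (any(n_distinct > 1)) {
      stop(sprintf("baseline covariate '%s' varies within person", nm),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Read / write long-form diary CSV
#'
#' Plain UTF-8 CSV with '.' decimal separator and the column set of
#' [diary_columns()]. Numeric values are written with 17 significant
#' digits so a write/read round trip reproduces every field exactly.
#' Unknown extra columns are kept with a warning; duplicate (person, day)
#' rows are an error.
#'
#' @param path file path.
#' @return [read_long_csv()] returns a [diary_table()].
#' @export
read_long_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(x), diary_columns())
  if (length(extra) > 0) {
    warning("unknown columns kept as-is: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  for (nm in c("tertiary_educated", "in_labor_force", "is_weekend",
               "day_index", "stress_severity", paste0("s", 1:5))) {
    if (nm %in% names(x)) x[[nm]] <- as.integer(x[[nm]])
  }
  for (nm in c("aarc_gains", "aarc_losses", "negative_affect",
               "positive_affect", "vitality", "age",
               "physical_functioning", paste0("sev", 1:5))) {
    if (nm %in% names(x)) x[[nm]] <- as.numeric(x[[nm]])
  }
  diary_table(x)
}

#' @param table a [diary_table()].
#' @rdname read_long_csv
#' @export
write_long_csv <- function(table, path) {
  stopifnot(inherits(table, "diary_table"))
  out <- as.data.frame(table)
  is_dbl <- vapply(out, is.double, logical(1))
  out[is_dbl] <- lapply(out[is_dbl], function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @export
print.diary_table <- function(x, ...) {
  cat(sprintf("<diary_table> %d observations from %d persons (days %d-%d)\n",
              nrow(x), length(unique(x$person_id)),
              min(x$day_index), max(x$day_index)))
  NextMethod()
}
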