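#' Score the 10-item daily awareness-of-age-related-change short form
#'
#' The daily AARC short form contains two five-item subscales tapping
#' perceived age-related gains and losses. Items are treated positionally:
#' the first five responses belong to the gains subscale, the last five to
#' the losses subscale. Each subscale is scored as the *sum* of its items,
#' so scores range from 5 to 25 with higher values indicating greater
#' awareness of gains (losses).
#'
#' @param item_responses integer vector of length 10, each in 1..5, or an
#'   n x 10 matrix of such responses (one row per person-day).
#' @return A list (or data frame for matrix input) with components
#'   `gains` and `losses`, each in \[5, 25\].
#' @examples
#' score_aarc(c(5, 4, 4, 4, 4, 1, 2, 1, 1, 1))
#' @export
score_aarc <- function(item_responses) {
  if (is.matrix(item_responses)) {
    out <- t(apply(item_responses, 1, function(r) unlist(score_aarc(r))))
    return(data.frame(gains = out[, "gains"], losses = out[, "losses"]))
  }
  check_items(item_responses, n = 10, lo = 1, hi = 5, scale = "AARC-10 SF")
  list(gains  = sum(item_responses[1:5]),
       losses = sum(item_responses[6:10]))
}

#' Score the 12-item scale of positive and negative experience (SPANE)
#'
#' Six positive-feeling items (positions 1-6) and six negative-feeling
#' items (positions 7-12), each rated 1-5. Positive and negative affect
#' are item *means* (range 1-5); affect balance is positive minus
#' negative affect (range -4 to 4).
#'
#' @param item_responses integer vector of length 12 (positions 1-6
#'   positive, 7-12 negative), each in 1..5, or an n x 12 matrix.
#' @return list (or data frame) with `positive_affect`, `negative_affect`,
#'   `affect_balance`.
#' @export
score_spane <- function(item_responses) {
  if (is.matrix(item_responses)) {
    out <- t(apply(item_responses, 1, function(r) unlist(score_spane(r))))
    return(as.data.frame(out))
  }
  check_items(item_responses, n = 12, lo = 1, hi = 5, scale = "SPANE")
  pa <- mean(item_responses[1:6])
  na <- mean(item_responses[7:12])
  list(positive_affect = pa, negative_affect = na, affect_balance = pa - na)
}

#' Score the six-item subjective vitality scale
#'
#' Item mean of six agreement ratings (1 = not at all true, 7 = very
#' true) about feeling alive and energetic; range 1-7.
#'
#' @param item_responses integer vector of length 6, each in 1..7, or an
#'   n x 6 matrix.
#' @return mean score in \[1, 7\] (vector for matrix input).
#' @export
score_vitality <- function(item_responses) {
  if (is.matrix(item_responses)) {
    return(apply(item_responses, 1, score_vitality))
  }
  check_items(item_responses, n = 6, lo = 1, hi = 7, scale = "vitality")
  mean(item_responses)
}

#' Daily stressor-severity index
#'
#' Participants report whether each of five stressor categories occurred
#' in the past 24 h and, where endorsed, rate its severity from 1 (not at
#' all stressful) to 5 (very stressful). The daily index sums the
#' severity ratings over endorsed stressors; stressors not endorsed
#' contribute 0, so a completed survey with no stressors scores 0.
#'
#' @param endorsements logical (or 0/1) vector of length 5.
#' @param severities numeric vector of length 5; must hold a rating in
#'   1..5 exactly where the stressor is endorsed and `NA` elsewhere.
#' @return integer sum in \[0, 25\].
#' @export
stress_severity_index <- function(endorsements, severities) {
  if (length(endorsements) != 5L || length(severities) != 5L) {
    stop("exactly five stressor slots are expected", call. = FALSE)
  }
  endorsements <- as.logical(endorsements)
  if (anyNA(endorsements)) stop("endorsements must be non-missing", call. = FALSE)
  if (any(!is.na(severities[!endorsements]))) {
    stop("severity supplied for a stressor that was not endorsed", call. = FALSE)
  }
  sev <- severities[endorsements]
  if (anyNA(sev) || any(sev < 1 | sev > 5) || any(sev != round(sev))) {
    stop("each endorsed stressor needs an integer severity in 1..5", call. = FALSE)
  }
  as.integer(sum(sev))
}

#' Recode the RAND physical-functioning subscale to 0-100
#'
#' Ten activity-limitation items on a 3-point scale (1 = limited a lot,
#' 2 = limited a little, 3 = not limited at all) are each linearly
#' recoded to 0/50/100 and averaged, the standard RAND-36 convention.
#' Higher scores mean better physical functioning.
#'
#' @param item_responses integer vector of length 10, each in 1..3, or an
#'   n x 10 matrix.
#' @return score in \[0, 100\].
#' @export
recode_physical_functioning <- function(item_responses) {
  if (is.matrix(item_responses)) {
    return(apply(item_responses, 1, recode_physical_functioning))
  }
  check_items(item_responses, n = 10, lo = 1, hi = 3, scale = "physical functioning")
  mean((item_responses - 1) * 50)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability for a respondent-by-item score
#' matrix: `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`.
#'
#' @param item_matrix numeric matrix, n respondents x k >= 2 items, no
#'   missing cells.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  if (k < 2L) stop("Cronbach's alpha needs at least two items", call. = FALSE)
  if (anyNA(item_matrix)) stop("item matrix contains missing cells", call. = FALSE)
  total_var <- stats::var(rowSums(item_matrix))
  if (total_var <= 0) stop("total-score variance is zero; alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(item_matrix, 2, stats::var)) / total_var)
}

# shared response validation: no partial-scale scoring
check_items <- function(x, n, lo, hi, scale) {
  if (length(x) != n || anyNA(x)) {
    stop(sprintf("%s scoring needs %d complete responses", scale, n), call. = FALSE)
  }
  if (any(x < lo | x > hi)) {
    stop(sprintf("%s responses must lie in %d..%d", scale, lo, hi), call. = FALSE)
  }
  invisible(TRUE)
}
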