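# Shared fixtures: small synthetic tables and cached fits so expensive
# sampling runs once per test session.

small_config <- function(n_persons = 40, n_days = 6, seed = 101) {
  generator_config(n_persons = n_persons, n_days = n_days, seed = seed)
}

small_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_config())$table
    cache
  }
})

# tiny hand-built two-person table for exact-value tests
tiny_table <- function() {
  base <- data.frame(
    person_id = rep(c("a", "b"), each = 3),
    day_index = rep(0:2, 2),
    is_weekend = rep(c(0L, 0L, 1L), 2),
    aarc_gains = c(20, 22, 21, 15, 16, 17),
    aarc_losses = c(10, 11, 9, 14, 13, 12),
    negative_affect = c(1, 2.5, 2, 3, 1.5, 1),
    positive_affect = c(4, 3.5, 3, 2, 2.5, 3),
    vitality = c(5, 4.5, 6, 3, 3.5, 4),
    stress_severity = c(0L, 6L, 2L, 0L, 3L, 5L),
    age = rep(c(70, 65), each = 3),
    gender = rep(c("female", "male"), each = 3),
    tertiary_educated = rep(c(1L, 0L), each = 3),
    in_labor_force = rep(c(0L, 1L), each = 3),
    physical_functioning = rep(c(85, 60), each = 3),
    stringsAsFactors = FALSE)
  for (j in 1:5) {
    base[[paste0("s", j)]] <- 0L
    base[[paste0("sev", j)]] <- NA_real_
  }
  base$s1 <- c(0L, 1L, 1L, 0L, 1L, 1L)
  base$sev1 <- c(NA, 2, 2, NA, 3, 5)
  base$s2 <- c(0L, 1L, 0L, 0L, 0L, 0L)
  base$sev2 <- c(NA, 4, NA, NA, NA, NA)
  diary_table(base[, diary_columns()])
}

# one shared small vitality fit (normal family) for probe/rope tests
cached_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fr <- build_model_frame(small_table(), design_spec("vitality"))
      cache <<- fit_hierarchical(fr, chains = 2, warmup = 400, iter = 400,
                                 seed = 11, check = "none")
    }
    cache
  }
})
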