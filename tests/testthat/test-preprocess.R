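test_that("person disaggregation splits into mean and deviation exactly", {
  d <- person_disaggregate(c(2, 4), c("a", "a"))
  expect_equal(d$bp, c(3, 3))
  expect_equal(d$wp, c(-1, 1))

  d <- person_disaggregate(c(5, 5, 5), rep("a", 3))
  expect_equal(d$wp, c(0, 0, 0))

  # reconstruction and zero-sum WP under missingness, random tables
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(60)
    x[sample(60, 8)] <- NA
    g <- sample(letters[1:6], 60, replace = TRUE)
    d <- person_disaggregate(x, g)
    ok <- !is.na(x)
    expect_equal(d$bp[ok] + d$wp[ok], x[ok])
    sums <- tapply(d$wp, g, sum, na.rm = TRUE)
    expect_true(all(abs(sums) < 1e-10))
  }
})

test_that("long-form standardization records invertible moments", {
  s <- standardize_long(c(0, 2))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sqrt(2))  # n - 1 denominator
  set.seed(3)
  x <- rnorm(200, 5, 3)
  s <- standardize_long(x)
  expect_equal(mean(s$z), 0, tolerance = 1e-12)
  expect_equal(sd(s$z), 1, tolerance = 1e-12)
  # applying stored moments to new data is affine and invertible
  y <- rnorm(50, 5, 3)
  z2 <- standardize_long(y, center = s$mean, scale = s$sd)$z
  expect_equal(z2 * s$sd + s$mean, y)
  expect_error(standardize_long(rep(2, 10)), "zero variance")
})

test_that("binary coding maps reference level to -1", {
  g <- code_binary(c("male", "female", "female"),
                   levels = c("male", "female"))
  expect_equal(as.vector(g), c(-1, 1, 1))
  w <- code_binary(c(0, 1, 0), levels = c(0, 1))
  expect_equal(as.vector(w), c(-1, 1, -1))
  expect_error(code_binary(c("a", "b", "c")), "two levels")
  expect_error(code_binary(rep("a", 3)), "two levels")
})

test_that("time covariates and bound transforms are exact", {
  tc <- build_time_covariates(c(0, 3, 9))
  expect_equal(tc$day, c(0, 3, 9))
  expect_equal(tc$day2, c(0, 9, 81))

  b <- transform_bounds(c(1, NA), 2.5, 1.28)
  expect_equal(b[1], (1 - 2.5) / 1.28)
  expect_equal(b[2], Inf)
  expect_equal(transform_bounds(c(2.5, 5), 2.5, 1.28)[1], 0)
  b2 <- transform_bounds(c(1, 7), 4.66, 1.36)
  expect_lt(b2[1], b2[2])
})

test_that("model frame has the documented schema and structure", {
  fr <- build_model_frame(small_table(), design_spec("negative_affect"))
  expect_identical(colnames(fr$X), design_predictors())
  expect_false(anyNA(fr$X))
  expect_false(anyNA(fr$y))

  # WP products equal elementwise products of their standardized parents
  expect_equal(fr$X[, "wp_gains:wp_losses"],
               fr$X[, "wp_gains"] * fr$X[, "wp_losses"])
  expect_equal(fr$X[, "wp_gains:wp_losses:wp_stress"],
               fr$X[, "wp_gains"] * fr$X[, "wp_losses"] * fr$X[, "wp_stress"])

  # standardized parents: bp + wp reconstructs the standardized variable
  z <- standardize_long(small_table()$aarc_gains)$z
  expect_equal(fr$X[, "bp_gains"] + fr$X[, "wp_gains"], z)

  # WP columns centre at zero within person and have SD < 1
  expect_true(all(abs(tapply(fr$X[, "wp_stress"], fr$person, sum)) < 1e-9))
  expect_lt(sd(fr$X[, "wp_gains"]), 1)

  # binaries coded -1/+1
  expect_true(all(fr$X[, "female"] %in% c(-1, 1)))
  expect_true(all(fr$X[, "weekend"] %in% c(-1, 1)))

  # censor codes match rows at the bounds
  raw <- small_table()$negative_affect
  expect_equal(sum(fr$censor == -1L), sum(raw == 1))
  expect_equal(sum(fr$censor == 1L), 0)

  # idempotence
  fr2 <- build_model_frame(small_table(), design_spec("negative_affect"))
  expect_identical(fr$X, fr2$X)
  expect_identical(fr$y, fr2$y)
})

test_that("quadratic design appends squared-stress columns", {
  fr <- build_model_frame(small_table(),
                          design_spec("negative_affect",
                                      quadratic_stress = TRUE))
  expect_identical(colnames(fr$X), design_predictors(TRUE))
  expect_equal(fr$X[, "wp_stress2"], fr$X[, "wp_stress"]^2)
  expect_equal(fr$X[, "bp_stress2"], fr$X[, "bp_stress"]^2)
  expect_equal(fr$X[, "wp_losses:wp_stress2"],
               fr$X[, "wp_losses"] * fr$X[, "wp_stress"]^2)
})

test_that("occasions with missing model variables are listwise-deleted", {
  tab <- as.data.frame(small_table())
  tab$negative_affect[3] <- NA
  tab$aarc_losses[7] <- NA
  fr <- build_model_frame(tab, design_spec("negative_affect"))
  expect_equal(fr$n_dropped, 2)
  expect_equal(length(fr$y), nrow(tab) - 2)
  # persons with remaining rows are all retained
  expect_true(all(unique(tab$person_id) %in% fr$person_ids))
})

test_that("model frames export to plain CSV with censor codes intact", {
  fr <- build_model_frame(small_table(), design_spec("negative_affect"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_frame_csv(fr, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), length(fr$y))
  expect_equal(back$censor_code, fr$censor)
  expect_equal(back$y, fr$y, tolerance = 1e-12)
  expect_true(all(design_predictors() %in% names(back)))
})

test_that("affect balance is derived from its components", {
  fr <- build_model_frame(small_table(), design_spec("affect_balance"))
  tab <- small_table()
  bal <- tab$positive_affect - tab$negative_affect
  s <- standardize_long(bal)
  expect_equal(fr$y, s$z)
  expect_equal(fr$family, "censored_skew_normal")
})
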