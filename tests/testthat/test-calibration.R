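panel <- nad_panel()

test_that("response ratios use the panel's ISTD mapping, surrogates included", {
  df <- data.frame(
    sample_id = "S1",
    channel_id = c("NAD+|12C", "NAD+|13C", "NCA|12C", "NAM|13C", "NAM|12C"),
    area = c(1000, 500, 300, 600, 120),
    rt = c(4.2, 4.2, 1.6, 1.0, 1.0), role = "unknown",
    level = NA_real_, stringsAsFactors = FALSE)
  resp <- compute_responses(read_peak_table(df, panel), panel)
  expect_equal(resp$response[resp$analyte == "NAD+"], 2.0)
  # NCA ratios against the NAM 13C surrogate channel
  nca <- resp[resp$analyte == "NCA", ]
  expect_equal(nca$istd_channel, "NAM|13C")
  expect_equal(nca$response, 300 / 600)
})

test_that("zero ISTD area is flagged, never an infinity", {
  df <- data.frame(sample_id = "S1",
                   channel_id = c("NAM|12C", "NAM|13C"),
                   area = c(100, 0), rt = 1, role = "unknown",
                   level = NA_real_, stringsAsFactors = FALSE)
  expect_message(resp <- compute_responses(read_peak_table(df, panel), panel),
                 "no_istd")
  expect_equal(resp$flag, "no_istd")
  expect_true(is.na(resp$response))
})

test_that("background subtraction removes a constant offset exactly", {
  x <- rep(c(50, 100, 500, 1000, 5000, 10000), each = 2)
  b <- 0.73
  resp <- data.frame(sample_id = seq_along(x), analyte = "NAM",
                     response = 0.001 * x + b, level = x, flag = "",
                     stringsAsFactors = FALSE)
  blanks <- data.frame(analyte = "NAM", response = rep(b, 3))
  corr <- subtract_matrix_background(resp, blanks)
  fit <- fit_calibration(corr$level, corr$response)
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  # zero background is the identity; negative results clip with a flag
  zero <- subtract_matrix_background(resp, data.frame(analyte = "NAM",
                                                      response = c(0, 0)))
  expect_equal(zero$response, resp$response)
  clip <- subtract_matrix_background(
    data.frame(analyte = "NAM", response = 0.1, flag = ""),
    data.frame(analyte = "NAM", response = 0.5))
  expect_equal(clip$response, 0)
  expect_match(clip$flag, "clipped")
  expect_error(subtract_matrix_background(resp, NULL), "no matrix blanks")
})

test_that("an exact line is recovered perfectly; degenerate designs error", {
  x <- rep(c(50, 100, 250, 500, 1000, 2000, 3000, 4000, 5000, 6500, 8000,
             10000), each = 2)
  fit <- fit_calibration(x, 0.001 * x, analyte = "NAD+")
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$sigma, 0, tolerance = 1e-12)
  expect_false(fit$rejected)

  expect_error(fit_calibration(c(1, 1, 2, 2), c(1, 1, 2, 2)), "3 distinct")
  expect_error(fit_calibration(rep(5, 4), 1:4), "3 distinct")
  down <- fit_calibration(c(1, 2, 3), c(3, 2, 1))
  expect_true(down$rejected)
})

test_that("noisy duplicate series recover the true slope with high linearity", {
  set.seed(101)
  x <- rep(c(50, 100, 250, 500, 1000, 2000, 3000, 4000, 5000, 6500, 8000,
             10000), each = 2)
  fit <- fit_calibration(x, 0.001 * x + rnorm(length(x), sd = 0.01))
  se <- summary(fit$fit)$coefficients["conc", "Std. Error"]
  expect_lt(abs(fit$slope - 0.001), 3 * se)
  expect_gte(fit$r_squared, 0.98)
})

test_that("1/x weighting stabilizes the intercept under proportional noise", {
  set.seed(404)
  x <- rep(c(50, 100, 250, 500, 1000, 2000, 3000, 4000, 5000, 6500, 8000,
             10000), each = 2)
  int_err <- replicate(50, {
    y <- 0.001 * x * exp(rnorm(length(x), sd = 0.05))
    c(abs(fit_calibration(x, y)$intercept),
      abs(fit_calibration(x, y, weighting = "1/x")$intercept))
  })
  expect_lt(median(int_err[2, ]), median(int_err[1, ]))
})

test_that("slope coverage of the +/-2 SE interval holds across batches", {
  set.seed(202)
  x <- rep(c(50, 100, 250, 500, 1000, 2000, 3000, 4000, 5000, 6500, 8000,
             10000), each = 2)
  hits <- vapply(seq_len(200), function(i) {
    fit <- fit_calibration(x, 0.001 * x + rnorm(length(x), sd = 0.01))
    se <- summary(fit$fit)$coefficients["conc", "Std. Error"]
    abs(fit$slope - 0.001) <= 2 * se
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("LOD/LOQ follow the slope formulas with a fixed 10/3.3 ratio", {
  # hand arithmetic: S = 0.001/nM, sigma = 0.002 -> LOD 6.6 nM, LOQ 20 nM
  curve <- list(slope = 0.001, sigma = 0.002, n = 10)
  class(curve) <- "nad_calibration"
  ll <- estimate_lod_loq(curve = curve)
  expect_equal(ll$lod, 6.6)
  expect_equal(ll$loq, 20)
  expect_equal(ll$loq / ll$lod, 10 / 3.3, tolerance = 1e-12)

  # noiseless low-range series: LOD = LOQ = 0
  x <- 0.78 * 2^(0:7)
  ll0 <- estimate_lod_loq(x, 0.001 * x)
  expect_equal(ll0$lod, 0, tolerance = 1e-12)
  expect_equal(ll0$loq, 0, tolerance = 1e-12)

  expect_error(estimate_lod_loq(c(1, 2, 3), c(1, 2, 3)), "5 low-range")
  expect_error(estimate_lod_loq(x, -0.001 * x), "non-positive slope")
})

test_that("back-calculation inverts the curve and respects rejection", {
  x <- c(50, 100, 500, 1000, 5000, 10000)
  fit <- fit_calibration(x, 0.001 * x)
  expect_equal(as.numeric(back_calculate(1.0, fit)), 1000, tolerance = 1e-9)
  expect_equal(as.numeric(back_calculate(fit$intercept, fit)), 0)
  neg <- back_calculate(fit$intercept - 0.01, fit)
  expect_equal(as.numeric(neg), 0)
  expect_true(attr(neg, "clipped"))

  # noiseless QC at 2500 comes back exactly
  expect_equal(as.numeric(back_calculate(0.001 * 2500, fit)), 2500,
               tolerance = 1e-9)

  rej <- fit_calibration(c(1, 2, 3), c(3, 2, 1))
  expect_error(back_calculate(1, rej), "rejected")
})

test_that("fit-then-back-calculate is the least-squares projection", {
  set.seed(33)
  x <- rep(c(50, 100, 500, 1000, 5000, 10000), each = 2)
  y <- 0.001 * x + rnorm(length(x), sd = 0.02)
  fit <- fit_calibration(x, y)
  back <- back_calculate(y, fit)
  expect_equal(mean(back - x), 0, tolerance = 1e-9)
})

test_that("model methods behave as a classed fit should", {
  x <- c(50, 100, 500, 1000, 5000, 10000)
  fit <- fit_calibration(x, 0.001 * x + 0.05, analyte = "FAD")
  expect_s3_class(fit, "nad_calibration")
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(predict(fit, 2000), fit$intercept + fit$slope * 2000)
  expect_equal(as.numeric(predict(fit, 1.0, type = "conc")),
               as.numeric(back_calculate(1.0, fit)))
  expect_length(residuals(fit), length(x))
  expect_output(print(fit), "Matrix-matched calibration")
  s <- summary(fit)
  expect_true(s$linearity_ok)
})
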