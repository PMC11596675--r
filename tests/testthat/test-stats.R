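mk_quant <- function(df) {
  df$censored <- df$censored %||% "none"
  if (is.null(df$outlier)) df$outlier <- FALSE
  structure(df, class = c("nad_quant", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("redox ratios are element-wise and skip censored denominators", {
  df <- data.frame(
    analyte = rep(c("NAD+", "NADH", "NADP+", "NADPH"), each = 2),
    sample_id = rep(c("S1", "S2"), 4), timepoint = "T1",
    value = c(500, 400, 50, 40, 100, 100, 30, 60),
    censored = "none", outlier = FALSE, stringsAsFactors = FALSE)
  rr <- redox_ratios(mk_quant(df))
  expect_equal(rr$value[rr$ratio == "NADH/NAD+" & rr$sample_id == "S1"], 0.1)
  expect_equal(rr$value[rr$ratio == "NADH/NAD+" & rr$sample_id == "S2"],
               0.1)
  expect_equal(rr$value[rr$ratio == "NADPH/NADP+" & rr$sample_id == "S2"],
               0.6)

  # the four ratios are algebraically consistent per sample
  for (s in c("S1", "S2")) {
    v <- function(r) rr$value[rr$ratio == r & rr$sample_id == s]
    expect_equal(v("NADPH/NADH"),
                 v("NADPH/NADP+") * v("NADP+/NAD+") / v("NADH/NAD+"),
                 tolerance = 1e-12)
  }

  # censoring the denominator drops that sample's ratio only
  df2 <- df
  df2$censored[df2$analyte == "NADP+" & df2$sample_id == "S2"] <- "below_loq"
  rr2 <- redox_ratios(mk_quant(df2))
  expect_false(any(rr2$ratio == "NADPH/NADP+" & rr2$sample_id == "S2"))
  expect_true(any(rr2$ratio == "NADPH/NADP+" & rr2$sample_id == "S1"))
})

test_that("equal pools give unit ratios", {
  df <- data.frame(analyte = c("NAD+", "NADH"), sample_id = "S1",
                   timepoint = "T1", value = c(300, 300),
                   censored = "none", outlier = FALSE)
  rr <- redox_ratios(mk_quant(df))
  expect_equal(rr$value[rr$ratio == "NADH/NAD+"], 1)
})

test_that("one-way ANOVA with Tukey matches closed-form sums of squares", {
  res <- one_way_anova_tukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$f, 13.5, tolerance = 1e-9)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)

  same <- one_way_anova_tukey(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)

  sep <- one_way_anova_tukey(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_equal(sep$p, 0)   # zero within-group variance, groups differ

  expect_error(one_way_anova_tukey(1:4, rep("a", 4)), "2 groups")
  expect_error(one_way_anova_tukey(1:3, c("a", "a", "b")), "2 values")
})

test_that("log2 fold changes report means ratios and the reference is 0", {
  df <- expand.grid(analyte = c("A", "B"), timepoint = c("T1", "T2"),
                    bio_rep = 1:2, tech_rep = 1:2,
                    stringsAsFactors = FALSE)
  df$sample_id <- paste(df$timepoint, df$bio_rep, df$tech_rep, sep = "_")
  df$value <- ifelse(df$analyte == "A" & df$timepoint == "T2", 200, 100)
  q <- mk_quant(df)
  fc <- log2_fold_changes(q, reference = "T1")
  expect_equal(fc$log2fc[fc$analyte == "A" & fc$timepoint == "T2"], 1)
  expect_equal(fc$log2fc[fc$analyte == "B" & fc$timepoint == "T2"], 0)

  df$value <- ifelse(df$analyte == "A" & df$timepoint == "T2", 25, 100)
  fc2 <- log2_fold_changes(mk_quant(df), reference = "T1")
  expect_equal(fc2$log2fc[fc2$analyte == "A" & fc2$timepoint == "T2"], -2)

  expect_error(log2_fold_changes(q, reference = "T9"), "absent")
})

test_that("ANOVA holds its nominal type-I error rate under the null", {
  set.seed(77)
  n_sim <- 400
  hits <- vapply(seq_len(n_sim), function(i) {
    one_way_anova_tukey(rnorm(15), rep(c("T1", "T2", "T3"), each = 5))$p <=
      0.05
  }, TRUE)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n_sim)
  expect_gte(mean(hits), ci[1])
  expect_lte(mean(hits), ci[2])
})

test_that("autoscaled PCA has the promised spectral structure", {
  set.seed(8)
  # two perfectly correlated analytes: one component carries everything
  a <- rnorm(10)
  p1 <- autoscale_pca(cbind(x = a, y = 2 * a + 3))
  expect_equal(p1$variance_explained[1], 100, tolerance = 1e-9)

  # orthogonal equal-variance pair: 50/50
  b <- c(1, -1, 1, -1, 1, -1, 1, -1)
  c2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  p2 <- autoscale_pca(cbind(b, c2))
  expect_equal(p2$variance_explained, c(50, 50), tolerance = 1e-9)

  # full decomposition always sums to 100%, loadings orthonormal
  m <- matrix(rnorm(60), 10, 6)
  p3 <- autoscale_pca(m)
  expect_equal(sum(p3$variance_explained), 100, tolerance = 1e-9)
  expect_true(all(diff(p3$variance_explained) <= 1e-9))
  expect_equal(crossprod(p3$loadings), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)

  # planted two-factor structure dominates the first two components
  f1 <- rnorm(40); f2 <- rnorm(40)
  planted <- cbind(f1, f1 + rnorm(40, sd = 0.1), f2,
                   f2 + rnorm(40, sd = 0.1), rnorm(40, sd = 0.1),
                   rnorm(40, sd = 0.1))
  p4 <- autoscale_pca(planted)
  expect_gte(sum(p4$variance_explained[1:2]), 60)

  # zero-variance columns are dropped with a warning
  expect_warning(p5 <- autoscale_pca(cbind(a = rnorm(5), b = rep(3, 5))),
                 "zero-variance")
  expect_equal(p5$dropped, "b")
})

test_that("PCA imputation fills censored cells within timepoint", {
  m <- matrix(rnorm(20, mean = 10), 10, 2)
  tp <- rep(c("T1", "T2"), each = 5)
  m[2, 1] <- NA
  p <- autoscale_pca(m, timepoint = tp)
  expect_equal(p$n_imputed, 1L)
  expect_false(anyNA(p$scores))
})
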