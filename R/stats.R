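# Downstream NADome analysis: redox ratios, log2 fold changes against the
# aerobic reference with ANOVA/Tukey/FDR significance, and autoscaled PCA.

.ratio_pairs <- list(
  "NADH/NAD+" = c("NADH", "NAD+"),
  "NADPH/NADP+" = c("NADPH", "NADP+"),
  "NADP+/NAD+" = c("NADP+", "NAD+"),
  "NADPH/NADH" = c("NADPH", "NADH")
)

#' Per-sample redox and phosphorylation ratios
#'
#' Element-wise ratios of intracellular pools for the four canonical pairs
#' NADH/NAD+, NADPH/NADP+, NADP+/NAD+ and NADPH/NADH. A ratio is computed
#' only for samples where both members are uncensored, non-outlying and the
#' denominator is positive; other samples are skipped with a flag count.
#' The four ratios are algebraically linked per sample:
#' NADPH/NADH = (NADPH/NADP+)(NADP+/NAD+)/(NADH/NAD+).
#'
#' @param quant an \code{"nad_quant"} table.
#' @return data.frame: ratio, sample_id, timepoint, value.
#' @export
redox_ratios <- function(quant) {
  df <- as.data.frame(quant)
  df <- df[df$censored == "none" & !df$outlier, , drop = FALSE]
  out <- list()
  for (rn in names(.ratio_pairs)) {
    pair <- .ratio_pairs[[rn]]
    num <- df[df$analyte == pair[1], c("sample_id", "timepoint", "value")]
    den <- df[df$analyte == pair[2], c("sample_id", "value")]
    m <- merge(num, den, by = "sample_id", suffixes = c("_num", "_den"))
    m <- m[m$value_den > 0, , drop = FALSE]
    if (nrow(m)) {
      out[[rn]] <- data.frame(ratio = rn, sample_id = m$sample_id,
                              timepoint = m$timepoint,
                              value = m$value_num / m$value_den,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Classical one-way analysis of variance across groups followed by Tukey's
#' Honestly Significant Difference pairwise comparisons (via
#' \code{stats::aov} and \code{stats::TukeyHSD}). The degenerate all-groups-
#' identical case returns F = 0, p = 1; zero within-group variance with
#' between-group differences yields p = 0 explicitly.
#'
#' @param values numeric measurements.
#' @param groups group labels (coerced to factor), >= 2 groups with >= 2
#'   values each.
#' @return list: \code{f}, \code{p}, and \code{tukey}, a data.frame of
#'   pairwise contrasts with diff, lwr, upr, p_adj.
#' @examples
#' one_way_anova_tukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("need at least 2 values per group")
  ssb <- sum(tapply(values, groups, function(x) length(x) *
                      (mean(x) - mean(values))^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  if (ssw == 0 && ssb == 0) {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    return(list(f = 0, p = 1, tukey = data.frame(
      contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = 0, lwr = 0, upr = 0, p_adj = 1, stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (ssw == 0) { f <- Inf; p <- 0 }
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)
  if (ssw == 0) tukey$p_adj[tukey$diff != 0] <- 0
  list(f = f, p = p, tukey = tukey)
}

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                              ifelse(p <= 0.01, "**",
                                     ifelse(p <= 0.05, "*", "ns"))))
}

#' Log2 fold changes against a reference timepoint, with significance
#'
#' For each analyte and non-reference timepoint: log2 of the ratio of group
#' means, where each group mean averages biological replicates (each
#' biological replicate first summarized as the mean of its technical
#' replicates, censored values and flagged outliers excluded). Significance
#' comes from a per-analyte one-way ANOVA across timepoints on the
#' biological-replicate means, Tukey HSD for the contrast against the
#' reference, then Benjamini-Hochberg FDR across analytes within each
#' timepoint contrast. Stars: * p<=0.05, ** p<=0.01, *** p<=0.001.
#'
#' @param quant an \code{"nad_quant"} table.
#' @param reference reference timepoint label (default \code{"T1"}).
#' @param fdr_alpha FDR cutoff used for the \code{significant} column
#'   (default 0.05).
#' @return data.frame: analyte, timepoint, log2fc, p_adjusted, stars,
#'   significant.
#' @export
log2_fold_changes <- function(quant, reference = "T1", fdr_alpha = 0.05) {
  df <- as.data.frame(quant)
  df <- df[df$censored == "none" & !df$outlier & !is.na(df$value), ,
           drop = FALSE]
  if (!reference %in% df$timepoint) {
    stop("reference timepoint '", reference, "' absent from data")
  }
  # biological-replicate means of technical replicates
  agg <- stats::aggregate(value ~ analyte + timepoint + bio_rep, df, mean)
  out <- list()
  for (a in unique(agg$analyte)) {
    sub <- agg[agg$analyte == a, , drop = FALSE]
    tps <- unique(sub$timepoint)
    if (!reference %in% tps || length(tps) < 2L) next
    ok_test <- all(table(sub$timepoint) >= 2L)
    tk <- if (ok_test) {
      one_way_anova_tukey(sub$value, sub$timepoint)$tukey
    } else NULL
    ref_mean <- mean(sub$value[sub$timepoint == reference])
    for (tp in setdiff(tps, reference)) {
      m <- mean(sub$value[sub$timepoint == tp])
      l2fc <- if (ref_mean > 0 && m > 0) log2(m / ref_mean) else NA_real_
      p <- NA_real_
      if (!is.null(tk)) {
        hit <- tk$contrast %in% paste(tp, reference, sep = "-") |
          tk$contrast %in% paste(reference, tp, sep = "-")
        if (any(hit)) p <- tk$p_adj[hit][1]
      }
      out[[length(out) + 1L]] <- data.frame(
        analyte = a, timepoint = tp, log2fc = l2fc, p_tukey = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # BH across analytes within each timepoint contrast
  res$p_adjusted <- NA_real_
  for (tp in unique(res$timepoint)) {
    idx <- res$timepoint == tp
    res$p_adjusted[idx] <- stats::p.adjust(res$p_tukey[idx], method = "BH")
  }
  res$stars <- .stars(res$p_adjusted)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted <= fdr_alpha
  rownames(res) <- NULL
  res
}

#' Autoscaled principal component analysis
#'
#' Mean-centers each analyte column and divides by its standard deviation
#' (\code{scale = "sd"}, the default) or by the square root of the SD
#' (\code{scale = "sqrt_sd"}), then computes a full PCA. Zero-variance
#' columns are dropped with a warning; missing values are mean-imputed
#' within timepoint when a \code{timepoint} grouping is supplied (flagged in
#' the result), otherwise by column mean.
#'
#' @param mat numeric matrix, samples in rows, analytes in columns.
#' @param scale \code{"sd"} or \code{"sqrt_sd"}.
#' @param timepoint optional per-row grouping for imputation.
#' @return list of class \code{"nad_pca"}: scores, loadings,
#'   variance_explained (percentages summing to 100 over all components),
#'   n_imputed, dropped.
#' @export
autoscale_pca <- function(mat, scale = c("sd", "sqrt_sd"), timepoint = NULL) {
  scale <- match.arg(scale)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  if (nrow(mat) < 3L) stop("PCA needs at least 3 samples")
  n_imp <- 0L
  if (anyNA(mat)) {
    for (j in seq_len(ncol(mat))) {
      na <- is.na(mat[, j])
      if (!any(na)) next
      if (!is.null(timepoint)) {
        for (tp in unique(timepoint[na])) {
          sel <- na & timepoint == tp
          fill <- mean(mat[timepoint == tp, j], na.rm = TRUE)
          if (is.nan(fill)) fill <- mean(mat[, j], na.rm = TRUE)
          mat[sel, j] <- fill
        }
      } else {
        mat[na, j] <- mean(mat[, j], na.rm = TRUE)
      }
      n_imp <- n_imp + sum(na)
    }
  }
  sds <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  div <- if (scale == "sd") sds else sqrt(sds)
  z <- sweep(sweep(mat, 2, colMeans(mat)), 2, div, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, n_imputed = n_imp,
                 dropped = dropped),
            class = "nad_pca")
}

#' @export
print.nad_pca <- function(x, ...) {
  k <- min(4L, length(x$variance_explained))
  cat("Autoscaled PCA:", nrow(x$scores), "samples x",
      nrow(x$loadings), "analytes\n")
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.2f", seq_len(k), x$variance_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
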