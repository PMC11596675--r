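# Method-validation metrics: precision (%CV), accuracy (relative bias %),
# and stability recoveries, with the acceptance bands used in targeted
# LC-MS/MS validation.

#' Precision and accuracy from QC measurements
#'
#' Computes the coefficient of variation CV = 100 * sd / mean and relative
#' bias = 100 * (mean - nominal) / nominal for quality-control injections,
#' intraday (per day) and interday (pooled across days). SD uses the n - 1
#' denominator. Acceptance: |CV| <= 20 and |bias| <= 20 (the +/-20\% band).
#' When the endogenous matrix concentration of an analyte exceeds the QC
#' level, bias at that level is not meaningful (the added standard is
#' swamped); supply \code{matrix_conc} to have those cells skipped via
#' [skip_rule_below_matrix()].
#'
#' @param qc data.frame with columns analyte, level (nominal nM), measured
#'   (back-calculated nM) and optionally day.
#' @param matrix_conc optional named vector of endogenous matrix
#'   concentrations (nM) per analyte.
#' @param cv_limit,bias_limit acceptance limits in percent (defaults 20).
#' @return data.frame with one row per (analyte, level, scope[, day]):
#'   n, mean_measured, cv_percent, bias_percent, bias_skipped, pass.
#' @export
precision_accuracy <- function(qc, matrix_conc = NULL,
                               cv_limit = 20, bias_limit = 20) {
  stopifnot(all(c("analyte", "level", "measured") %in% names(qc)))
  if (!"day" %in% names(qc)) qc$day <- 1L
  cell <- function(x, analyte, level, scope, day = NA) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3L) warning("fewer than 3 replicates for ", analyte, " at ",
                        level, " nM (", scope, ")", call. = FALSE)
    m <- mean(x)
    cv <- if (n >= 2L && m != 0) 100 * stats::sd(x) / m else NA_real_
    mc <- if (!is.null(matrix_conc) && analyte %in% names(matrix_conc))
      matrix_conc[[analyte]] else 0
    skip <- !is.null(matrix_conc) && skip_rule_below_matrix(level, mc)
    bias <- if (skip) NA_real_ else 100 * (m - level) / level
    data.frame(analyte = analyte, level = level, scope = scope, day = day,
               n = n, mean_measured = m, cv_percent = cv,
               bias_percent = bias, bias_skipped = skip,
               pass = (is.na(cv) || abs(cv) <= cv_limit) &&
                 (is.na(bias) || abs(bias) <= bias_limit),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (a in unique(qc$analyte)) {
    for (lv in unique(qc$level[qc$analyte == a])) {
      sub <- qc[qc$analyte == a & qc$level == lv, , drop = FALSE]
      for (d in unique(sub$day)) {
        out[[length(out) + 1L]] <-
          cell(sub$measured[sub$day == d], a, lv, "intraday", d)
      }
      out[[length(out) + 1L]] <- cell(sub$measured, a, lv, "interday")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stability recovery
#'
#' Percentage recovery after a stability challenge: 100 * mean(after) /
#' mean(before), paired by analyte and level. Default acceptance band is
#' 75-120\%; for 24 h autosampler stability the report additionally
#' annotates the narrower 75-115\% band observed in routine use of this
#' panel.
#'
#' @param before,after data.frames with columns analyte, level, measured.
#' @param condition label, e.g. \code{"autosampler_24h"} or
#'   \code{"freeze_thaw_1"}.
#' @param band acceptance band, length-2 numeric in percent
#'   (default \code{c(75, 120)}).
#' @return data.frame: analyte, level, condition, recovery_percent, pass
#'   (and within_115 for autosampler conditions).
#' @export
recovery <- function(before, after, condition = "autosampler_24h",
                     band = c(75, 120)) {
  key_b <- paste(before$analyte, before$level, sep = "\r")
  key_a <- paste(after$analyte, after$level, sep = "\r")
  keys <- unique(key_b)
  out <- lapply(keys, function(k) {
    b <- mean(before$measured[key_b == k], na.rm = TRUE)
    a <- mean(after$measured[key_a == k], na.rm = TRUE)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    rec <- if (is.finite(b) && b > 0) 100 * a / b else NA_real_
    data.frame(analyte = parts[1], level = as.numeric(parts[2]),
               condition = condition, recovery_percent = rec,
               pass = !is.na(rec) && rec >= band[1] && rec <= band[2],
               flag = if (is.na(rec)) "zero_before" else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (grepl("autosampler", condition)) {
    res$within_115 <- !is.na(res$recovery_percent) &
      res$recovery_percent >= 75 & res$recovery_percent <= 115
  }
  rownames(res) <- NULL
  res
}

#' Should bias assessment be skipped at a QC level?
#'
#' TRUE when the endogenous matrix concentration strictly exceeds the QC
#' nominal level, in which case the spiked standard is a small perturbation
#' on a large background and relative bias is not determined (this applies
#' to NAD+ and NADH at the 250 nM low-QC level in E. coli matrix).
#'
#' @param qc_level nominal QC concentration (nM).
#' @param matrix_conc endogenous concentration in the matrix (nM).
#' @return logical.
#' @export
skip_rule_below_matrix <- function(qc_level, matrix_conc) {
  isTRUE(matrix_conc > qc_level)
}
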