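# Isotope-dilution response computation and matrix-matched calibration.
#
# The measured quantity is never a raw peak area but the response ratio
# (12C analyte area) / (13C internal-standard area), which cancels matrix
# ionization effects. Calibration standards are prepared in pooled biological
# matrix, so the endogenous background response is subtracted before the
# least-squares fit ("matrix-matched" calibration).

#' Compute isotope-dilution response ratios
#'
#' For every (sample, analyte) pair with both channels present, computes
#' response = area(analyte 12C) / area(ISTD 13C), where the ISTD channel is
#' the analyte's own 13C isotopologue or its surrogate's 13C channel exactly
#' as the panel specifies. Records with zero ISTD area are flagged
#' \code{"no_istd"} and carry \code{NA} responses (never infinities); they
#' are excluded downstream and their count is reported in a message.
#'
#' @param peaks an \code{"nad_peaks"} table ([read_peak_table()]).
#' @param panel an [nad_panel()] object.
#' @return data.frame: sample_id, role, level, timepoint/replicate columns
#'   when present, analyte, area, istd_channel, istd_area, response, flag.
#' @export
compute_responses <- function(peaks, panel) {
  stopifnot(inherits(panel, "nad_panel"))
  df <- as.data.frame(peaks)
  istd_of <- vapply(panel$analytes, `[[`, "", "istd")
  a12 <- df[df$label == "12C", , drop = FALSE]
  a13 <- df[df$label == "13C", , drop = FALSE]
  a12$istd_analyte <- istd_of[a12$analyte]
  key12 <- paste(a12$sample_id, a12$istd_analyte, sep = "\r")
  key13 <- paste(a13$sample_id, a13$analyte, sep = "\r")
  idx <- match(key12, key13)
  out <- data.frame(
    sample_id = a12$sample_id, role = a12$role, level = a12$level,
    analyte = a12$analyte, area = a12$area,
    istd_channel = paste0(a12$istd_analyte, "|13C"),
    istd_area = a13$area[idx],
    stringsAsFactors = FALSE
  )
  for (extra in c("timepoint", "bio_rep", "tech_rep", "day")) {
    if (extra %in% names(a12)) out[[extra]] <- a12[[extra]]
  }
  out <- out[!is.na(out$istd_area), , drop = FALSE]  # no ISTD channel at all
  out$flag <- ifelse(out$istd_area == 0, "no_istd", "")
  out$response <- ifelse(out$istd_area > 0, out$area / out$istd_area, NA_real_)
  n_bad <- sum(out$flag == "no_istd")
  if (n_bad) message(n_bad, " record(s) flagged no_istd (zero ISTD area)")
  rownames(out) <- NULL
  out
}

#' Subtract the matrix background from standard responses
#'
#' Matrix-matched calibration standards sit on top of the endogenous analyte
#' already present in the pooled matrix. The per-analyte mean response of
#' matrix-only blanks is subtracted from every standard response before
#' regression; corrected responses that would go negative are clipped at 0
#' and flagged \code{"clipped"}.
#'
#' @param responses data.frame from [compute_responses()] restricted to the
#'   rows to correct (standards).
#' @param blanks data.frame of matrix-blank responses (same layout).
#' @return \code{responses} with columns \code{response} (corrected),
#'   \code{background} and \code{flag} updated.
#' @export
subtract_matrix_background <- function(responses, blanks) {
  if (is.null(blanks) || !nrow(blanks)) {
    stop("matrix-matched correction requested but no matrix blanks supplied")
  }
  ok <- !is.na(blanks$response)
  bg <- tapply(blanks$response[ok], blanks$analyte[ok], mean)
  responses$background <- as.numeric(ifelse(is.na(bg[responses$analyte]), 0,
                                            bg[responses$analyte]))
  corrected <- responses$response - responses$background
  clip <- !is.na(corrected) & corrected < 0
  corrected[clip] <- 0
  responses$flag <- ifelse(clip, paste0(responses$flag, ";clipped"),
                           responses$flag)
  responses$response <- corrected
  responses
}

#' Fit a matrix-matched calibration curve
#'
#' Ordinary (unweighted) least-squares regression of background-corrected
#' response on nominal concentration. Duplicate injections at each level
#' enter as individual points, not averaged. The residual standard deviation
#' uses the n - 2 denominator. A negative slope marks the curve rejected
#' rather than erroring, so a batch report can show it. Optional 1/x
#' weighting is available but off by default.
#'
#' @param conc nominal concentrations (nM).
#' @param response corrected response ratios (dimensionless).
#' @param analyte analyte name carried into the object (optional).
#' @param weighting \code{"none"} (default) or \code{"1/x"}.
#' @return object of class \code{"nad_calibration"}: list with slope,
#'   intercept, r_squared, sigma (residual SD), n, lod, loq (NA until
#'   [estimate_lod_loq()] or a low-range fit fills them), rejected,
#'   matrix_matched, and the underlying \code{lm} fit.
#' @seealso [back_calculate()], [estimate_lod_loq()].
#' @examples
#' x <- rep(c(50, 100, 500, 1000, 5000, 10000), each = 2)
#' fit <- fit_calibration(x, 0.001 * x + rnorm(length(x), sd = 1e-3), "NAD+")
#' coef(fit)
#' @export
fit_calibration <- function(conc, response, analyte = "",
                            weighting = c("none", "1/x"),
                            matrix_matched = TRUE) {
  weighting <- match.arg(weighting)
  keep <- !is.na(conc) & !is.na(response)
  conc <- conc[keep]; response <- response[keep]
  if (length(unique(conc)) < 3L) {
    stop("calibration requires at least 3 distinct concentration levels")
  }
  if (stats::var(conc) == 0) stop("all calibration concentrations identical")
  w <- if (weighting == "1/x") 1 / conc else NULL
  fit <- stats::lm(response ~ conc, weights = w)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / (length(res) - 2L))
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  structure(list(
    analyte = analyte,
    slope = unname(cf[2]), intercept = unname(cf[1]),
    r_squared = r2, sigma = sigma,
    n = length(conc), levels = sort(unique(conc)),
    lod = NA_real_, loq = NA_real_,
    rejected = unname(cf[2]) <= 0,
    matrix_matched = matrix_matched,
    weighting = weighting,
    fit = fit, conc = conc, response = response
  ), class = "nad_calibration")
}

#' Slope-based limits of detection and quantification
#'
#' ICH Q2(R2) slope method on a dedicated low-concentration dilution series
#' (0.78-100 nM by default in this workflow): LOD = 3.3 sigma / S and
#' LOQ = 10 sigma / S, with S the regression slope and sigma the residual
#' standard deviation of that low-range regression. The LOQ/LOD ratio is
#' 10/3.3 by construction.
#'
#' @param conc low-range nominal concentrations (nM); at least 5 levels.
#' @param response responses at those concentrations.
#' @param curve alternatively, an already-fitted \code{"nad_calibration"}
#'   on the low-range series; its S and sigma are used directly.
#' @return list with lod, loq (nM), slope, sigma, n.
#' @examples
#' estimate_lod_loq(curve = fit_calibration(1:6, 0.001 * (1:6)))
#' @export
estimate_lod_loq <- function(conc = NULL, response = NULL, curve = NULL) {
  if (is.null(curve)) {
    if (length(unique(conc)) < 5L) {
      stop("LOD/LOQ estimation requires at least 5 low-range levels")
    }
    curve <- fit_calibration(conc, response)
  }
  if (curve$slope <= 0) stop("non-positive slope: LOD/LOQ undefined")
  list(lod = 3.3 * curve$sigma / curve$slope,
       loq = 10 * curve$sigma / curve$slope,
       slope = curve$slope, sigma = curve$sigma, n = curve$n)
}

#' Back-calculate concentration from a response
#'
#' Inverts the calibration line: x = (response - intercept) / S. Negative
#' back-calculated concentrations are reported as 0 and flagged via the
#' \code{"clipped"} attribute.
#'
#' @param response response ratio(s).
#' @param curve an accepted \code{"nad_calibration"}.
#' @return numeric concentrations (nM) with logical attribute
#'   \code{"clipped"}.
#' @export
back_calculate <- function(response, curve) {
  stopifnot(inherits(curve, "nad_calibration"))
  if (isTRUE(curve$rejected)) {
    stop("calibration curve for '", curve$analyte,
         "' was rejected (non-positive slope)")
  }
  x <- (response - curve$intercept) / curve$slope
  clip <- !is.na(x) & x < 0
  x[clip] <- 0
  attr(x, "clipped") <- clip
  x
}

#' @export
print.nad_calibration <- function(x, ...) {
  cat("Matrix-matched calibration", if (nzchar(x$analyte))
    paste0("for ", x$analyte) else "", "\n")
  cat(sprintf("  response = %.6g + %.6g * conc(nM)   (n = %d, R^2 = %.4f)\n",
              x$intercept, x$slope, x$n, x$r_squared))
  cat(sprintf("  residual SD = %.4g", x$sigma))
  if (!is.na(x$lod)) cat(sprintf(", LOD = %.4g nM, LOQ = %.4g nM", x$lod, x$loq))
  cat("\n")
  if (x$rejected) cat("  ** REJECTED: non-positive slope **\n")
  invisible(x)
}

#' @export
summary.nad_calibration <- function(object, ...) {
  out <- as.data.frame(object)
  out$linearity_ok <- object$r_squared >= 0.98
  class(out) <- c("summary.nad_calibration", "data.frame")
  out
}

#' @export
print.summary.nad_calibration <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.nad_calibration <- function(x, ...) {
  data.frame(analyte = x$analyte, slope = x$slope, intercept = x$intercept,
             r_squared = x$r_squared, sigma = x$sigma, n = x$n,
             lod = x$lod, loq = x$loq, rejected = x$rejected,
             matrix_matched = x$matrix_matched, stringsAsFactors = FALSE)
}

#' @export
coef.nad_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.nad_calibration <- function(object, ...) {
  stats::residuals(object$fit)
}

#' Predict responses or back-calculated concentrations
#'
#' \code{type = "response"} evaluates the calibration line at new
#' concentrations; \code{type = "conc"} inverts it (equivalent to
#' [back_calculate()]).
#'
#' @param object an \code{"nad_calibration"}.
#' @param newdata numeric vector (concentrations for \code{"response"},
#'   responses for \code{"conc"}); defaults to the fitting points.
#' @param type \code{"response"} or \code{"conc"}.
#' @param ... unused.
#' @export
predict.nad_calibration <- function(object, newdata = NULL,
                                    type = c("response", "conc"), ...) {
  type <- match.arg(type)
  if (type == "response") {
    x <- if (is.null(newdata)) object$conc else newdata
    object$intercept + object$slope * x
  } else {
    y <- if (is.null(newdata)) object$response else newdata
    back_calculate(y, object)
  }
}

#' @export
plot.nad_calibration <- function(x, ...) {
  graphics::plot(x$conc, x$response, xlab = "nominal concentration (nM)",
                 ylab = "response (12C/13C area ratio)",
                 main = paste("Calibration", x$analyte), ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Fit calibration curves for every analyte in a batch
#'
#' Convenience wrapper: computes responses, subtracts the matrix background
#' using blank samples, and fits one curve per quantified analyte from the
#' standard samples. When low-range points (standards at or below
#' \code{low_max} nM) are present in a separate low-range table, LOD/LOQ are
#' filled from them.
#'
#' @param peaks \code{"nad_peaks"} table containing standards and blanks.
#' @param panel panel object.
#' @param low_peaks optional \code{"nad_peaks"} table with the low-range
#'   dilution series (solvent + ISTD) used for LOD/LOQ.
#' @param matrix_matched subtract blank background (default TRUE).
#' @param weighting passed to [fit_calibration()]; \code{"1/x"} stabilizes
#'   the intercept (hence trace-level back-calculation) when the calibration
#'   spans orders of magnitude.
#' @return named list of \code{"nad_calibration"} objects.
#' @export
calibrate_batch <- function(peaks, panel, low_peaks = NULL,
                            matrix_matched = TRUE,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  resp <- compute_responses(peaks, panel)
  std <- resp[resp$role == "standard" & resp$flag == "", , drop = FALSE]
  if (matrix_matched) {
    blanks <- resp[resp$role == "blank" & resp$flag == "", , drop = FALSE]
    std <- subtract_matrix_background(std, blanks)
  }
  low <- NULL
  if (!is.null(low_peaks)) {
    lowr <- compute_responses(low_peaks, panel)
    low <- lowr[lowr$role == "standard" & lowr$flag == "", , drop = FALSE]
  }
  curves <- list()
  for (a in .quantified(panel)) {
    s <- std[std$analyte == a, , drop = FALSE]
    if (length(unique(s$level)) < 3L) next
    cv <- fit_calibration(s$level, s$response, analyte = a,
                          weighting = weighting,
                          matrix_matched = matrix_matched)
    if (!is.null(low)) {
      l <- low[low$analyte == a, , drop = FALSE]
      if (length(unique(l$level)) >= 5L && !cv$rejected) {
        ll <- estimate_lod_loq(l$level, l$response)
        cv$lod <- ll$lod; cv$loq <- ll$loq
      }
    }
    curves[[a]] <- cv
  }
  curves
}
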