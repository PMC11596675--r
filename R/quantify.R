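# From back-calculated extract concentrations (nM) to absolute intracellular
# pools (nmol per g CDW): dilution/volume correction, cell-dry-weight
# normalization, LOQ censoring and Dixon's Q outlier screening.

#' Convert an extract concentration to an intracellular pool
#'
#' amount (nmol) = conc(nM) x dilution_factor x extract_volume(L);
#' biomass (g) = cdw(g/L) x broth_volume(L); result = amount / biomass in
#' nmol per g CDW. Linear in concentration and dilution; halving CDW doubles
#' the result.
#'
#' @param extract_conc concentration in the injected extract (nM), possibly
#'   vectorized.
#' @param dilution_factor dilution applied before injection (>= 1).
#' @param extract_volume_L extraction solvent volume (L).
#' @param broth_volume_L sampled culture broth volume (L).
#' @param cdw_g_L cell dry weight of the culture (g/L).
#' @return intracellular pool(s), nmol per g CDW.
#' @examples
#' normalize_to_cdw(1000, 1, 0.0003, 0.001, 1)  # 300 nmol/gCDW
#' @export
normalize_to_cdw <- function(extract_conc, dilution_factor,
                             extract_volume_L, broth_volume_L, cdw_g_L) {
  if (any(extract_conc < 0, na.rm = TRUE)) stop("negative extract concentration")
  biomass <- cdw_g_L * broth_volume_L
  if (any(biomass <= 0)) stop("non-positive biomass (CDW x broth volume)")
  extract_conc * dilution_factor * extract_volume_L / biomass
}

#' Censor concentrations below the limit of quantification
#'
#' Censoring is applied at the extract level (nM), where the LOQ is defined,
#' before CDW normalization. Values strictly below the LOQ are flagged
#' \code{"below_loq"}; values at or above pass. Censored values are retained
#' (not zeroed) but are excluded from means and tests downstream and
#' rendered as \code{"<LOQ"} in reports.
#'
#' @param values extract concentrations (nM).
#' @param loq limit of quantification (nM), e.g. from [estimate_lod_loq()].
#' @return character vector of censoring flags (\code{"none"} /
#'   \code{"below_loq"}), same length as \code{values}.
#' @export
censor_below_loq <- function(values, loq) {
  if (is.na(loq)) return(rep("none", length(values)))
  ifelse(!is.na(values) & values < loq, "below_loq", "none")
}

# Two-tailed Dixon r10 critical values at the 95% confidence level,
# n = 3..30 (Rorabacher's recomputed tables).
.dixon_crit95 <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.526, `9` = 0.493, `10` = 0.466, `11` = 0.444, `12` = 0.426,
  `13` = 0.410, `14` = 0.396, `15` = 0.384, `16` = 0.374, `17` = 0.365,
  `18` = 0.356, `19` = 0.349, `20` = 0.342, `21` = 0.337, `22` = 0.331,
  `23` = 0.326, `24` = 0.321, `25` = 0.317, `26` = 0.312, `27` = 0.308,
  `28` = 0.305, `29` = 0.301, `30` = 0.298
)

#' Dixon's Q outlier test on a replicate group
#'
#' Two-tailed Dixon's Q (r10 statistic) at the 95\% confidence level:
#' Q = gap / range for the most extreme value (the larger of the two end
#' gaps), compared against the tabulated critical value for the group size.
#' At most one value is removed per pass; a single pass is performed, since
#' the test is defined for a single suspect value. Groups smaller than 3
#' (or with zero range) are returned unchanged, with a warning for n < 3.
#' Q is invariant under affine transforms of the data.
#'
#' @param values numeric replicate measurements (3 <= n <= 30 for a test).
#' @param alpha significance level; only 0.05 is tabulated.
#' @return list with \code{kept}, \code{removed}, \code{q} (the observed
#'   statistic, NA when no test ran) and \code{critical}.
#' @examples
#' dixon_q_filter(c(1, 2, 3, 100))  # removes 100 (Q ~ 0.980 > 0.829)
#' dixon_q_filter(c(1, 2, 3, 4))    # removes nothing (Q ~ 0.333)
#' @export
dixon_q_filter <- function(values, alpha = 0.05) {
  if (!isTRUE(all.equal(alpha, 0.05))) {
    stop("only the 95% confidence level (alpha = 0.05) is tabulated")
  }
  x <- values[!is.na(values)]
  n <- length(x)
  none <- list(kept = values, removed = numeric(0), q = NA_real_,
               critical = NA_real_)
  if (n < 3L) {
    warning("Dixon's Q requires at least 3 values; returning unchanged")
    return(none)
  }
  if (n > 30L) {
    warning("Dixon's Q tabulated only up to n = 30; returning unchanged")
    return(none)
  }
  s <- sort(x)
  rng <- s[n] - s[1]
  if (rng == 0) return(none)
  gap_low <- s[2] - s[1]
  gap_high <- s[n] - s[n - 1L]
  if (gap_high >= gap_low) {
    q <- gap_high / rng; suspect <- s[n]
  } else {
    q <- gap_low / rng; suspect <- s[1]
  }
  crit <- .dixon_crit95[[as.character(n)]]
  if (q > crit) {
    drop_idx <- which(values == suspect)[1]
    list(kept = values[-drop_idx], removed = values[drop_idx],
         q = q, critical = crit)
  } else {
    list(kept = values, removed = numeric(0), q = q, critical = crit)
  }
}

#' Quantify unknown samples end to end
#'
#' The full quantification chain for unknown (biological) samples:
#' isotope-dilution responses, back-calculation against per-analyte
#' calibration curves, LOQ censoring at the extract level, dilution/volume
#' correction and CDW normalization, and Dixon's Q outlier flagging within
#' technical-replicate groups (per analyte x timepoint x biological
#' replicate). Outliers are retained with a flag; summaries exclude them.
#'
#' @param peaks \code{"nad_peaks"} table of unknown samples.
#' @param meta sample metadata ([read_sample_meta()]).
#' @param curves named list of \code{"nad_calibration"} objects (e.g. from
#'   [calibrate_batch()]).
#' @param panel panel object.
#' @param dixon apply Dixon's Q flagging (default TRUE).
#' @return data.frame of class \code{"nad_quant"}: analyte, sample_id,
#'   timepoint, bio_rep, tech_rep, extract_nM, value (nmol per g CDW),
#'   censored, outlier, flag.
#' @export
quantify_samples <- function(peaks, meta, curves, panel, dixon = TRUE) {
  resp <- compute_responses(peaks, panel)
  resp <- resp[resp$role == "unknown" & resp$flag == "", , drop = FALSE]
  mi <- match(resp$sample_id, meta$sample_id)
  if (anyNA(mi)) stop("metadata missing for sample(s): ",
                      paste(unique(resp$sample_id[is.na(mi)]), collapse = ", "))
  rows <- list()
  for (a in intersect(unique(resp$analyte), names(curves))) {
    cv <- curves[[a]]
    if (isTRUE(cv$rejected)) next
    sub <- resp[resp$analyte == a, , drop = FALSE]
    m <- meta[match(sub$sample_id, meta$sample_id), , drop = FALSE]
    extract_nM <- back_calculate(sub$response, cv)
    cens <- censor_below_loq(as.numeric(extract_nM), cv$loq)
    # a zero-area channel has no measurable peak at all: not detected
    cens[sub$area == 0] <- "not_detected"
    value <- normalize_to_cdw(as.numeric(extract_nM), m$dilution_factor,
                              m$extract_volume_L, m$broth_volume_L,
                              m$cdw_g_L)
    rows[[a]] <- data.frame(
      analyte = a, sample_id = sub$sample_id,
      timepoint = if ("timepoint" %in% names(sub)) sub$timepoint
                  else m$timepoint %||% NA_character_,
      bio_rep = if ("bio_rep" %in% names(sub)) sub$bio_rep else NA,
      tech_rep = if ("tech_rep" %in% names(sub)) sub$tech_rep else NA,
      extract_nM = as.numeric(extract_nM), value = value,
      censored = cens, outlier = FALSE,
      flag = ifelse(attr(extract_nM, "clipped"), "clipped", ""),
      stringsAsFactors = FALSE
    )
  }
  quant <- do.call(rbind, rows)
  rownames(quant) <- NULL
  if (dixon && !is.null(quant) && nrow(quant)) {
    grp <- paste(quant$analyte, quant$timepoint, quant$bio_rep, sep = "\r")
    for (g in unique(grp)) {
      idx <- which(grp == g & quant$censored == "none")
      if (length(idx) >= 3L) {
        res <- dixon_q_filter(quant$value[idx])
        if (length(res$removed)) {
          out_idx <- idx[which(quant$value[idx] %in% res$removed)[1]]
          quant$outlier[out_idx] <- TRUE
        }
      }
    }
  }
  structure(quant, class = c("nad_quant", "data.frame"))
}

#' Summarize a quantification table
#'
#' Per analyte x timepoint means and SDs over uncensored, non-outlier
#' values, with counts of censored and outlying replicates.
#'
#' @param object an \code{"nad_quant"} table.
#' @param ... unused.
#' @export
summary.nad_quant <- function(object, ...) {
  df <- as.data.frame(object)
  keys <- unique(df[c("analyte", "timepoint")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$analyte == keys$analyte[i] &
                df$timepoint %in% keys$timepoint[i], , drop = FALSE]
    use <- sub$censored == "none" & !sub$outlier
    data.frame(analyte = keys$analyte[i], timepoint = keys$timepoint[i],
               n = sum(use),
               mean = if (any(use)) mean(sub$value[use]) else NA_real_,
               sd = if (sum(use) > 1) stats::sd(sub$value[use]) else NA_real_,
               n_censored = sum(sub$censored != "none"),
               n_outlier = sum(sub$outlier), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
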