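# CSV interfaces: TargetLynx-export-like peak tables, sample metadata, and
# result writers. One fixed dialect throughout: comma-separated, UTF-8,
# header row, "." decimal.
#
# Channel naming convention: "<analyte>|12C" for the analyte channel and
# "<analyte>|13C" for its labelled internal-standard channel; the analyte
# name is the join key against the panel.

#' Read a long-format MRM peak-area table
#'
#' Reads a CSV with one row per sample x MRM channel. Required columns:
#' \code{sample_id}, \code{channel_id}, \code{area}, \code{role}; optional:
#' \code{rt}, \code{level} (nM, for standards/QCs), \code{tech_rep},
#' \code{bio_rep}, \code{timepoint}, \code{day}. Every \code{channel_id} must
#' be of the form \code{"<analyte>|12C"} or \code{"<analyte>|13C"}; rows
#' whose analyte does not resolve against the panel are excluded from
#' quantification and reported via the \code{"unmapped"} attribute (with a
#' warning), not silently dropped. Observed retention times deviating from
#' the panel RT by more than \code{rt_tol} are flagged (\code{rt_flag}), not
#' filtered, since RT drift on column or mobile-phase change is expected.
#'
#' @param path CSV file path, or a data.frame already in the same layout.
#' @param panel an [nad_panel()] object.
#' @param rt_tol retention-time flagging tolerance in minutes (default 0.5).
#' @return data.frame of class \code{"nad_peaks"} with parsed columns
#'   \code{analyte} and \code{label} added; attribute \code{unmapped} holds
#'   any excluded rows.
#' @export
read_peak_table <- function(path, panel, rt_tol = 0.5) {
  stopifnot(inherits(panel, "nad_panel"))
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "channel_id", "area", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("peak table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(is.na(df$area)) || any(df$area < 0)) {
    stop("peak table validation error: negative or missing areas in rows ",
         paste(utils::head(which(is.na(df$area) | df$area < 0), 10),
               collapse = ", "))
  }
  dup <- duplicated(df[c("sample_id", "channel_id")])
  if (any(dup)) {
    stop("duplicate (sample_id, channel_id) pairs: ",
         paste(utils::head(paste(df$sample_id[dup], df$channel_id[dup],
                                 sep = "/"), 10), collapse = ", "))
  }
  bad_role <- !df$role %in% c("blank", "standard", "qc", "unknown")
  if (any(bad_role)) stop("unknown sample role(s): ",
                          paste(unique(df$role[bad_role]), collapse = ", "))
  if (!"level" %in% names(df)) df$level <- NA_real_
  need_level <- df$role %in% c("standard", "qc")
  if (any(need_level & (is.na(df$level) | df$level <= 0))) {
    stop("standard/QC rows must carry a positive nominal level (nM)")
  }

  parts <- strsplit(df$channel_id, "|", fixed = TRUE)
  ok_form <- lengths(parts) == 2L &
    vapply(parts, function(p) p[2] %in% c("12C", "13C"), TRUE)
  df$analyte <- vapply(parts, `[[`, "", 1)
  df$label <- ifelse(ok_form, vapply(parts, function(p) p[min(2, length(p))], ""),
                     NA_character_)
  mapped <- ok_form & df$analyte %in% names(panel$analytes)
  unmapped <- df[!mapped, , drop = FALSE]
  if (nrow(unmapped)) {
    warning(nrow(unmapped), " peak row(s) with unmapped channel(s) excluded: ",
            paste(unique(unmapped$channel_id), collapse = ", "))
  }
  df <- df[mapped, , drop = FALSE]

  if ("rt" %in% names(df)) {
    ref_rt <- vapply(panel$analytes, `[[`, 0, "retention_time")[df$analyte]
    df$rt_flag <- !is.na(df$rt) & abs(df$rt - ref_rt) > rt_tol
  } else {
    df$rt_flag <- FALSE
  }
  rownames(df) <- NULL
  structure(df, unmapped = unmapped, class = c("nad_peaks", "data.frame"))
}

#' Read per-sample metadata
#'
#' Reads the sample table carrying what is needed to convert extract
#' concentrations (nM) into intracellular pools (nmol per g CDW): required
#' columns \code{sample_id}, \code{dilution_factor} (>= 1),
#' \code{extract_volume_L}, \code{broth_volume_L}, \code{cdw_g_L}; optional
#' \code{timepoint}, \code{bio_rep}, \code{tech_rep}, \code{time_h}.
#'
#' @param path CSV path or equivalent data.frame.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "dilution_factor", "extract_volume_L",
           "broth_volume_L", "cdw_g_L")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample metadata is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(df$extract_volume_L <= 0) || any(df$broth_volume_L <= 0)) {
    stop("sample volumes must be positive")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' Write quantification results, calibration curves and a run manifest
#'
#' Writes three files into \code{out_dir}: \code{concentrations.csv} (long
#' format: analyte, sample, timepoint, value in nmol per g CDW, censoring and
#' outlier flags, with censored values rendered as \code{"<LOQ"} in a
#' display column), \code{calibration_curves.csv} (slope, intercept, R2,
#' residual SD, LOD, LOQ per analyte) and \code{run_manifest.json} (seed,
#' package version, timestamp, input hash when supplied).
#'
#' @param quant a quantification data.frame as returned by
#'   [quantify_samples()] (columns analyte, sample_id, value, censored,
#'   outlier at minimum).
#' @param curves list of \code{"nad_calibration"} objects or a data.frame of
#'   curve parameters.
#' @param out_dir output directory, created if absent.
#' @param seed,config_hash optional provenance fields for the manifest.
#' @return invisibly, named character vector of the files written.
#' @export
write_results <- function(quant, curves, out_dir, seed = NA,
                          config_hash = NA_character_) {
  if (is.null(quant) || !nrow(as.data.frame(quant))) {
    stop("empty quantification matrix: nothing to write")
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  qdf <- as.data.frame(quant)
  qdf$display <- ifelse(!is.na(qdf$censored) & qdf$censored == "below_loq",
                        "<LOQ", format(qdf$value, trim = TRUE))
  f_quant <- file.path(out_dir, "concentrations.csv")
  utils::write.csv(qdf, f_quant, row.names = FALSE)

  cdf <- if (is.data.frame(curves)) curves else
    do.call(rbind, lapply(curves, as.data.frame))
  f_curves <- file.path(out_dir, "calibration_curves.csv")
  utils::write.csv(cdf, f_curves, row.names = FALSE)

  manifest <- list(
    package = "nadomics",
    version = as.character(utils::packageVersion("nadomics")),
    seed = seed, config_hash = config_hash,
    n_analytes = length(unique(qdf$analyte)),
    n_samples = length(unique(qdf$sample_id)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  f_manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(c(concentrations = f_quant, curves = f_curves,
              manifest = f_manifest))
}
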