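# The NADome analyte registry: formulas, retention times, MRM transitions and
# the 13C internal-standard mapping for the zic-HILIC MS/MS panel.
#
# Thirteen channels are monitored; NAAD is carried for crosstalk diagnostics
# but excluded from quantification because the co-eluting, far more abundant
# NAD+ M+1 isotopologue masks its MRM channel. Five low-abundance analytes
# whose own 13C isotopologues are undetectable in labelled extract use the
# 13C channel of a structurally similar, closest-eluting analyte as surrogate
# internal standard.

.analyte <- function(name, formula, rt, rt_sd, parent, quant, ce, cone, qual,
                     istd, quantified = TRUE) {
  list(name = name, formula = formula,
       retention_time = rt, rt_sd = rt_sd,
       parent_mz = parent, quant_mz = quant, qual_mz = qual,
       cone_voltage = cone, collision_energy = ce,
       istd = istd,           # analyte whose 13C channel is ratioed against
       istd_mode = if (identical(istd, name)) "own_13C" else "surrogate",
       quantified = quantified)
}

.builtin_panel <- list(
  .analyte("NAM",    "C6H6N2O",       1.0, 0.0, 123.0,  79.7, 18, 38,  96.0, "NAM"),
  .analyte("NCA",    "C6H5NO2",       1.6, 0.2, 124.0,  80.2, 18, 38,  53.0, "NAM"),
  .analyte("1-mNAM", "C7H9N2O",       2.5, 0.2, 137.0,  78.0, 22, 24, 108.1, "NR"),
  .analyte("NR",     "C11H15N2O5",    2.9, 0.1, 255.9, 123.7,  8, 14,  80.2, "NR"),
  .analyte("FAD",    "C27H33N9O15P2", 3.2, 0.5, 786.1, 348.0, 22, 20, 439.1, "FAD"),
  .analyte("NADH",   "C21H29N7O14P2", 3.7, 0.4, 666.1, 649.0, 17, 20, 514.1, "NADH"),
  .analyte("ADPR",   "C15H23N5O14P2", 3.8, 0.3, 560.1, 136.1, 32, 26, 348.1, "NADH"),
  .analyte("NAD+",   "C21H27N7O14P2", 4.2, 0.3, 664.1, 428.0, 26, 20, 524.0, "NAD+"),
  .analyte("NAAD",   "C21H26N6O15P2", 4.5, 0.1, 665.2, 136.1, 36, 42, 428.1, "NAD+",
           quantified = FALSE),
  .analyte("NMN",    "C11H15N2O8P",   4.9, 0.2, 335.0, 123.1, 14, 22,  97.0, "NAMN"),
  .analyte("NAMN",   "C11H14NO9P",    5.1, 0.2, 336.0, 124.1, 12, 22,  97.0, "NAMN"),
  .analyte("NADPH",  "C21H30N7O17P3", 5.1, 0.2, 746.1, 729.0, 17, 20, 302.0, "NADPH"),
  .analyte("NADP+",  "C21H28N7O17P3", 5.5, 0.2, 744.1, 604.0, 20, 20, 508.0, "NADP+")
)
names(.builtin_panel) <- vapply(.builtin_panel, `[[`, "", "name")

.validate_panel <- function(analytes) {
  nm <- vapply(analytes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate analyte names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  for (a in analytes) {
    for (f in c("name", "formula", "retention_time", "parent_mz", "quant_mz",
                "istd")) {
      if (is.null(a[[f]])) {
        stop("panel configuration error: analyte '", a$name %||% "?",
             "' is missing field '", f, "'")
      }
    }
    if (a$retention_time <= 0) {
      stop("panel configuration error: non-positive retention time for '",
           a$name, "'")
    }
    if (a$quant_mz >= a$parent_mz) {
      stop("panel configuration error: product m/z must be below parent m/z",
           " for '", a$name, "'")
    }
    parse_formula(a$formula)
    if (!a$istd %in% nm) {
      stop("panel configuration error: analyte '", a$name,
           "' references unknown surrogate ISTD '", a$istd, "'")
    }
  }
  # a surrogate must point at an analyte that carries its own 13C channel
  for (a in analytes) {
    if (a$istd != a$name && analytes[[a$istd]]$istd != a$istd) {
      stop("panel configuration error: surrogate ISTD '", a$istd,
           "' for '", a$name, "' has no own 13C channel")
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The NADome MRM analyte panel
#'
#' Returns the built-in thirteen-channel panel: twelve quantified analytes of
#' the NAD biosynthesis/utilization network (NAM, NCA, 1-mNAM, NR, FAD, NADH,
#' ADPR, NAD+, NMN, NAMN, NADPH, NADP+) plus the NAAD channel, which is
#' monitored but flagged non-quantified because of NAD+ M+1 crosstalk.
#' Each analyte carries its molecular formula, mean retention time with
#' inter-run SD, quantifier and qualifier MRM transitions (ESI positive), and
#' its internal-standard mapping: either its own uniformly-13C-labelled
#' isotopologue channel or the 13C channel of a surrogate analyte
#' (NCA uses NAM-13C, 1-mNAM uses NR-13C, ADPR uses NADH-13C, NAAD uses
#' NAD+-13C, NMN uses NAMN-13C).
#'
#' @return object of class \code{"nad_panel"}: list with element
#'   \code{analytes}, a named list of analyte definitions.
#' @seealso [load_panel()] to read a customized panel from YAML,
#'   [crosstalk_scan()] for channel-interference screening.
#' @examples
#' p <- nad_panel()
#' sum(vapply(p$analytes, `[[`, TRUE, "quantified"))  # 12
#' @export
nad_panel <- function() {
  .validate_panel(.builtin_panel)
  structure(list(analytes = .builtin_panel), class = "nad_panel")
}

#' Load an analyte panel from a YAML configuration
#'
#' Reads a panel definition file with one block per analyte (fields:
#' \code{name}, \code{formula}, \code{retention_time}, \code{rt_sd},
#' \code{parent_mz}, \code{quant_mz}, \code{qual_mz}, \code{cone_voltage},
#' \code{collision_energy}, \code{istd}, \code{quantified}) and validates it:
#' unique names, positive retention times, product below parent m/z,
#' parseable formulas, and referential integrity of surrogate internal
#' standards. With \code{path = NULL} the built-in panel is returned.
#'
#' @param path YAML file path, or \code{NULL} for the built-in panel.
#' @return an \code{"nad_panel"} object.
#' @export
load_panel <- function(path = NULL) {
  if (is.null(path)) return(nad_panel())
  if (!file.exists(path)) stop("panel configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$analytes)) raw <- raw$analytes
  analytes <- lapply(raw, function(a) {
    a$rt_sd <- a$rt_sd %||% 0
    a$qual_mz <- a$qual_mz %||% NA_real_
    a$cone_voltage <- a$cone_voltage %||% NA_real_
    a$collision_energy <- a$collision_energy %||% NA_real_
    a$istd <- a$istd %||% a$name
    a$quantified <- a$quantified %||% TRUE
    a$istd_mode <- if (identical(a$istd, a$name)) "own_13C" else "surrogate"
    a
  })
  names(analytes) <- vapply(analytes, function(a) a$name %||%
                              stop("panel configuration error: unnamed analyte"),
                            "")
  .validate_panel(analytes)
  structure(list(analytes = analytes), class = "nad_panel")
}

#' @export
print.nad_panel <- function(x, ...) {
  n_q <- sum(vapply(x$analytes, `[[`, TRUE, "quantified"))
  cat("NADome MRM panel:", n_q, "quantified analytes (",
      length(x$analytes), "monitored channels )\n")
  df <- as.data.frame.nad_panel(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.nad_panel <- function(x, ...) {
  data.frame(
    analyte = vapply(x$analytes, `[[`, "", "name"),
    formula = vapply(x$analytes, `[[`, "", "formula"),
    rt_min = vapply(x$analytes, `[[`, 0, "retention_time"),
    parent_mz = vapply(x$analytes, `[[`, 0, "parent_mz"),
    quant_mz = vapply(x$analytes, `[[`, 0, "quant_mz"),
    istd = vapply(x$analytes, `[[`, "", "istd"),
    istd_mode = vapply(x$analytes, `[[`, "", "istd_mode"),
    quantified = vapply(x$analytes, `[[`, TRUE, "quantified"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# names of quantified analytes
.quantified <- function(panel) {
  names(panel$analytes)[vapply(panel$analytes, `[[`, TRUE, "quantified")]
}

#' Reference sensitivity of the validated method
#'
#' LOD and LOQ values (nM) per analyte from the method's original slope-based
#' validation (low-range calibration in solvent with 10\% ISTD), shipped as
#' reference metadata. Useful as realistic censoring thresholds for the
#' simulator and for regression-testing the LOQ = LOD x 10/3.3 relationship
#' that the slope method enforces by construction.
#'
#' @return data.frame with columns analyte, r2_solvent, r2_matrix, lod_nM,
#'   loq_nM.
#' @export
nad_reference_sensitivity <- function() {
  data.frame(
    analyte = c("NAM", "NCA", "1-mNAM", "NR", "FAD", "NADH", "ADPR", "NAD+",
                "NMN", "NAMN", "NADPH", "NADP+"),
    r2_solvent = c(1.00, 1.00, 1.00, 1.00, 1.00, 0.99, 0.98, 1.00, 1.00,
                   1.00, 0.99, 1.00),
    r2_matrix = c(0.99, 0.99, 0.99, 1.00, 0.99, 0.99, 0.99, 0.98, 1.00,
                  1.00, 0.99, 0.99),
    lod_nM = c(26.73, 11.77, 4.02, 5.64, 6.74, 57.14, 1.52, 3.96, 3.79,
               5.38, 29.47, 16.67),
    loq_nM = c(80.98, 35.68, 12.19, 17.11, 20.43, 173.15, 4.61, 11.99, 11.48,
               16.32, 89.29, 50.51),
    stringsAsFactors = FALSE
  )
}
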