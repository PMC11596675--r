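# Natural-abundance isotopologue distributions and MRM crosstalk screening.
#
# A triple-quadrupole MRM channel resolves only unit (nominal) masses, so the
# per-element isotope fine structure is collapsed to nominal mass shifts
# M+0, M+1, ... before any comparison between channels.

# Per-element natural isotope abundances (IUPAC representative values).
# Each entry: numeric vector of abundances indexed by nominal mass shift
# starting at 0. Phosphorus is monoisotopic.
.isotope_table <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = c(1)
)

# convolve two shift-indexed abundance vectors, truncating at max_shift
.conv_trunc <- function(a, b, max_shift) {
  out <- numeric(max_shift + 1L)
  for (i in seq_along(a)) {
    jmax <- min(length(b), max_shift + 2L - i)
    if (jmax >= 1L) {
      idx <- i + seq_len(jmax) - 1L
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
  }
  out
}

# n-fold self-convolution by exponentiation-by-squaring
.conv_pow <- function(a, n, max_shift) {
  res <- c(1, numeric(max_shift))
  base <- c(a, numeric(max(0L, max_shift + 1L - length(a))))[1:(max_shift + 1L)]
  while (n > 0L) {
    if (n %% 2L == 1L) res <- .conv_trunc(res, base, max_shift)
    base <- .conv_trunc(base, base, max_shift)
    n <- n %/% 2L
  }
  res
}

#' Natural-abundance isotopologue distribution of a molecule
#'
#' Computes the probability that a molecule of the given formula carries a
#' total nominal mass excess of 0, 1, ..., \code{max_shift} Da over the
#' monoisotopic species, by exact convolution of per-element binomial /
#' multinomial isotope distributions (13C 1.07\%, 2H 0.0115\%, 15N 0.364\%,
#' 17O 0.038\%, 18O 0.205\%, P monoisotopic). Fractions are reported on the
#' all-molecules scale, i.e. they sum to at most 1; the truncated tail beyond
#' \code{max_shift} is the missing mass.
#'
#' For NAD+ (C21H27N7O14P2) the M+1 species is about 26\% of M+0, which is
#' why its natural M+1 signal can bleed into the MRM channel of an analyte
#' one nominal mass unit heavier (NAAD at 665.2) when the two co-elute.
#'
#' @param formula molecular formula string or named count vector
#'   (see [parse_formula()]).
#' @param max_shift largest nominal shift K to compute (default 3; M+2 is
#'   needed for channels two mass units apart, M+3 is negligible for
#'   panel-sized molecules).
#' @param abundances optional replacement isotope table, a named list of
#'   shift-indexed abundance vectors, to override the built-in constants.
#' @return object of class \code{"isotopologue_distribution"}: a list with
#'   \code{fractions} (length \code{max_shift + 1}, names \code{"M+0"} ...),
#'   \code{formula}, and \code{max_shift}.
#' @examples
#' d <- isotopologue_distribution("C21H27N7O14P2")
#' d$fractions[["M+1"]] / d$fractions[["M+0"]]  # ~0.26
#' @export
isotopologue_distribution <- function(formula, max_shift = 3L,
                                      abundances = NULL) {
  stopifnot(max_shift >= 1L)
  tab <- .isotope_table
  if (!is.null(abundances)) tab[names(abundances)] <- abundances
  counts <- parse_formula(formula)
  frac <- c(1, numeric(max_shift))
  for (el in names(counts)) {
    a <- tab[[el]]
    if (is.null(a)) stop("no isotope data for element: ", el)
    frac <- .conv_trunc(frac, .conv_pow(a, counts[[el]], max_shift), max_shift)
  }
  names(frac) <- paste0("M+", 0:max_shift)
  structure(
    list(fractions = frac, formula = counts, max_shift = as.integer(max_shift)),
    class = "isotopologue_distribution"
  )
}

#' @export
print.isotopologue_distribution <- function(x, ...) {
  cat("Isotopologue distribution (",
      paste0(names(x$formula), x$formula, collapse = ""), ")\n", sep = "")
  print(round(x$fractions, 6))
  cat("M+1/M+0 =", format(x$fractions[[2]] / x$fractions[[1]], digits = 5), "\n")
  invisible(x)
}

#' Ratio of the M+k to the monoisotopic species
#'
#' Convenience accessor: the relative abundance of the M+k isotopologue as a
#' fraction of M+0 (the quantity that determines crosstalk into a channel k
#' nominal mass units heavier).
#'
#' @param formula molecular formula (string or named counts).
#' @param k nominal mass shift (default 1).
#' @inheritParams isotopologue_distribution
#' @return a single number, M+k / M+0.
#' @export
isotope_ratio <- function(formula, k = 1L, abundances = NULL) {
  d <- isotopologue_distribution(formula, max_shift = max(1L, k),
                                 abundances = abundances)
  unname(d$fractions[k + 1L] / d$fractions[1L])
}

#' Screen an analyte panel for MRM isotopologue crosstalk
#'
#' For every ordered pair of panel analytes, flags the target channel as at
#' risk of natural-abundance bleed-through when (a) the source parent m/z
#' plus some shift k in 1..K falls within \code{mz_tol} of the target parent
#' m/z, and (b) the two retention times are within \code{rt_window}. The
#' predicted relative interference is the source M+k abundance expressed as a
#' fraction of its M+0 signal. With the built-in panel this reproduces the
#' NAD+ (664.1, 4.2 min) into NAAD (665.2, 4.5 min) bleed-through at k = 1
#' with ~26\% interference.
#'
#' Flagging is diagnostic only: quantification does not attempt to unmix
#' flagged channels (crosstalk-masked analytes are instead excluded from the
#' quantified panel).
#'
#' @param panel an [nad_panel()] object.
#' @param mz_tol parent m/z match tolerance in Da (default 0.5, unit-mass
#'   quadrupole selection).
#' @param rt_window co-elution window in minutes (default 0.5).
#' @param max_shift largest isotopologue shift considered (default 3).
#' @return data.frame with one row per flag: source, target, mass_shift,
#'   mz_gap (Da, target minus shifted source), rt_gap (min), interference.
#' @export
crosstalk_scan <- function(panel, mz_tol = 0.5, rt_window = 0.5,
                           max_shift = 3L) {
  stopifnot(inherits(panel, "nad_panel"), mz_tol > 0, rt_window > 0)
  an <- panel$analytes
  ratios <- lapply(an, function(a) {
    d <- isotopologue_distribution(a$formula, max_shift = max_shift)
    d$fractions / d$fractions[[1]]
  })
  names(ratios) <- names(an)
  out <- list()
  for (src in names(an)) {
    for (tgt in names(an)) {
      if (src == tgt) next
      dmz <- an[[tgt]]$parent_mz - an[[src]]$parent_mz
      drt <- an[[tgt]]$retention_time - an[[src]]$retention_time
      if (abs(drt) > rt_window) next
      for (k in seq_len(max_shift)) {
        if (abs(dmz - k) <= mz_tol) {
          out[[length(out) + 1L]] <- data.frame(
            source = src, target = tgt, mass_shift = k,
            mz_gap = dmz - k, rt_gap = drt,
            interference = ratios[[src]][[k + 1L]],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(source = character(), target = character(),
                      mass_shift = integer(), mz_gap = numeric(),
                      rt_gap = numeric(), interference = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
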