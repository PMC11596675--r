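#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula string (e.g. \code{"C21H27N7O14P2"})
#' into a named integer vector of element counts. Only elements for which
#' natural-abundance isotope data are carried (C, H, N, O, P) are accepted,
#' because downstream isotopologue computations need abundance constants for
#' every atom present.
#'
#' @param x a single formula string, or an already-parsed named numeric
#'   vector (returned unchanged after validation).
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C6H6N2O")      # nicotinamide
#' parse_formula("C21H27N7O14P2") # NAD+
#' @export
parse_formula <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L, nzchar(x))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
    if (sum(nchar(toks)) != nchar(x)) {
      stop("cannot parse molecular formula: '", x, "'")
    }
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(n == "", 1L, suppressWarnings(as.integer(n)))
    names(counts) <- el
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  bad <- setdiff(names(counts), names(.isotope_table))
  if (length(bad)) {
    stop("unknown element symbol(s) in formula: ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative element counts are not allowed")
  if (sum(counts) == 0) stop("empty molecular formula")
  counts[counts > 0]
}
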