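# Modified Ashworth Scale levels and label handling.

.MAS_LEVELS <- c("0", "1", "1+", "2", "3", "4")

#' The six Modified Ashworth Scale grades
#'
#' Ordered grades of the Modified Ashworth Scale (MAS), the ordinal clinical
#' scale for spasticity severity: `"0" < "1" < "1+" < "2" < "3" < "4"`.
#'
#' @return Character vector of the six admissible grades, in scale order.
#' @export
#' @examples
#' mas_levels()
mas_levels <- function() .MAS_LEVELS

#' Coerce to a MAS label factor
#'
#' Validates values against the six admissible MAS grades and returns an
#' ordered factor. `NA` input stays `NA`; any other value outside the scale
#' is an error.
#'
#' @param x Character (or factor) vector of MAS grades.
#' @return Ordered factor with levels `mas_levels()`.
#' @export
#' @examples
#' as_mas(c("1+", "0", "4"))
as_mas <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% .MAS_LEVELS)
  if (any(bad)) {
    stop("invalid MAS label(s): ", paste(unique(x[bad]), collapse = ", "),
         "; admissible grades are ", paste(.MAS_LEVELS, collapse = ", "))
  }
  factor(x, levels = .MAS_LEVELS, ordered = TRUE)
}
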