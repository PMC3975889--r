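# The nine 120 x 120 degree rotamer sections tiling (chi1, chi2) space.
#
# chi classes: g+ = [0,120), t = [120,240), g- = [240,360).  Sections are
# numbered row-major with chi1 columns (g+, t, g-) and chi2 rows from g-
# (top) to g+ (bottom):
#     1 = (g+, g-)  2 = (t, g-)  3 = (g-, g-)
#     4 = (g+, t )  5 = (t, t )  6 = (g-, t )
#     7 = (g+, g+)  8 = (t, g+)  9 = (g-, g+)
# so that e.g. (293, 162) falls in section 6 and (300, 60) in section 9.
# The layout lives in this one table; boundaries are half-open [lo, hi).

CHI_CLASSES <- c("g+", "t", "g-")

#' The nine-section layout of chi1/chi2 rotamer space
#'
#' @return data.frame with one row per section: `section`, `chi1_class`,
#'   `chi2_class` and the half-open `[lo, hi)` bounds of each axis.
#' @export
rotamer_sections <- function() {
  chi1_col <- rep(1:3, times = 3)          # g+, t, g- left to right
  chi2_row <- rep(c(3, 2, 1), each = 3)    # g- top row, g+ bottom row
  data.frame(
    section = 1:9,
    chi1_class = CHI_CLASSES[chi1_col],
    chi2_class = CHI_CLASSES[chi2_row],
    chi1_lo = (chi1_col - 1) * 120, chi1_hi = chi1_col * 120,
    chi2_lo = (chi2_row - 1) * 120, chi2_hi = chi2_row * 120,
    stringsAsFactors = FALSE
  )
}

#' Section index of chi1/chi2 pairs
#'
#' Vectorized classification into the nine sections; boundary angles
#' belong to the lower-edge-inclusive cell, so (0, 0) is section 7.
#'
#' @param chi1,chi2 torsions in degrees (wrapped into `[0, 360)`).
#' @return integer vector of section indices 1-9.
#' @export
section_of <- function(chi1, chi2) {
  if (any(!is.finite(chi1)) || any(!is.finite(chi2))) {
    stop("section_of: non-finite angle")
  }
  c1 <- floor(wrap360(chi1) / 120)
  c2 <- floor(wrap360(chi2) / 120)
  as.integer((2 - c2) * 3 + c1 + 1)
}
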