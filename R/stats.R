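# Resolution-binned rotamer statistics: 2D torsion histograms, per-section
# population fractions and binned circular means with standard errors.

#' Two-dimensional chi1/chi2 histogram
#'
#' Counts observations on a regular grid over `[0, 360)^2` (rows follow
#' chi1, columns chi2) plus a log-scaled render grid, `log(1 + count)`
#' normalized to `[0, 1]`, for black-to-white display.
#'
#' @param chi1,chi2 torsions in degrees, or a data.frame with `chi1` and
#'   `chi2` columns as first argument.
#' @param bin bin width in degrees; must divide 360.
#' @return list with `counts`, `render`, `bin` and the bin `breaks`.
#' @export
histogram2d <- function(chi1, chi2 = NULL, bin = 1) {
  if (is.data.frame(chi1)) {
    chi2 <- chi1$chi2
    chi1 <- chi1$chi1
  }
  if (360 %% bin != 0) stop("bin width must divide 360")
  n <- as.integer(360 / bin)
  i <- floor(wrap360(chi1) / bin) + 1
  j <- floor(wrap360(chi2) / bin) + 1
  counts <- matrix(tabulate((j - 1) * n + i, nbins = n * n), n, n)
  lg <- log1p(counts)
  rng <- range(lg)
  render <- if (diff(rng) > 0) (lg - rng[1L]) / diff(rng) else lg * 0
  list(counts = counts, render = render, bin = bin, breaks = seq(0, 360, bin))
}

resolution_bin_mid <- function(res, bin) (floor(res / bin) + 0.5) * bin

#' Per-section population fractions by resolution bin
#'
#' For each grouping class (secondary structure by default) and resolution
#' bin, the percentage of observations falling in each requested section.
#' Bins whose group denominator is below `min_count` are suppressed.
#'
#' @param obs observation data.frame with `section`, `resolution` and the
#'   grouping column.
#' @param sections sections to report (the denominator always spans all
#'   nine).
#' @param bin resolution bin width in Angstrom.
#' @param group name of the grouping column.
#' @param min_count minimum observations per (group, bin).
#' @return data.frame with `group`, `res_bin`, `n_bin`, `section`,
#'   `fraction` (percent).
#' @export
fraction_by_resolution <- function(obs, sections = 1:9, bin = 0.1,
                                   group = "ss", min_count = 50) {
  obs <- obs[is.finite(obs$resolution) & !is.na(obs$section), , drop = FALSE]
  obs$res_bin <- resolution_bin_mid(obs$resolution, bin)
  obs$.group <- obs[[group]]
  denom <- dplyr::count(obs, .data$.group, .data$res_bin, name = "n_bin")
  num <- dplyr::count(obs, .data$.group, .data$res_bin, .data$section,
                      name = "n_sec")
  out <- dplyr::inner_join(num, denom, by = c(".group", "res_bin"))
  out <- out[out$n_bin >= min_count & out$section %in% sections, , drop = FALSE]
  out$fraction <- 100 * out$n_sec / out$n_bin
  names(out)[names(out) == ".group"] <- group
  out[order(out[[group]], out$res_bin, out$section), , drop = FALSE]
}

#' Binned mean torsion angles by resolution
#'
#' Mean and standard error of chi1 or chi2 per resolution bin within
#' grouping keys (section and secondary-structure subclass by default;
#' refinement program or year class can be added).  Because a section
#' spans a contiguous 120 degree interval of `[0, 360)` and observed
#' spreads are far below 60 degrees, plain means in the section frame are
#' used rather than full circular statistics.  Rows with fewer than
#' `min_count` observations are suppressed.
#'
#' @param obs observation data.frame.
#' @param angle `"chi1"` or `"chi2"`.
#' @param group_vars grouping column names (besides the resolution bin).
#' @param bin resolution bin width in Angstrom.
#' @param min_count minimum observations per emitted row.
#' @return data.frame with the group keys, `res_bin`, `n`, `mean`, `sem`.
#' @export
mean_angle_by_resolution <- function(obs, angle = c("chi1", "chi2"),
                                     group_vars = c("section", "ss"),
                                     bin = 0.2, min_count = 50) {
  angle <- match.arg(angle)
  obs <- obs[is.finite(obs$resolution) & is.finite(obs[[angle]]), , drop = FALSE]
  obs$res_bin <- resolution_bin_mid(obs$resolution, bin)
  obs$.angle <- obs[[angle]]
  out <- dplyr::summarise(
    dplyr::group_by(obs, dplyr::across(dplyr::all_of(c(group_vars, "res_bin")))),
    n = dplyr::n(),
    mean = mean(.data$.angle),
    sem = stats::sd(.data$.angle) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  out <- out[out$n >= min_count, , drop = FALSE]
  as.data.frame(out[do.call(order, out[c(group_vars, "res_bin")]), , drop = FALSE])
}
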