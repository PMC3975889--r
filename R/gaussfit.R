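# Two-dimensional Gaussian fits of per-section chi1/chi2 histograms,
# giving the local optimum (mu1, mu2) and the two-dimensional spread of
# each rotamer section.

#' Fit a 2D Gaussian to one rotamer section of a chi1/chi2 histogram
#'
#' Nonlinear least squares of
#' `background + amplitude * exp(-q/2)` against the bin counts of one
#' 120 x 120 degree section, where `q` is the correlated quadratic form in
#' `(chi1 - mu1, chi2 - mu2)` with spreads `sigma1`, `sigma2` and
#' correlation `rho`.  Starting values come from the background-subtracted
#' weighted centroid and second moments.  On non-convergence (or a peak
#' indistinguishable from the Poisson noise of the background) the fit is
#' flagged and the centroid is returned as a fallback optimum.
#'
#' @param hist result of [histogram2d()] (or a compatible list with
#'   `counts` and `bin`).
#' @param section section index 1-9.
#' @param min_counts minimum total counts required in the section.
#' @return list with `mu1`, `mu2`, `sigma1`, `sigma2`, `rho`, `amplitude`,
#'   `background`, `n`, `converged`.
#' @export
fit_section_gaussian <- function(hist, section, min_counts = 200) {
  sec <- rotamer_sections()
  sec <- sec[sec$section == section, ]
  bin <- hist$bin
  i_rng <- seq.int(sec$chi1_lo / bin + 1L, sec$chi1_hi / bin)
  j_rng <- seq.int(sec$chi2_lo / bin + 1L, sec$chi2_hi / bin)
  z <- hist$counts[i_rng, j_rng, drop = FALSE]
  ntot <- sum(z)
  if (ntot < min_counts) stop("section holds fewer counts than min_counts")
  x <- (i_rng - 0.5) * bin
  y <- (j_rng - 0.5) * bin
  d <- data.frame(x = rep(x, times = length(y)),
                  y = rep(y, each = length(x)),
                  z = as.vector(z))
  bg0 <- stats::median(d$z)
  w <- pmax(d$z - bg0, 0)
  if (sum(w) == 0) w <- d$z + 1e-9
  mu1_0 <- sum(w * d$x) / sum(w)
  mu2_0 <- sum(w * d$y) / sum(w)
  s1_0 <- sqrt(max(sum(w * (d$x - mu1_0)^2) / sum(w), 1))
  s2_0 <- sqrt(max(sum(w * (d$y - mu2_0)^2) / sum(w), 1))
  rho_0 <- sum(w * (d$x - mu1_0) * (d$y - mu2_0)) / (sum(w) * s1_0 * s2_0)
  rho_0 <- max(min(rho_0, 0.9), -0.9)
  a_0 <- max(max(d$z) - bg0, 1)
  centroid <- list(mu1 = mu1_0, mu2 = mu2_0, sigma1 = s1_0, sigma2 = s2_0,
                   rho = rho_0, amplitude = a_0, background = bg0,
                   n = ntot, converged = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ bg + A * exp(-0.5 / (1 - rho^2) *
                         (((x - mu1) / s1)^2 - 2 * rho * (x - mu1) * (y - mu2) / (s1 * s2) +
                            ((y - mu2) / s2)^2)),
      data = d,
      start = list(bg = bg0, A = a_0, mu1 = mu1_0, mu2 = mu2_0,
                   s1 = s1_0, s2 = s2_0, rho = rho_0),
      lower = c(0, 0, sec$chi1_lo, sec$chi2_lo, bin / 2, bin / 2, -0.95),
      upper = c(Inf, Inf, sec$chi1_hi, sec$chi2_hi, 120, 120, 0.95),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(centroid)
  p <- as.list(stats::coef(fit))
  # peak must stand above the Poisson noise floor of the background
  significant <- p$A > 3 * sqrt(p$bg + 1)
  list(mu1 = p$mu1, mu2 = p$mu2, sigma1 = p$s1, sigma2 = p$s2, rho = p$rho,
       amplitude = p$A, background = p$bg, n = ntot,
       converged = isTRUE(significant))
}
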