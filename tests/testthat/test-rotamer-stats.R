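test_that("section_of reproduces the published anchors and boundaries", {
  expect_equal(section_of(293, 162), 6L)   # chi1 g-, chi2 t
  expect_equal(section_of(300, 60), 9L)    # gauche-, gauche+
  expect_equal(section_of(0, 0), 7L)       # lower-edge-inclusive cell
  expect_equal(section_of(60, 300), 1L)
  expect_equal(section_of(180, 180), 5L)
  expect_error(section_of(NA, 10), "non-finite")
})

test_that("section_of agrees with the brute-force classifier", {
  set.seed(21)
  chi1 <- c(runif(500, 0, 360), c(0, 119.999, 120, 239.999, 240, 359.999))
  chi2 <- c(runif(500, 0, 360), c(0, 120, 240, 359.999, 119.999, 239.999))
  brute <- mapply(oracle_section, chi1, chi2)
  expect_equal(section_of(chi1, chi2), unname(brute))
})

test_that("the nine sections tile rotamer space exactly", {
  sec <- rotamer_sections()
  expect_equal(sort(sec$section), 1:9)
  area <- sum((sec$chi1_hi - sec$chi1_lo) * (sec$chi2_hi - sec$chi2_lo))
  expect_equal(area, 360^2)
  expect_equal(sec$section[sec$chi1_class == "g-" & sec$chi2_class == "t"], 6L)
  expect_equal(sec$section[sec$chi1_class == "g-" & sec$chi2_class == "g+"], 9L)
})

test_that("B-factor criterion accepts absolute or relative passes", {
  cand <- data.frame(
    entry_id = "X", chain_id = "A", seq_num = 1:3,
    chi1 = 293, chi2 = 162, phi = -57, psi = -47,
    ss = "H", ss_source = "builtin", phipsi_class = "helical",
    subclass = "H", resolution = 1.5, program = "REFMAC", year = 2010L,
    method = "X-RAY DIFFRACTION", is_terminal = FALSE,
    next_to_terminus = FALSE, neighbor_gly_pro = FALSE,
    neighbor_noncanonical = FALSE, complete = TRUE,
    b_max_atom = c(59.9, 70, 80), mean_ca_b = c(10, 30, 30),
    min_occ = 1, bad_bond = FALSE, clash = FALSE, section = 6L,
    stringsAsFactors = FALSE
  )
  res <- apply_filters(cand)
  # 59.9 < 60 passes; 70 < 2.5*30 = 75 passes; 80 fails both
  expect_equal(res$observations$seq_num, 1:2)
  expect_equal(res$audit$reason, "b_factor")
  expect_equal(res$audit$seq_num, 3L)
})

test_that("residues next to Gly/Pro or a terminus are rejected with reasons", {
  ch <- build_ideal_secondary("helix", n = 9, ile_pos = 5)
  ch[[6]]$res_name <- "PRO"   # neighbour becomes proline
  parsed <- list(chains = list(A = ch),
                 meta = list(entry_id = "T1", resolution = 1.8,
                             method = "X-RAY DIFFRACTION",
                             programs = "REFMAC", mixed_programs = FALSE,
                             year = 2010L))
  cand <- extract_ile_observations(parsed)
  res <- apply_filters(cand)
  expect_equal(nrow(res$observations), 0L)
  expect_equal(res$audit$reason, "neighbor")
  # non-X-ray entries are rejected up front
  parsed$meta$method <- "SOLUTION NMR"
  parsed$chains$A[[6]]$res_name <- "ALA"
  res2 <- apply_filters(extract_ile_observations(parsed))
  expect_equal(res2$audit$reason, "method")
})

test_that("apply_filters is order-independent", {
  spec <- synthetic_spec(n_ile = 60, violation_rate = 0.2)
  gen <- generate_dataset(spec, seed = 5)
  cand <- do.call(rbind, lapply(gen$structures, extract_ile_observations))
  fwd <- apply_filters(cand)
  perm <- cand[rev(seq_len(nrow(cand))), ]
  bwd <- apply_filters(perm)
  key <- function(d) sort(paste(d$entry_id, d$seq_num))
  expect_equal(key(fwd$observations), key(bwd$observations))
  expect_equal(key(fwd$audit), key(bwd$audit))
})

test_that("histogram2d conserves counts and renders on a log scale", {
  h <- histogram2d(c(60.2, 60.3, 60.4), c(60.2, 60.3, 60.4), bin = 1)
  expect_equal(sum(h$counts), 3)
  expect_equal(h$counts[61, 61], 3)
  expect_equal(max(h$render), 1)
  set.seed(9)
  h2 <- histogram2d(runif(5000, 0, 360), runif(5000, 0, 360), bin = 5)
  expect_equal(sum(h2$counts), 5000)
  expect_error(histogram2d(1, 1, bin = 7), "divide")
})

test_that("uniform input spreads counts evenly over the nine sections", {
  set.seed(10)
  n <- 18000
  chi1 <- runif(n, 0, 360)
  chi2 <- runif(n, 0, 360)
  counts <- table(factor(section_of(chi1, chi2), levels = 1:9))
  expval <- n / 9
  sdev <- sqrt(n * (1 / 9) * (8 / 9))
  expect_true(all(abs(counts - expval) < 3 * sdev))
})

test_that("fractions are ratios per bin, suppressed below the count floor", {
  obs <- data.frame(
    section = c(rep(6L, 12), rep(5L, 88), rep(6L, 30), rep(5L, 19)),
    resolution = c(rep(1.55, 100), rep(2.05, 49)),
    ss = "H", stringsAsFactors = FALSE
  )
  fr <- fraction_by_resolution(obs, bin = 0.1, min_count = 50)
  expect_equal(fr$fraction[fr$section == 6], 12)
  expect_false(any(fr$res_bin > 2))        # 49-observation bin suppressed
  expect_equal(sum(fr$fraction[fr$res_bin < 1.6]), 100)
})

test_that("binned means recover degenerate and dispersed populations", {
  obs <- data.frame(section = 6L, ss = "H", chi1 = 293, chi2 = 162,
                    resolution = 1.7, stringsAsFactors = FALSE)[rep(1, 50), ]
  m <- mean_angle_by_resolution(obs, "chi1")
  expect_equal(m$mean, 293)
  expect_equal(m$sem, 0)
  set.seed(4)
  big <- data.frame(section = 6L, ss = "H",
                    chi1 = rnorm(5000, 293, 8), chi2 = rnorm(5000, 162, 8),
                    resolution = runif(5000, 1.6, 1.8))
  m2 <- mean_angle_by_resolution(big, "chi1")
  expect_true(all(abs(m2$mean - 293) < 2 * m2$sem + 1e-9))
  expect_true(all(m2$n >= 50))
})

test_that("grouping by program separates two target populations", {
  set.seed(5)
  obs <- data.frame(
    section = 6L, ss = "H",
    program = rep(c("REFMAC", "CNS"), each = 2000),
    chi1 = c(rnorm(2000, 288, 4), rnorm(2000, 298, 4)),
    chi2 = 162, resolution = 2.5
  )
  m <- mean_angle_by_resolution(obs, "chi1", group_vars = c("section", "program"))
  expect_equal(nrow(m), 2L)
  d <- diff(m$mean[order(m$program)])   # CNS first alphabetically
  expect_lt(abs(abs(d) - 10), 1)
})

test_that("the 2D Gaussian fit recovers a known generative optimum", {
  set.seed(6)
  xy <- rmvn2(10000, c(293, 162), 8, 10, 0.3)
  f <- fit_section_gaussian(histogram2d(xy[, 1], xy[, 2]), 6)
  expect_true(f$converged)
  expect_equal(f$mu1, 293, tolerance = 0.5 / 293)
  expect_equal(f$mu2, 162, tolerance = 0.5 / 162)
  expect_equal(f$sigma1, 8, tolerance = 0.05)
  expect_equal(f$sigma2, 10, tolerance = 0.05)
  expect_equal(f$rho, 0.3, tolerance = 0.3)
  # isotropic input: correlation vanishes
  xy2 <- rmvn2(10000, c(293, 162), 8, 8, 0)
  f2 <- fit_section_gaussian(histogram2d(xy2[, 1], xy2[, 2]), 6)
  expect_lt(abs(f2$rho), 0.05)
  # flat input: flagged, centroid fallback stays inside the section
  set.seed(8)
  xy3 <- cbind(runif(4000, 240, 360), runif(4000, 120, 240))
  f3 <- fit_section_gaussian(histogram2d(xy3[, 1], xy3[, 2]), 6)
  expect_false(f3$converged)
  expect_true(f3$mu1 >= 240 && f3$mu1 < 360)
  expect_error(fit_section_gaussian(histogram2d(numeric(0), numeric(0)), 6),
               "min_counts")
})
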