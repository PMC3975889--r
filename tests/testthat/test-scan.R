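test_that("vdW-corrected distances reproduce the radius table arithmetic", {
  expect_equal(vdw_corrected(3.20, "C", "C"), 0)
  expect_equal(vdw_corrected(3.45, "RM", "O"), 0)   # methyl pseudo vs O
  expect_equal(vdw_corrected(2.65, "H", "O"), 0)
  expect_equal(vdw_corrected(3.50, "R2Q", "N"), 0)
  r <- vdw_radii()
  expect_equal(unname(r[c("H", "C", "N", "O")]), c(1.20, 1.60, 1.50, 1.45))
})

test_that("steric energy is zero for separated atoms and frame invariant", {
  ch <- build_ideal_secondary("helix", n = 5, ile_pos = 3)
  norep <- steric_params(attraction_weight = 0)
  e0 <- steric_energy(ch, norep)
  # atoms farther apart than the radius sum contribute nothing
  far <- ch
  for (a in names(far[[5]]$atoms)) {
    far[[5]]$atoms[[a]]$xyz <- far[[5]]$atoms[[a]]$xyz + c(30, 0, 0)
  }
  e_far <- steric_energy(far, norep)
  expect_lt(e_far$energy, e0$energy)
  # rigid rotation + translation leaves the energy unchanged
  R <- rotation_about_axis(c(1, 2, 3), 37)
  moved <- ch
  for (i in seq_along(moved)) {
    for (a in names(moved[[i]]$atoms)) {
      moved[[i]]$atoms[[a]]$xyz <- as.numeric(R %*% moved[[i]]$atoms[[a]]$xyz) +
        c(5, -3, 11)
    }
  }
  e1 <- steric_energy(ch)
  e2 <- steric_energy(moved)
  expect_equal(e1$energy, e2$energy, tolerance = 1e-9)
  expect_equal(sort(e1$force_mag), sort(e2$force_mag), tolerance = 1e-7)
})

test_that("analytic forces match central finite differences", {
  set.seed(13)
  ch <- build_ideal_secondary("helix", n = 5, ile_pos = 3)
  ch[[3]] <- set_side_chain(ch[[3]], 20, 75)   # a strained pose
  params <- steric_params()
  ref <- steric_energy(ch, params)
  h <- 1e-6
  # probe a handful of atoms in all three directions
  at <- sample(seq_along(ref$force_mag), 5)
  flat <- list()
  k <- 0
  for (i in seq_along(ch)) {
    for (a in names(ch[[i]]$atoms)) {
      k <- k + 1
      flat[[k]] <- c(i = i, a = a)
    }
  }
  for (idx in at) {
    i <- as.integer(flat[[idx]][["i"]])
    a <- flat[[idx]][["a"]]
    for (dim in 1:3) {
      chp <- ch; chm <- ch
      chp[[i]]$atoms[[a]]$xyz[dim] <- chp[[i]]$atoms[[a]]$xyz[dim] + h
      chm[[i]]$atoms[[a]]$xyz[dim] <- chm[[i]]$atoms[[a]]$xyz[dim] - h
      num <- (steric_energy(chp, params)$energy -
                steric_energy(chm, params)$energy) / (2 * h)
      expect_equal(-num, ref$force[idx, dim], tolerance = 1e-4)
    }
  }
})

test_that("coarse scans give complete, deterministic, periodic grids", {
  ch <- build_ideal_secondary("helix")
  sc <- scan_chi_grid(ch, step = 120)
  expect_equal(dim(sc$energy), c(3L, 3L))
  expect_equal(sum(!is.na(sc$energy)), 9L)
  sc2 <- scan_chi_grid(ch, step = 120)
  expect_identical(sc$energy, sc2$energy)
  expect_identical(sc$min_contact, sc2$min_contact)
  expect_error(scan_chi_grid(ch, step = 7), "divide")
  # periodicity: energies at 0 and 360 are the same grid point; check
  # continuity across the wrap on a finer grid
  sc5 <- scan_chi_grid(ch, step = 5, contacts = FALSE)
  wrap_jump <- abs(sc5$energy[1, ] - sc5$energy[72, ])
  interior_jump <- abs(sc5$energy[36, ] - sc5$energy[37, ])
  expect_lt(median(wrap_jump), 10 * (median(interior_jump) + 1))
})

test_that("scan grid energies equal the single-pose objective", {
  ch <- build_ideal_secondary("helix")
  sc <- scan_chi_grid(ch, step = 45, contacts = FALSE)
  for (a in c(1, 3, 6)) {
    for (b in c(2, 5, 8)) {
      expect_equal(sc$energy[a, b],
                   side_chain_energy(sc$chain, sc$ile, sc$angles[a],
                                     sc$angles[b], sc$params),
                   tolerance = 1e-9)
    }
  }
})

test_that("scan contact grids agree with the single-pose contact map", {
  ch <- build_ideal_secondary("helix")
  sc <- scan_chi_grid(ch, step = 45)
  ile <- sc$ile
  for (a in c(2, 5)) {
    for (b in c(3, 7)) {
      posed <- ch
      posed[[ile]] <- set_side_chain(posed[[ile]], sc$angles[a], sc$angles[b])
      mc <- min_contact_map(posed, ile)
      expect_equal(sc$min_contact[a, b], mc$min_contact, tolerance = 1e-9)
      expect_setequal(decode_pair(sc, sc$closest_pair[a, b]), mc$pair)
    }
  }
})

test_that("min_contact_map decreases monotonically as a clash approaches", {
  ch <- build_ideal_secondary("helix")
  ile <- which(vapply(ch, `[[`, "", "res_name") == "ILE")
  vals <- vapply(c(162, 120, 80), function(c2) {
    posed <- ch
    posed[[ile]] <- set_side_chain(posed[[ile]], 293, c2)
    min_contact_map(posed, ile)$min_contact
  }, 0)
  expect_equal(vals, sort(vals, decreasing = TRUE))
})

test_that("find_optimum locates the well of a constructed quadratic surface", {
  step <- 5
  ang <- seq(0, 355, by = step)
  w <- function(x) ((x + 180) %% 360) - 180
  E <- outer(ang, ang, function(a, b) w(a - 200)^2 + 0.5 * w(b - 105)^2)
  fake <- structure(list(step = step, angles = ang, energy = E, chain = NULL),
                    class = "ilerot_scan")
  opt <- find_optimum(fake, refine = FALSE)
  expect_equal(unname(opt), c(200, 105))
  flat <- fake
  flat$energy <- E * 0
  expect_error(find_optimum(flat, refine = FALSE), "flat")
})

test_that("refinement improves on the grid argmin deterministically", {
  ch <- build_ideal_secondary("helix")
  sc <- scan_chi_grid(ch, step = 15, contacts = FALSE)
  grid_opt <- find_optimum(sc, refine = FALSE)
  ref_opt <- find_optimum(sc, refine = TRUE)
  e_grid <- side_chain_energy(sc$chain, sc$ile, grid_opt[1], grid_opt[2],
                              sc$params)
  e_ref <- side_chain_energy(sc$chain, sc$ile, ref_opt[1], ref_opt[2],
                             sc$params)
  expect_lte(e_ref, e_grid)
  expect_identical(ref_opt, find_optimum(sc, refine = TRUE))
  expect_lt(max(abs(wrap180(ref_opt - grid_opt))), 15)
})
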