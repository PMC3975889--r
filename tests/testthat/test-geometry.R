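test_that("dihedral reproduces analytic right-angle and planar cases", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral matches the projection oracle on random quadruples", {
  set.seed(11)
  for (k in 1:200) {
    pts <- matrix(stats::rnorm(12), 4L, 3L)
    # reject nearly-degenerate geometries
    if (min(dist(pts)) < 0.3) next
    expect_equal(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral is symmetric under reversal and flips sign on reflection", {
  set.seed(12)
  for (k in 1:50) {
    pts <- matrix(stats::rnorm(12, sd = 2), 4L, 3L)
    if (min(dist(pts)) < 0.3) next
    fwd <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    rev <- dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(rev, fwd, tolerance = 1e-9)
    mir <- pts
    mir[, 3] <- -mir[, 3]   # mirror image: the sign inverts
    ref <- dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ])
    expect_equal((fwd + ref) %% 360, 0, tolerance = 1e-9)
  }
})

test_that("ideal helix reproduces its phi/psi targets", {
  ch <- build_ideal_secondary("helix")
  expect_length(ch, 11L)
  for (i in 2:10) {
    t <- measure_torsions(ch, i)
    expect_equal(t$phi, -57, tolerance = 0.1)
    expect_equal(t$psi, -47, tolerance = 0.1)
  }
  expect_true(is.na(measure_torsions(ch, 1)$phi))
  expect_true(is.na(measure_torsions(ch, 11)$psi))
})

test_that("hairpin has a Gly turn and a strand isoleucine at chi (0,0)", {
  ch <- build_ideal_secondary("hairpin")
  expect_equal(vapply(ch, `[[`, "", "res_name")[7], "GLY")
  expect_equal(vapply(ch, `[[`, "", "res_name")[11], "ILE")
  t <- measure_torsions(ch, 11)
  expect_equal(t$chi1, 0, tolerance = 1e-6)
  expect_equal(t$chi2, 0, tolerance = 1e-6)
  expect_lt(t$phi, -90)   # strand-like backbone at the isoleucine
  expect_gt(t$psi, 90)
})

test_that("set_side_chain round-trips over a grid and preserves geometry", {
  ch <- build_ideal_secondary("helix")
  ile <- which(vapply(ch, `[[`, "", "res_name") == "ILE")
  r0 <- ch[[ile]]
  blen <- function(r, a, b) sqrt(sum((r$atoms[[a]]$xyz - r$atoms[[b]]$xyz)^2))
  ref <- c(blen(r0, "CA", "CB"), blen(r0, "CB", "CG1"), blen(r0, "CG1", "CD1"))
  for (c1 in seq(0, 324, by = 36)) {
    for (c2 in seq(18, 342, by = 36)) {
      r <- set_side_chain(r0, c1, c2)
      ch[[ile]] <- r
      t <- measure_torsions(ch, ile)
      expect_equal(t$chi1, c1, tolerance = 1e-6)
      expect_equal(t$chi2, c2, tolerance = 1e-6)
      expect_equal(c(blen(r, "CA", "CB"), blen(r, "CB", "CG1"),
                     blen(r, "CG1", "CD1")), ref, tolerance = 1e-9)
    }
  }
  # setter is idempotent: (0,0) then (293,162) measures (293,162)
  r <- set_side_chain(set_side_chain(r0, 0, 0), 293, 162)
  ch[[ile]] <- r
  t <- measure_torsions(ch, ile)
  expect_equal(unname(c(t$chi1, t$chi2)), c(293, 162), tolerance = 1e-6)
})

test_that("pseudo-atoms replace exactly the methyl/methylene groups", {
  ch <- build_ideal_secondary("helix")
  ps <- make_pseudo_atoms(ch)
  ile <- which(vapply(ch, `[[`, "", "res_name") == "ILE")
  ile_ps <- ps$label[ps$res_idx == ile & ps$pseudo]
  expect_setequal(ile_ps, c("QG", "MG", "MD"))
  # alanine CB -> MB at the centre of mass of CB + 3 H
  ala <- 2L
  r <- ch[[ala]]
  com <- (12 * r$atoms[["CB"]]$xyz + r$atoms[["HB1"]]$xyz +
            r$atoms[["HB2"]]$xyz + r$atoms[["HB3"]]$xyz) / 15
  mb <- ps[ps$res_idx == ala & ps$label == "MB", ]
  expect_equal(unlist(mb[, c("x", "y", "z")], use.names = FALSE), com,
               tolerance = 1e-12)
  expect_equal(mb$cls, "RM")
  # methine CB of Ile and backbone atoms survive as plain atoms
  expect_true("CB" %in% ps$label[ps$res_idx == ile])
  expect_true(all(c("N", "CA", "C", "O") %in% ps$label[ps$res_idx == ala]))
})

test_that("pseudo-atom fallback without hydrogens uses the heavy position", {
  ch <- build_ideal_secondary("helix", n = 7, ile_pos = 4)
  # strip the CG2 methyl protons
  for (h in c("HG21", "HG22", "HG23")) ch[[4]]$atoms[[h]] <- NULL
  expect_message(ps <- make_pseudo_atoms(ch), "without hydrogens")
  mg <- ps[ps$res_idx == 4 & ps$label == "MG", ]
  expect_equal(unlist(mg[, c("x", "y", "z")], use.names = FALSE),
               ch[[4]]$atoms[["CG2"]]$xyz)
})
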