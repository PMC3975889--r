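test_that("write/parse round trip preserves coordinates, B factors and metadata", {
  ch <- build_ideal_secondary("helix")
  for (i in seq_along(ch)) {
    for (a in names(ch[[i]]$atoms)) {
      ch[[i]]$atoms[[a]]$b <- 10 + i + 0.25
    }
  }
  meta <- list(entry_id = "RT01", resolution = 2.3, method = "X-RAY DIFFRACTION",
               programs = "REFMAC", year = 2008)
  lines <- write_pdb(ch, meta)
  expect_true(any(grepl("REMARK   2 RESOLUTION\\.    2\\.30 ANGSTROMS", lines)))
  p <- parse_pdb(lines)
  expect_equal(p$meta$resolution, 2.3)
  expect_equal(p$meta$programs, "REFMAC")
  expect_equal(p$meta$method, "X-RAY DIFFRACTION")
  expect_equal(p$meta$year, 2008L)
  ch2 <- p$chains[["A"]]
  expect_length(ch2, length(ch))
  for (i in seq_along(ch)) {
    for (a in names(ch[[i]]$atoms)) {
      if (ch[[i]]$atoms[[a]]$element == "H") next  # heavy-atom output
      expect_equal(ch2[[i]]$atoms[[a]]$xyz, ch[[i]]$atoms[[a]]$xyz,
                   tolerance = 1.1e-3)
      expect_equal(ch2[[i]]$atoms[[a]]$b, ch[[i]]$atoms[[a]]$b,
                   tolerance = 1e-6)
    }
  }
  # second round trip is exact (idempotent on the rounded representation)
  lines2 <- write_pdb(ch2, p$meta)
  p2 <- parse_pdb(lines2)
  at_a <- do.call(rbind, lapply(p$chains[["A"]], function(r)
    t(vapply(r$atoms, `[[`, numeric(3), "xyz"))))
  at_b <- do.call(rbind, lapply(p2$chains[["A"]], function(r)
    t(vapply(r$atoms, `[[`, numeric(3), "xyz"))))
  expect_equal(at_a, at_b)
})

test_that("neighbour links are mutual and severed at chain breaks", {
  ch <- build_ideal_secondary("helix")
  lines <- write_pdb(ch, list(resolution = 2.0))
  p <- parse_pdb(lines)
  ch2 <- p$chains[["A"]]
  for (i in seq_along(ch2)) {
    if (!is.na(ch2[[i]]$nxt)) expect_equal(ch2[[ch2[[i]]$nxt]]$prev, i)
    if (!is.na(ch2[[i]]$prev)) expect_equal(ch2[[ch2[[i]]$prev]]$nxt, i)
  }
  expect_true(is.na(ch2[[1]]$prev))
  expect_true(is.na(ch2[[length(ch2)]]$nxt))
  # translate the tail far away: C-N distance > 2.5 A severs the link
  for (i in 6:11) {
    for (a in names(ch[[i]]$atoms)) {
      ch[[i]]$atoms[[a]]$xyz <- ch[[i]]$atoms[[a]]$xyz + c(50, 0, 0)
    }
  }
  p3 <- parse_pdb(write_pdb(ch, list(resolution = 2.0)))
  ch3 <- p3$chains[["A"]]
  expect_true(is.na(ch3[[5]]$nxt))
  expect_true(is.na(ch3[[6]]$prev))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  base <- helix_fragment_lines()
  atom_rows <- grep("^ATOM", base)
  # duplicate the Ile CD1 record as altlocs A (0.6) and B (0.4)
  cd1 <- base[grep(" CD1", base)]
  a_rec <- sub("^(.{16}).", "\\1A", cd1)
  a_rec <- sub("  1\\.00", "  0.60", a_rec)
  b_rec <- sub("^(.{16}).", "\\1B", cd1)
  b_rec <- sub("  1\\.00", "  0.40", b_rec)
  # shift the B conformer so the kept one is identifiable
  xb <- as.numeric(substr(b_rec, 31, 38)) + 1
  substr(b_rec, 31, 38) <- sprintf("%8.3f", xb)
  lines <- append(base[-grep(" CD1", base)], c(a_rec, b_rec),
                  after = grep(" CG2", base)[1])
  p <- parse_pdb(lines)
  ile <- p$chains[["A"]][[4]]
  expect_equal(ile$res_name, "ILE")
  orig <- as.numeric(substr(cd1, 31, 38))
  expect_equal(ile$atoms[["CD1"]]$xyz[1], orig, tolerance = 1e-6)
  expect_equal(ile$atoms[["CD1"]]$occ, 0.6)
})

test_that("metadata extraction normalizes programs and flags mixtures", {
  lines <- c(
    "HEADER    SYNTHETIC PROTEIN                       12-MAR-99   1ABC",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
    "REMARK   3   PROGRAM     : REFMAC 5.5.0109"
  )
  m <- extract_metadata(lines)
  expect_equal(m$resolution, 1.5)
  expect_equal(m$programs, "REFMAC")
  expect_false(m$mixed_programs)
  expect_equal(m$year, 1999L)
  expect_equal(m$entry_id, "1ABC")
  lines2 <- c(lines, "REMARK   3   PROGRAM     : CNS 1.1")
  m2 <- extract_metadata(lines2)
  expect_setequal(m2$programs, c("REFMAC", "CNS"))
  expect_true(m2$mixed_programs)
  m3 <- extract_metadata(c("EXPDTA    X-RAY DIFFRACTION",
                           "REMARK   3   PROGRAM     : SOMETOOL 9"))
  expect_true(is.na(m3$resolution))
  expect_equal(m3$programs, "other")
})

test_that("DSSP files parse with the 8-state alphabet collapsed to H/E/L", {
  lines <- dssp_fixture(seq_num = 1:6, chain_id = rep("A", 6),
                        code = c("H", "E", "T", "B", "G", " "))
  d <- read_dssp(lines)
  expect_equal(d$ss, c("H", "E", "L", "L", "L", "L"))
  expect_equal(d$seq_num, 1:6)
  expect_error(read_dssp(c("not", "a dssp", "file")), "DSSP")
})

test_that("write_pdb rejects degenerate input", {
  expect_error(write_pdb(list(), list()), "no residues")
  ch <- build_ideal_secondary("helix", n = 5, ile_pos = 3)
  ch[[1]]$atoms[["N"]]$xyz <- c(123456, 0, 0)
  expect_error(write_pdb(ch, list()), "field width")
})
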