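# Independent oracles and fixture builders shared across test files.

# Torsion oracle built from frame projection + 2D angle difference: an
# orthonormal basis perpendicular to the central bond is constructed and
# the torsion read off as the difference of atan2 angles of the projected
# outer bonds.  Independent of the cross-product formula in dihedral().
oracle_dihedral <- function(p1, p2, p3, p4) {
  e1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  ref <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
          e1[3L] * e2[1L] - e1[1L] * e2[3L],
          e1[1L] * e2[2L] - e1[2L] * e2[1L])
  w1 <- p1 - p2
  w2 <- p4 - p3
  a1 <- atan2(sum(w1 * e3), sum(w1 * e2))
  a2 <- atan2(sum(w2 * e3), sum(w2 * e2))
  ((a2 - a1) * 180 / pi) %% 360
}

# Brute-force section classifier: explicit nested conditionals, no
# arithmetic shared with section_of().
oracle_section <- function(chi1, chi2) {
  cls <- function(x) {
    if (x < 120) "g+" else if (x < 240) "t" else "g-"
  }
  c1 <- cls(chi1 %% 360)
  c2 <- cls(chi2 %% 360)
  if (c2 == "g-") {
    switch(c1, "g+" = 1L, "t" = 2L, "g-" = 3L)
  } else if (c2 == "t") {
    switch(c1, "g+" = 4L, "t" = 5L, "g-" = 6L)
  } else {
    switch(c1, "g+" = 7L, "t" = 8L, "g-" = 9L)
  }
}

# Minimal DSSP-format fixture writer (classic column layout).
dssp_fixture <- function(seq_num, chain_id, code) {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  )
  body <- sprintf("%5d%5d %s %s  %s", seq_along(seq_num), seq_num,
                  chain_id, "A", code)
  # enforce fixed columns: resnum 6-10, chain 12, aa 14, ss 17
  body <- vapply(seq_along(seq_num), function(i) {
    ln <- sprintf("%5d%5d %1s %1s  %1s", i, seq_num[i], chain_id[i], "A",
                  code[i])
    ln
  }, "")
  c(header, body)
}

# Correlated bivariate normal sample without external dependencies.
rmvn2 <- function(n, mu, sd1, sd2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(mu[1L] + sd1 * z1, mu[2L] + sd2 * z2)
}

# Tiny handcrafted PDB fixture: a three-residue Ala-Ile-Ala fragment
# cut from the ideal helix, with configurable header records.
helix_fragment_lines <- function(resolution = 1.5, programs = "REFMAC",
                                 method = "X-RAY DIFFRACTION", year = 2010) {
  ch <- build_ideal_secondary("helix", n = 7, ile_pos = 4)
  meta <- list(entry_id = "TEST", resolution = resolution, method = method,
               programs = programs, year = year)
  write_pdb(ch, meta)
}
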