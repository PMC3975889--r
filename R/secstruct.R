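# Secondary-structure assignment (hydrogen-bond based, DSSP-style,
# collapsed to H/E/L) and the phi/psi-window subclassification used to
# split loop residues into helical-, strand- and other-backbone classes.

KS_HBOND_CUTOFF <- -0.5  # kcal/mol

# Kabsch-Sander hydrogen-bond energy between donor residue i (N-H) and
# acceptor residue j (C=O):
#   E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol.
# The amide H is rebuilt from the preceding carbonyl (1.0 A from N,
# opposite the C=O direction), so heavy-atom-only structures work too.
ks_hbond_energy <- function(N, H, C, O) {
  f <- function(a, b) 1 / v_norm(a - b)
  0.084 * (f(O, N) + f(C, H) - f(O, H) - f(C, N)) * 332
}

backbone_coords <- function(chain) {
  n <- length(chain)
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    r <- chain[[i]]
    for (nm in c("N", "CA", "C", "O")) {
      xyz <- res_xyz(r, nm)
      if (!is.null(xyz)) {
        switch(nm, N = N[i, ] <- xyz, CA = CA[i, ] <- xyz,
               C = C[i, ] <- xyz, O = O[i, ] <- xyz)
      }
    }
  }
  for (i in seq_len(n)) {
    p <- chain[[i]]$prev
    if (is.na(p) || anyNA(N[i, ]) || anyNA(C[p, ]) || anyNA(O[p, ])) next
    H[i, ] <- N[i, ] + v_unit(C[p, ] - O[p, ])
  }
  list(N = N, CA = CA, C = C, O = O, H = H)
}

#' Assign H/E/L secondary structure from backbone hydrogen bonds
#'
#' A residue pair (donor i, acceptor j) is hydrogen bonded when the
#' Kabsch-Sander electrostatic energy is below -0.5 kcal/mol.  Alpha
#' helix (H) is assigned on runs of at least two consecutive i -> i+4
#' turns; strand (E) on parallel or antiparallel bridge ladders; all other
#' residues are loop (L).  Prolines and chain-terminal residues without an
#' amide H cannot donate.
#'
#' @param chain an `ilerot_chain`.
#' @return character vector of per-residue codes in `{"H","E","L"}`.
#' @export
assign_ss <- function(chain) {
  n <- length(chain)
  ss <- rep("L", n)
  if (n < 5L) return(ss)
  bb <- backbone_coords(chain)
  hb <- matrix(FALSE, n, n)  # hb[i, j]: N-H of i donates to C=O of j
  for (i in seq_len(n)) {
    if (anyNA(bb$H[i, ])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L || anyNA(bb$C[j, ]) || anyNA(bb$O[j, ])) next
      if (sum((bb$N[i, ] - bb$O[j, ])^2) > 49) next  # 7 A O..N prefilter
      e <- ks_hbond_energy(bb$N[i, ], bb$H[i, ], bb$C[j, ], bb$O[j, ])
      hb[i, j] <- e < KS_HBOND_CUTOFF
    }
  }
  turn4 <- vapply(seq_len(n - 4L), function(i) hb[i + 4L, i], TRUE)
  for (i in seq_len(max(0L, n - 5L))) {
    if (turn4[i] && turn4[i + 1L]) ss[(i + 1L):(i + 4L)] <- "H"
  }
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[i, j - 1L] && hb[j + 1L, i]) || (hb[j, i - 1L] && hb[i + 1L, j])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) bridge[i] <- TRUE
    }
  }
  ss[bridge & ss != "H"] <- "E"
  ss
}

#' Classify a phi/psi pair as helical, strand or other
#'
#' Window defaults: helical phi in `[-100, -30]` and psi in `[-80, -5]`;
#' strand phi in `[-180, -45]` and psi in `[85, 180]` or `[-180, -170]`.
#' Undefined angles classify as `"other"`.
#'
#' @param phi,psi backbone torsions in degrees, `(-180, 180]`.
#' @param windows optional list overriding the window boundaries
#'   (`helix_phi`, `helix_psi`, `strand_phi`, `strand_psi1`, `strand_psi2`).
#' @return character vector in `{"helical", "strand", "other"}`.
#' @export
classify_phipsi <- function(phi, psi, windows = NULL) {
  w <- list(helix_phi = c(-100, -30), helix_psi = c(-80, -5),
            strand_phi = c(-180, -45), strand_psi1 = c(85, 180),
            strand_psi2 = c(-180, -170))
  if (!is.null(windows)) w[names(windows)] <- windows
  inw <- function(x, b) !is.na(x) & x >= b[1L] & x <= b[2L]
  out <- rep("other", length(phi))
  out[inw(phi, w$strand_phi) &
        (inw(psi, w$strand_psi1) | inw(psi, w$strand_psi2))] <- "strand"
  out[inw(phi, w$helix_phi) & inw(psi, w$helix_psi)] <- "helical"
  out
}

#' Combine secondary structure and phi/psi class into a subclass
#'
#' H and E keep their class; loop residues split into `"L-a"`, `"L-b"` and
#' `"L-other"` by their backbone torsions.  In strict mode, helix or
#' strand residues whose phi/psi class disagrees with the assignment are
#' dropped (`NA`), keeping only residues whose backbone supports their
#' secondary structure.
#'
#' @param ss character vector in `{"H","E","L"}`.
#' @param phipsi_class character vector from [classify_phipsi()].
#' @param strict drop H/E residues with discordant backbone torsions.
#' @return character vector in `{"H","E","L-a","L-b","L-other"}`, with
#'   `NA` for residues dropped in strict mode.
#' @export
subclassify <- function(ss, phipsi_class, strict = FALSE) {
  out <- ifelse(ss == "L",
                c(helical = "L-a", strand = "L-b", other = "L-other")[phipsi_class],
                ss)
  if (strict) {
    out[ss == "H" & phipsi_class != "helical"] <- NA_character_
    out[ss == "E" & phipsi_class != "strand"] <- NA_character_
  }
  unname(out)
}
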