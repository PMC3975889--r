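# Idealized secondary-structure builders and torsion manipulation.

# Place the three backbone atoms of residue i given the previous residue
# and the torsion targets; seed geometry for residue 1 is arbitrary
# (results are frame-invariant).
build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(BACKBONE_GEOM$omega, n)
  g <- BACKBONE_GEOM
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- .rad(g$a_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1L]) {
    N[i, ] <- nerf_place(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1L])
    CA[i, ] <- nerf_place(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, omega[i - 1L])
    C[i, ] <- nerf_place(C[i - 1L, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  list(N = N, CA = CA, C = C)
}

# Complete one residue: O, amide H (non-terminal) and side chain.
complete_residue <- function(res, Nprev, Cprev, Oprev, psi,
                             chi1 = 0, chi2 = 0) {
  g <- BACKBONE_GEOM
  N <- res$atoms[["N"]]$xyz
  CA <- res$atoms[["CA"]]$xyz
  C <- res$atoms[["C"]]$xyz
  res$atoms[["O"]] <- new_atom("O", nerf_place(N, CA, C, g$b_c_o, g$a_ca_c_o,
                                               wrap360(psi + 180)))
  if (!is.null(Oprev)) {
    res$atoms[["H"]] <- new_atom("H", nerf_place(Oprev, Cprev, N, g$b_n_h,
                                                 g$a_c_n_h, 180))
  }
  build_side_chain(res, chi1, chi2)
}

# Run the side-chain z-matrix of a residue whose backbone is in place.
build_side_chain <- function(res, chi1 = 0, chi2 = 0) {
  zmat <- SIDECHAIN_ZMAT[[res$res_name]]
  chi <- c(chi1 = chi1, chi2 = chi2)
  for (row in zmat) {
    tors <- row$tors + if (!is.na(row$ref)) chi[[row$ref]] else 0
    f <- lapply(row$f, function(nm) res$atoms[[nm]]$xyz)
    res$atoms[[row$at]] <- new_atom(row$at, nerf_place(f[[1L]], f[[2L]], f[[3L]],
                                                       row$bond, row$ang, tors))
  }
  res
}

#' Build an idealized helix or beta-hairpin host chain
#'
#' Constructs a polyalanine motif with one central intact isoleucine, in
#' the spirit of the energy-minimized crambin helix / rhinovirus hairpin
#' hosts used for side-chain scanning, but from fixed textbook geometry so
#' no external coordinates are needed.  The helix uses phi,psi =
#' (-57, -47) throughout; the hairpin uses two (-139, 135) strands joined
#' by a two-residue type-I' turn whose first residue is glycine.  All
#' hydrogens are placed by standard covalent geometry and the isoleucine
#' side chain starts at chi1 = 0, chi2 = 0.
#'
#' @param motif `"helix"` or `"hairpin"`.
#' @param n residue count; default 11 (helix) or 14 (hairpin).
#' @param ile_pos index of the isoleucine; default 6 (helix centre) or 11
#'   (on the second strand of the hairpin).
#' @param phi,psi override the motif torsion targets (degrees); for the
#'   hairpin these set the strand values only.
#' @param chain_id chain identifier for the produced residues.
#' @return an `ilerot_chain` of residues with full atom records.
#' @export
build_ideal_secondary <- function(motif = c("helix", "hairpin"), n = NULL,
                                  ile_pos = NULL, phi = NULL, psi = NULL,
                                  chain_id = "A") {
  motif <- match.arg(motif)
  if (motif == "helix") {
    if (is.null(n)) n <- 11L
    if (n < 5L) stop("motif too short: need at least 5 residues")
    if (is.null(ile_pos)) ile_pos <- (n + 1L) %/% 2L
    if (is.null(phi)) phi <- -57
    if (is.null(psi)) psi <- -47
    phis <- rep(phi, n)
    psis <- rep(psi, n)
    res_names <- rep("ALA", n)
  } else {
    if (is.null(n)) n <- 14L
    if (n < 8L) stop("hairpin too short: need at least 8 residues")
    if (is.null(ile_pos)) ile_pos <- min(11L, n - 2L)
    turn <- c(n %/% 2L, n %/% 2L + 1L)       # two-residue turn mid-chain
    if (n == 14L && is.null(phi) && is.null(psi)) {
      # strand/turn torsions calibrated once so the two strands form the
      # canonical antiparallel hydrogen-bond ladder (rungs 6-9, 4-11,
      # 2-13) without a minimization step
      phis <- c(-137.2, -139, -137.1, -136.6, -138.1, -171.4, 61.8,
                104.1, -114.3, -135.7, -136.5, -137.5, -137, -138)
      psis <- c(134.9, 136.5, 136.3, 141.3, 135.7, 157, 6.7, 0.7, 136.1,
                128.7, 137.6, 137.3, 136.6, 141.9)
    } else {
      if (is.null(phi)) phi <- -139
      if (is.null(psi)) psi <- 135
      phis <- rep(phi, n)
      psis <- rep(psi, n)
      phis[turn] <- c(60, 90)                # type-I' beta turn
      psis[turn] <- c(30, 0)
    }
    res_names <- rep("ALA", n)
    res_names[turn[1L]] <- "GLY"
    if (ile_pos %in% c(1L, 2L, n - 1L, n) || ile_pos %in% turn) {
      stop("isoleucine must sit on a strand interior position")
    }
  }
  res_names[ile_pos] <- "ILE"
  bb <- build_backbone(phis, psis)
  chain <- vector("list", n)
  for (i in seq_len(n)) {
    r <- new_residue(res_names[i], chain_id = chain_id, seq_num = i)
    r$atoms[["N"]] <- new_atom("N", bb$N[i, ])
    r$atoms[["CA"]] <- new_atom("CA", bb$CA[i, ])
    r$atoms[["C"]] <- new_atom("C", bb$C[i, ])
    r$prev <- if (i > 1L) i - 1L else NA_integer_
    r$nxt <- if (i < n) i + 1L else NA_integer_
    chain[[i]] <- r
  }
  for (i in seq_len(n)) {
    prev_ok <- i > 1L
    chain[[i]] <- complete_residue(
      chain[[i]],
      Nprev = if (prev_ok) bb$N[i - 1L, ] else NULL,
      Cprev = if (prev_ok) bb$C[i - 1L, ] else NULL,
      Oprev = if (prev_ok) chain[[i - 1L]]$atoms[["O"]]$xyz else NULL,
      psi = psis[i], chi1 = 0, chi2 = 0
    )
  }
  new_chain(chain)
}

#' Measure backbone and side-chain torsions of one residue
#'
#' chi1 is N-CA-CB-CG1 and chi2 is CA-CB-CG1-CD1 (isoleucine atom
#' topology); both are reported in `[0, 360)`.  phi and psi use the
#' neighbouring residues and are reported in `(-180, 180]`; a missing or
#' unlinked neighbour yields `NA` for the corresponding angle, and missing
#' side-chain atoms yield `NA` chi values.
#'
#' @param chain an `ilerot_chain`.
#' @param i residue index within the chain.
#' @return named list with `chi1`, `chi2`, `phi`, `psi` (degrees).
#' @export
measure_torsions <- function(chain, i) {
  r <- chain[[i]]
  a <- function(nm) res_xyz(r, nm)
  chi1 <- chi2 <- phi <- psi <- NA_real_
  if (has_atoms(r, c("N", "CA", "CB", "CG1"))) {
    chi1 <- dihedral(a("N"), a("CA"), a("CB"), a("CG1"))
  }
  if (has_atoms(r, c("CA", "CB", "CG1", "CD1"))) {
    chi2 <- dihedral(a("CA"), a("CB"), a("CG1"), a("CD1"))
  }
  if (!is.na(r$prev) && !is.null(res_xyz(chain[[r$prev]], "C")) &&
      has_atoms(r, c("N", "CA", "C"))) {
    phi <- wrap180(dihedral(res_xyz(chain[[r$prev]], "C"), a("N"), a("CA"), a("C")))
  }
  if (!is.na(r$nxt) && !is.null(res_xyz(chain[[r$nxt]], "N")) &&
      has_atoms(r, c("N", "CA", "C"))) {
    psi <- wrap180(dihedral(a("N"), a("CA"), a("C"), res_xyz(chain[[r$nxt]], "N")))
  }
  list(chi1 = chi1, chi2 = chi2, phi = phi, psi = psi)
}

#' Pose an isoleucine side chain at given chi1, chi2
#'
#' Rigid rotations about the CA-CB and CB-CG1 bonds: only atoms distal to
#' the rotated bond move (hydrogens ride with their parent group), so all
#' bond lengths and angles are untouched.
#'
#' @param res an intact isoleucine residue (list form used throughout).
#' @param chi1,chi2 target torsions in degrees.
#' @return the residue with side-chain atoms repositioned.
#' @export
set_side_chain <- function(res, chi1, chi2) {
  if (res$res_name != "ILE") stop("set_side_chain: residue is not isoleucine")
  if (!is.finite(chi1) || !is.finite(chi2)) stop("non-finite chi target")
  need <- c("N", "CA", "CB", "CG1", "CD1")
  if (!has_atoms(res, need)) stop("set_side_chain: incomplete side chain")
  rotate_set <- function(res, names, origin, axis, ang) {
    names <- intersect(names, names(res$atoms))
    xyz <- t(vapply(res$atoms[names], `[[`, numeric(3L), "xyz"))
    xyz <- rotate_points(xyz, origin, axis, ang)
    for (k in seq_along(names)) res$atoms[[names[k]]]$xyz <- xyz[k, ]
    res
  }
  cur <- dihedral(res_xyz(res, "N"), res_xyz(res, "CA"),
                  res_xyz(res, "CB"), res_xyz(res, "CG1"))
  res <- rotate_set(res, ILE_CHI1_ATOMS, res_xyz(res, "CA"),
                    res_xyz(res, "CB") - res_xyz(res, "CA"), chi1 - cur)
  cur2 <- dihedral(res_xyz(res, "CA"), res_xyz(res, "CB"),
                   res_xyz(res, "CG1"), res_xyz(res, "CD1"))
  res <- rotate_set(res, ILE_CHI2_ATOMS, res_xyz(res, "CB"),
                    res_xyz(res, "CG1") - res_xyz(res, "CB"), chi2 - cur2)
  res
}

# Index of the (single) isoleucine in a chain; errors if absent/ambiguous.
central_ile <- function(chain) {
  idx <- which(vapply(chain, `[[`, "", "res_name") == "ILE")
  if (length(idx) != 1L) stop("chain must contain exactly one isoleucine")
  idx
}
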