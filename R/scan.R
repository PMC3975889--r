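# Exhaustive chi1/chi2 conformational scan of the central isoleucine in
# an idealized motif.  The steric field is a documented soft-sphere model:
# pairwise repulsion w * max(0, r_i + r_j - d)^k plus an optional smooth
# Gaussian attraction centred at the van der Waals contact distance, so
# the surface has genuine minima where the side chain packs well.  1-2 and
# 1-3 bonded pairs are excluded; energies are in model units.

#' Parameters of the soft-sphere steric field
#'
#' @param repulsion_weight weight `w` of the overlap penalty (model units
#'   per Angstrom^softness).
#' @param softness exponent `k` of the overlap penalty (default 2: smooth
#'   harmonic-like repulsion).
#' @param attraction_weight depth of the smooth contact attraction; 0
#'   disables it.
#' @param attraction_width Gaussian width of the attraction (Angstrom).
#' @param intra_scale scale factor applied to pairs internal to the
#'   isoleucine side chain (the analogue of force-field 1-4 scaling;
#'   softens artefacts of the fixed staggered methyl-proton convention).
#' @param torsion_barrier height (model units) of the intrinsic threefold
#'   staggering potential `h/2 * (1 + cos(3 chi))` applied to chi1 and
#'   chi2 in the scan objective; represents the sp3 torsional preference
#'   that rigid spheres with frozen rotors underestimate.
#' @param cutoff nonbonded cutoff (Angstrom).
#' @return list of class `ilerot_steric_params`.
#' @export
steric_params <- function(repulsion_weight = 100, softness = 2,
                          attraction_weight = 1, attraction_width = 0.75,
                          intra_scale = 0.25, torsion_barrier = 10,
                          cutoff = 20) {
  stopifnot(repulsion_weight >= 0, attraction_weight >= 0, cutoff >= 8,
            intra_scale >= 0, intra_scale <= 1, torsion_barrier >= 0)
  structure(list(repulsion_weight = repulsion_weight, softness = softness,
                 attraction_weight = attraction_weight,
                 attraction_width = attraction_width,
                 intra_scale = intra_scale,
                 torsion_barrier = torsion_barrier, cutoff = cutoff),
            class = "ilerot_steric_params")
}

# intrinsic threefold staggering term of the scan objective
chi_torsion_energy <- function(chi1, chi2, params) {
  h <- params$torsion_barrier
  if (h == 0) return(0 * chi1 + 0 * chi2)
  h / 2 * (2 + cos(3 * .rad(chi1)) + cos(3 * .rad(chi2)))
}

BIG_DIST <- 1e6   # marks excluded pairs; all terms vanish there

pair_energy <- function(d, rsum, params) {
  dd <- pmax(d, 0.1)                       # capped overlap contribution
  p <- pmax(rsum - dd, 0)
  e <- params$repulsion_weight * p^params$softness
  if (params$attraction_weight > 0) {
    e <- e - params$attraction_weight *
      exp(-((dd - rsum)^2) / (2 * params$attraction_width^2))
  }
  e[dd > params$cutoff] <- 0
  e
}

# dE/dd (positive means energy rises with distance)
pair_dEdd <- function(d, rsum, params) {
  dd <- pmax(d, 0.1)
  p <- pmax(rsum - dd, 0)
  g <- -params$softness * params$repulsion_weight * p^(params$softness - 1)
  if (params$attraction_weight > 0) {
    g <- g + params$attraction_weight * (dd - rsum) / params$attraction_width^2 *
      exp(-((dd - rsum)^2) / (2 * params$attraction_width^2))
  }
  g[dd > params$cutoff] <- 0
  g[d < 0.1] <- 0                          # capped region is flat
  g
}

#' Total steric energy and per-atom forces of a chain
#'
#' Sums the soft-sphere pair energy over all nonbonded pairs (1-2 and 1-3
#' excluded) within the cutoff and returns the analytic per-atom force
#' vectors and magnitudes.  Deterministic and invariant under rigid-body
#' motion.  Overlapping atoms closer than 0.1 Angstrom contribute a
#' finite capped energy and are flagged.
#'
#' @param chain an `ilerot_chain` with hydrogens.
#' @param params [steric_params()].
#' @param vdw radius table from [vdw_radii()].
#' @return list with `energy`, `force` (n x 3 matrix), `force_mag`,
#'   `atoms` (labels) and `overlaps` (count of capped pairs).
#' @export
steric_energy <- function(chain, params = steric_params(), vdw = vdw_radii()) {
  at <- atom_table(chain)
  adj <- bond_adjacency(at, chain)
  n <- nrow(at)
  X <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(vdw[at$element])
  D <- as.matrix(stats::dist(X))
  for (i in seq_len(n)) D[i, excluded_partners(adj, i)] <- BIG_DIST
  RS <- outer(rad, rad, "+")
  overlaps <- sum(D < 0.1) / 2
  E <- sum(pair_energy(D, RS, params)) / 2
  W <- pair_dEdd(D, RS, params) / pmax(D, 0.1)
  Fx <- -rowSums(W * outer(X[, 1L], X[, 1L], "-"))
  Fy <- -rowSums(W * outer(X[, 2L], X[, 2L], "-"))
  Fz <- -rowSums(W * outer(X[, 3L], X[, 3L], "-"))
  force <- cbind(Fx, Fy, Fz)
  list(energy = E, force = force, force_mag = sqrt(rowSums(force^2)),
       atoms = sprintf("%s(%d)", at$name, at$seq_num), overlaps = overlaps)
}

# Interaction energy of the isoleucine side chain with its environment:
# all non-excluded pairs involving at least one atom distal to CA-CB.
# This is the scan objective; static-static pairs (constant during the
# scan) are omitted.
#' Side-chain interaction energy at a given chi1/chi2 pose
#'
#' @param chain an `ilerot_chain` with hydrogens.
#' @param ile isoleucine index (found automatically when `NULL`).
#' @param chi1,chi2 pose torsions in degrees.
#' @param params [steric_params()].
#' @param vdw radius table.
#' @return scalar energy (model units).
#' @export
side_chain_energy <- function(chain, ile = NULL, chi1, chi2,
                              params = steric_params(), vdw = vdw_radii()) {
  if (is.null(ile)) ile <- central_ile(chain)
  chain[[ile]] <- set_side_chain(chain[[ile]], chi1, chi2)
  at <- atom_table(chain)
  adj <- bond_adjacency(at, chain)
  mov <- which(at$res_idx == ile & at$name %in% ILE_CHI1_ATOMS)
  X <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(vdw[at$element])
  e <- 0
  seen <- integer(0L)
  for (i in mov) {
    part <- setdiff(seq_len(nrow(at)), c(excluded_partners(adj, i), seen))
    d <- sqrt(colSums((t(X[part, , drop = FALSE]) - X[i, ])^2))
    pe <- pair_energy(d, rad[i] + rad[part], params)
    w <- ifelse(part %in% mov, params$intra_scale, 1)
    e <- e + sum(w * pe)
    seen <- c(seen, i)                    # avoid double-counting intra pairs
  }
  e + chi_torsion_energy(chi1, chi2, params)
}

#' Exhaustive chi1/chi2 scan of the central isoleucine
#'
#' Rotates the side chain through every (chi1, chi2) combination on a
#' regular grid (1 degree steps give the full 360^2 = 129600
#' conformations) and records, per conformation: the side-chain steric
#' energy, the atom experiencing the greatest force, and the minimum
#' vdW-corrected distance from the QG/MG/MD pseudo-atoms to any other
#' (pseudo-)atom together with the achieving pair.  The backbone is held
#' rigid; the scan is fully deterministic.
#'
#' @param chain an `ilerot_chain` with hydrogens (from
#'   [build_ideal_secondary()]).
#' @param ile isoleucine index (found automatically when `NULL`).
#' @param step grid step in degrees; must divide 360.
#' @param params [steric_params()].
#' @param vdw radius table from [vdw_radii()].
#' @param contacts compute the contact grids too (default `TRUE`).
#' @return an `ilerot_scan` list: `angles`, `step`, `energy` (chi1 rows x
#'   chi2 columns), `max_force_atom` (integer grid + `atom_labels`),
#'   `min_contact`, `closest_pair` (integer grid + `pair_labels`), plus
#'   the inputs needed by [find_optimum()].
#' @export
scan_chi_grid <- function(chain, ile = NULL, step = 1,
                          params = steric_params(), vdw = vdw_radii(),
                          contacts = TRUE) {
  if (360 %% step != 0) stop("step must divide 360")
  if (is.null(ile)) ile <- central_ile(chain)
  n <- as.integer(360 / step)
  ang <- (seq_len(n) - 1L) * step
  chain[[ile]] <- set_side_chain(chain[[ile]], 0, 0)
  at <- atom_table(chain)
  adj <- bond_adjacency(at, chain)
  natom <- nrow(at)
  X <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(vdw[at$element])
  glob <- function(nm) which(at$res_idx == ile & at$name == nm)
  m2 <- which(at$res_idx == ile & at$name %in% ILE_CHI2_ATOMS)
  m1 <- which(at$res_idx == ile & at$name %in%
                setdiff(ILE_CHI1_ATOMS, ILE_CHI2_ATOMS))
  mov <- c(m1, m2)
  stat <- setdiff(seq_len(natom), mov)
  ns <- length(stat)
  pCA <- X[glob("CA"), ]
  pCB <- X[glob("CB"), ]
  axis1 <- X[glob("CB"), ] - pCA
  axis2 <- X[glob("CG1"), ] - pCB

  # chi2-rotated coordinates of the chi2 group, base (chi1 = 0) frame
  n2 <- length(m2)
  A2 <- array(NA_real_, c(n, n2, 3L))
  for (b in seq_len(n)) {
    A2[b, , ] <- rotate_points(X[m2, , drop = FALSE], pCB, axis2, ang[b])
  }
  M1 <- X[m1, , drop = FALSE]

  # per-moving-atom static exclusion columns and radius-sum rows
  excl_cols <- lapply(mov, function(i) match(intersect(excluded_partners(adj, i),
                                                       stat), stat))
  names(excl_cols) <- as.character(mov)
  RSstat <- lapply(mov, function(i) rad[i] + rad[stat])
  names(RSstat) <- as.character(mov)

  # intra-moving allowed pairs (depend on chi2 only, in the base frame)
  intra <- list()
  for (a in seq_along(mov)) {
    for (b in seq_along(mov)) {
      if (b <= a) next
      i <- mov[a]; j <- mov[b]
      if (j %in% excluded_partners(adj, i)) next
      intra[[length(intra) + 1L]] <- c(i, j)
    }
  }
  loc <- function(i) match(i, mov)
  coords_at_b <- function(i, b) {
    if (i %in% m2) A2[b, match(i, m2), ] else X[i, ]
  }
  intraE <- numeric(n)
  iFx <- iFy <- iFz <- matrix(0, n, length(mov))
  for (pr in intra) {
    i <- pr[1L]; j <- pr[2L]
    Pi <- if (i %in% m2) A2[, match(i, m2), ] else
      matrix(X[i, ], n, 3L, byrow = TRUE)
    Pj <- if (j %in% m2) A2[, match(j, m2), ] else
      matrix(X[j, ], n, 3L, byrow = TRUE)
    dvec <- Pi - Pj
    d <- sqrt(rowSums(dvec^2))
    rsum <- rad[i] + rad[j]
    intraE <- intraE + params$intra_scale * pair_energy(d, rsum, params)
    w <- params$intra_scale * pair_dEdd(d, rsum, params) / pmax(d, 0.1)
    iFx[, loc(i)] <- iFx[, loc(i)] - w * dvec[, 1L]
    iFy[, loc(i)] <- iFy[, loc(i)] - w * dvec[, 2L]
    iFz[, loc(i)] <- iFz[, loc(i)] - w * dvec[, 3L]
    iFx[, loc(j)] <- iFx[, loc(j)] + w * dvec[, 1L]
    iFy[, loc(j)] <- iFy[, loc(j)] + w * dvec[, 2L]
    iFz[, loc(j)] <- iFz[, loc(j)] + w * dvec[, 3L]
  }

  S <- X[stat, , drop = FALSE]

  # contact bookkeeping: static pseudo partners + the moving trio
  if (contacts) {
    cp <- scan_contact_precomp(chain, ile, at, adj, stat, vdw)
  }

  E <- matrix(NA_real_, n, n)
  FMAX <- matrix(NA_integer_, n, n)
  MINC <- matrix(NA_real_, n, n)
  CPAIR <- matrix(NA_integer_, n, n)
  atom_labels <- sprintf("%s(%d)", at$name, at$seq_num)

  A2flat <- matrix(A2, n * n2, 3L)
  for (a in seq_len(n)) {
    R1 <- rotation_about_axis(axis1, ang[a])
    rot <- function(M) sweep(sweep(M, 2L, pCA) %*% t(R1), 2L, pCA, "+")
    M1r <- rot(M1)
    A2r <- rot(A2flat)
    Erow <- intraE
    # rotate intra force vectors (no translation for vectors)
    Fmovx <- iFx * R1[1L, 1L] + iFy * R1[1L, 2L] + iFz * R1[1L, 3L]
    Fmovy <- iFx * R1[2L, 1L] + iFy * R1[2L, 2L] + iFz * R1[2L, 3L]
    Fmovz <- iFx * R1[3L, 1L] + iFy * R1[3L, 2L] + iFz * R1[3L, 3L]
    FSx <- FSy <- FSz <- matrix(0, n, ns)
    # chi1-group vs static: constant along the chi2 axis
    for (k in seq_along(m1)) {
      i <- m1[k]
      dv <- t(S) - M1r[k, ]
      d <- sqrt(colSums(dv^2))
      d[excl_cols[[as.character(i)]]] <- BIG_DIST
      Erow <- Erow + sum(pair_energy(d, RSstat[[as.character(i)]], params))
      w <- pair_dEdd(d, RSstat[[as.character(i)]], params) / pmax(d, 0.1)
      Fmovx[, loc(i)] <- Fmovx[, loc(i)] + sum(w * dv[1L, ])
      Fmovy[, loc(i)] <- Fmovy[, loc(i)] + sum(w * dv[2L, ])
      Fmovz[, loc(i)] <- Fmovz[, loc(i)] + sum(w * dv[3L, ])
      FSx <- sweep(FSx, 2L, w * dv[1L, ], "-")
      FSy <- sweep(FSy, 2L, w * dv[2L, ], "-")
      FSz <- sweep(FSz, 2L, w * dv[3L, ], "-")
    }
    # chi2-group vs static
    for (k in seq_len(n2)) {
      i <- m2[k]
      P <- A2r[(k - 1L) * n + seq_len(n), , drop = FALSE]
      dx <- outer(P[, 1L], S[, 1L], "-")
      dy <- outer(P[, 2L], S[, 2L], "-")
      dz <- outer(P[, 3L], S[, 3L], "-")
      d <- sqrt(dx * dx + dy * dy + dz * dz)
      ec <- excl_cols[[as.character(i)]]
      if (length(ec)) d[, ec] <- BIG_DIST
      rs <- RSstat[[as.character(i)]]
      rsm <- matrix(rs, n, ns, byrow = TRUE)
      Erow <- Erow + rowSums(pair_energy(d, rsm, params))
      W <- pair_dEdd(d, rsm, params) / pmax(d, 0.1)
      Fmovx[, loc(i)] <- Fmovx[, loc(i)] - rowSums(W * dx)
      Fmovy[, loc(i)] <- Fmovy[, loc(i)] - rowSums(W * dy)
      Fmovz[, loc(i)] <- Fmovz[, loc(i)] - rowSums(W * dz)
      FSx <- FSx + W * dx
      FSy <- FSy + W * dy
      FSz <- FSz + W * dz
    }
    E[a, ] <- Erow + chi_torsion_energy(ang[a], ang, params)
    # assemble per-atom force norms and take the row-wise argmax
    Fn <- matrix(0, n, natom)
    Fn[, mov] <- sqrt(Fmovx^2 + Fmovy^2 + Fmovz^2)
    Fn[, stat] <- sqrt(FSx^2 + FSy^2 + FSz^2)
    FMAX[a, ] <- max.col(Fn, ties.method = "first")
    if (contacts) {
      cc <- scan_contact_row(cp, a, n, M1r, A2r, m1, m2, at)
      MINC[a, ] <- cc$min
      CPAIR[a, ] <- cc$pair
    }
  }
  structure(list(step = step, angles = ang, energy = E,
                 max_force_atom = FMAX, atom_labels = atom_labels,
                 min_contact = if (contacts) MINC else NULL,
                 closest_pair = if (contacts) CPAIR else NULL,
                 pair_labels = if (contacts) cp$pair_labels else NULL,
                 chain = chain, ile = ile, params = params, vdw = vdw),
            class = "ilerot_scan")
}

# Static (pseudo-)partner table for the contact grids and the allowed
# pairing of the moving trio (QG, MG, MD) with everything else.
scan_contact_precomp <- function(chain, ile, at, adj, stat, vdw) {
  ps <- make_pseudo_atoms(chain)
  padj <- attr(ps, "adj")
  trio_lab <- c("QG", "MG", "MD")
  trio <- match(paste(ile, trio_lab), paste(ps$res_idx, ps$label))
  hb <- which(ps$res_idx == ile & ps$label == "HB")
  moving_rows <- c(trio, hb)
  static_rows <- setdiff(seq_len(nrow(ps)), moving_rows)
  rad <- unname(vdw[ps$cls])
  lab <- sprintf("%s(%d)", ps$label, ps$seq_num)
  partners <- lapply(trio, function(t) {
    setdiff(static_rows, excluded_partners(padj, t))
  })
  # moving partners for each trio member (e.g. MD-MG, MD-HB)
  mov_partners <- lapply(trio, function(t) {
    setdiff(moving_rows, c(t, excluded_partners(padj, t)))
  })
  list(ps = ps, trio = trio, hb = hb, rad = rad, lab = lab,
       partners = partners, mov_partners = mov_partners,
       static_xyz = as.matrix(ps[static_rows, c("x", "y", "z")]),
       static_rows = static_rows,
       pair_labels = lab)
}

# One chi1 row of the contact grids.  Pseudo-atom positions are linear
# combinations of the rotated atom coordinates.
scan_contact_row <- function(cp, a, n, M1r, A2r, m1, m2, at) {
  ile_names_m1 <- at$name[m1]
  ile_names_m2 <- at$name[m2]
  m1pos <- function(nm) M1r[match(nm, ile_names_m1), ]
  m2pos <- function(nm) A2r[(match(nm, ile_names_m2) - 1L) * n + seq_len(n), ,
                            drop = FALSE]
  # centres of mass: QG and MD vary along the row, MG and HB do not
  QG <- (12 * matrix(m1pos("CG1"), n, 3L, byrow = TRUE) +
           m2pos("HG12") + m2pos("HG13")) / 14
  MD <- (12 * m2pos("CD1") + m2pos("HD11") + m2pos("HD12") + m2pos("HD13")) / 15
  MG <- (12 * m1pos("CG2") + m1pos("HG21") + m1pos("HG22") + m1pos("HG23")) / 15
  mov_pos <- list(QG = QG, MG = matrix(MG, n, 3L, byrow = TRUE), MD = MD,
                  HB = matrix(m1pos("HB"), n, 3L, byrow = TRUE))
  bmin <- rep(Inf, n)
  btrio <- bpart <- rep(NA_integer_, n)
  ps <- cp$ps
  for (t_i in seq_along(cp$trio)) {
    t <- cp$trio[t_i]
    P <- mov_pos[[ps$label[t]]]
    part <- cp$partners[[t_i]]
    if (length(part)) {
      Sx <- as.matrix(ps[part, c("x", "y", "z")])
      dx <- outer(P[, 1L], Sx[, 1L], "-")
      dy <- outer(P[, 2L], Sx[, 2L], "-")
      dz <- outer(P[, 3L], Sx[, 3L], "-")
      corr <- sqrt(dx^2 + dy^2 + dz^2) - cp$rad[t] -
        rep(cp$rad[part], each = n)
      k <- max.col(-corr, ties.method = "first")
      v <- corr[cbind(seq_len(n), k)]
      upd <- v < bmin
      bmin[upd] <- v[upd]
      bpart[upd] <- part[k[upd]]
      btrio[upd] <- t
    }
    for (mp in cp$mov_partners[[t_i]]) {
      Q <- mov_pos[[ps$label[mp]]]
      if (is.null(Q)) next
      v <- sqrt(rowSums((P - Q)^2)) - cp$rad[t] - cp$rad[mp]
      upd <- v < bmin
      bmin[upd] <- v[upd]
      bpart[upd] <- mp
      btrio[upd] <- t
    }
  }
  # encode the achieving pair as trio_row * 10000 + partner_row
  list(min = bmin, pair = btrio * 10000L + bpart)
}

#' Decode a closest-pair code from a scan grid
#'
#' @param scan an `ilerot_scan`.
#' @param code integer code from `scan$closest_pair`.
#' @return character vector of two labels.
#' @export
decode_pair <- function(scan, code) {
  c(scan$pair_labels[code %/% 10000L], scan$pair_labels[code %% 10000L])
}

#' Locate the energy-optimal chi1/chi2 conformation of a scan
#'
#' Takes the grid argmin (ties broken toward the smaller chi1, then chi2)
#' and optionally refines it by a deterministic pattern search on the
#' continuous side-chain energy down to 0.05 degree steps.
#'
#' @param scan an `ilerot_scan` from [scan_chi_grid()].
#' @param refine run the local refinement (requires the chain stored in
#'   the scan).
#' @return named numeric `c(chi1, chi2)` in degrees.
#' @export
find_optimum <- function(scan, refine = TRUE) {
  E <- scan$energy
  if (diff(range(E)) < 1e-12) stop("flat energy surface: no unique optimum")
  idx <- which(E == min(E), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
  opt <- c(chi1 = scan$angles[idx[1L]], chi2 = scan$angles[idx[2L]])
  if (!refine || is.null(scan$chain)) return(opt)
  f <- function(c1, c2) side_chain_energy(scan$chain, scan$ile,
                                          wrap360(c1), wrap360(c2),
                                          scan$params, scan$vdw)
  cur <- opt
  fcur <- f(cur[1L], cur[2L])
  h <- scan$step / 2
  while (h >= 0.05) {
    moved <- TRUE
    while (moved) {
      moved <- FALSE
      for (d in list(c(h, 0), c(-h, 0), c(0, h), c(0, -h))) {
        cand <- cur + d
        fc <- f(cand[1L], cand[2L])
        if (fc < fcur - 1e-12) {
          cur <- cand
          fcur <- fc
          moved <- TRUE
        }
      }
    }
    h <- h / 2
  }
  out <- wrap360(cur)
  names(out) <- c("chi1", "chi2")
  out
}
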