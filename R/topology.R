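# Residue and chain containers plus the covalent topology templates used
# by the builders, the torsion setters and the nonbonded exclusion rules.
#
# A residue is a plain list: res_name, chain_id, seq_num, icode, het,
# atoms (named list of atom records) and prev/nxt neighbour indices into
# the owning chain.  An atom record is list(name, element, xyz, occ, b,
# serial).  A chain is a list of residues with class "ilerot_chain".

new_atom <- function(name, xyz, element = NULL, occ = 1, b = 0, serial = NA_integer_) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1L, 1L)
  list(name = name, element = element, xyz = as.numeric(xyz),
       occ = occ, b = b, serial = serial)
}

new_residue <- function(res_name, chain_id = "A", seq_num = 1L, icode = "",
                        het = FALSE) {
  list(res_name = res_name, chain_id = chain_id, seq_num = as.integer(seq_num),
       icode = icode, het = het, atoms = list(),
       prev = NA_integer_, nxt = NA_integer_)
}

new_chain <- function(residues) {
  structure(residues, class = "ilerot_chain")
}

#' @export
print.ilerot_chain <- function(x, ...) {
  cat(sprintf("<ilerot_chain> %d residues (%s), %d atoms\n", length(x),
              paste(unique(vapply(x, `[[`, "", "res_name")), collapse = ","),
              sum(vapply(x, function(r) length(r$atoms), 0L))))
  invisible(x)
}

res_xyz <- function(res, name) {
  a <- res$atoms[[name]]
  if (is.null(a)) NULL else a$xyz
}

has_atoms <- function(res, names) all(names %in% names(res$atoms))

# Heavy atoms an "intact" residue of each type must carry.
REQUIRED_HEAVY <- list(
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  ALA = c("N", "CA", "C", "O", "CB"),
  GLY = c("N", "CA", "C", "O")
)

# Within-residue covalent bonds (by atom name) for the residue types the
# package builds.  Peptide C(i)-N(i+1) bonds are added chain-wise.
RESIDUE_BONDS <- list(
  ALA = list(c("N", "CA"), c("N", "H"), c("CA", "C"), c("CA", "HA"),
             c("CA", "CB"), c("C", "O"),
             c("CB", "HB1"), c("CB", "HB2"), c("CB", "HB3")),
  GLY = list(c("N", "CA"), c("N", "H"), c("CA", "C"), c("CA", "HA2"),
             c("CA", "HA3"), c("C", "O")),
  ILE = list(c("N", "CA"), c("N", "H"), c("CA", "C"), c("CA", "HA"),
             c("CA", "CB"), c("C", "O"),
             c("CB", "HB"), c("CB", "CG1"), c("CB", "CG2"),
             c("CG1", "HG12"), c("CG1", "HG13"), c("CG1", "CD1"),
             c("CG2", "HG21"), c("CG2", "HG22"), c("CG2", "HG23"),
             c("CD1", "HD11"), c("CD1", "HD12"), c("CD1", "HD13"))
)

# Ile side-chain atoms distal to the CA-CB bond (move with chi1) and the
# subset distal to the CB-CG1 bond (move with chi2).
ILE_CHI1_ATOMS <- c("CG1", "CG2", "CD1", "HB", "HG12", "HG13",
                    "HG21", "HG22", "HG23", "HD11", "HD12", "HD13")
ILE_CHI2_ATOMS <- c("CD1", "HG12", "HG13", "HD11", "HD12", "HD13")

# Engh & Huber style backbone geometry (lengths in Angstrom, angles deg).
BACKBONE_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_n_h = 1.00,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_c_n_h = 119.3, omega = 180
)

# Side-chain z-matrix rows: atom placed from frame (a, b, c) with the given
# bond/angle and torsion = `tors` + chi1/chi2 when `ref` is set.  Torsions
# follow the dihedral() sign convention; values match ideal tetrahedral
# amino-acid geometry (staggered methyl protons).
SIDECHAIN_ZMAT <- list(
  ALA = list(
    list(at = "CB",  f = c("C", "N", "CA"),    bond = 1.521, ang = 110.4, tors = -122.6, ref = NA),
    list(at = "HA",  f = c("C", "N", "CA"),    bond = 1.090, ang = 108.5, tors = 120.0,  ref = NA),
    list(at = "HB1", f = c("N", "CA", "CB"),   bond = 1.090, ang = 109.5, tors = 180.0,  ref = NA),
    list(at = "HB2", f = c("N", "CA", "CB"),   bond = 1.090, ang = 109.5, tors = 60.0,   ref = NA),
    list(at = "HB3", f = c("N", "CA", "CB"),   bond = 1.090, ang = 109.5, tors = -60.0,  ref = NA)
  ),
  GLY = list(
    list(at = "HA2", f = c("C", "N", "CA"),    bond = 1.090, ang = 109.5, tors = 120.0,  ref = NA),
    list(at = "HA3", f = c("C", "N", "CA"),    bond = 1.090, ang = 109.5, tors = -120.0, ref = NA)
  ),
  ILE = list(
    list(at = "CB",   f = c("C", "N", "CA"),   bond = 1.540, ang = 110.5, tors = -122.6, ref = NA),
    list(at = "HA",   f = c("C", "N", "CA"),   bond = 1.090, ang = 108.5, tors = 120.0,  ref = NA),
    list(at = "CG1",  f = c("N", "CA", "CB"),  bond = 1.530, ang = 110.4, tors = 0,      ref = "chi1"),
    list(at = "CG2",  f = c("N", "CA", "CB"),  bond = 1.521, ang = 110.5, tors = -120.0, ref = "chi1"),
    list(at = "HB",   f = c("N", "CA", "CB"),  bond = 1.090, ang = 109.5, tors = 120.0,  ref = "chi1"),
    list(at = "CD1",  f = c("CA", "CB", "CG1"), bond = 1.513, ang = 113.8, tors = 0,     ref = "chi2"),
    list(at = "HG12", f = c("CA", "CB", "CG1"), bond = 1.090, ang = 109.4, tors = -120.0, ref = "chi2"),
    list(at = "HG13", f = c("CA", "CB", "CG1"), bond = 1.090, ang = 109.5, tors = 120.0,  ref = "chi2"),
    list(at = "HG21", f = c("CA", "CB", "CG2"), bond = 1.090, ang = 109.5, tors = 60.0,   ref = NA),
    list(at = "HG22", f = c("CA", "CB", "CG2"), bond = 1.090, ang = 109.5, tors = 180.0,  ref = NA),
    list(at = "HG23", f = c("CA", "CB", "CG2"), bond = 1.090, ang = 109.5, tors = -60.0,  ref = NA),
    list(at = "HD11", f = c("CB", "CG1", "CD1"), bond = 1.090, ang = 109.5, tors = 180.0, ref = NA),
    list(at = "HD12", f = c("CB", "CG1", "CD1"), bond = 1.090, ang = 109.5, tors = -60.0, ref = NA),
    list(at = "HD13", f = c("CB", "CG1", "CD1"), bond = 1.090, ang = 109.5, tors = 60.0,  ref = NA)
  )
)

# Flat atom table for a chain: one row per atom with residue bookkeeping.
atom_table <- function(chain) {
  rows <- lapply(seq_along(chain), function(i) {
    r <- chain[[i]]
    if (length(r$atoms) == 0L) return(NULL)
    xyz <- t(vapply(r$atoms, `[[`, numeric(3L), "xyz"))
    data.frame(res_idx = i, res_name = r$res_name, seq_num = r$seq_num,
               name = vapply(r$atoms, `[[`, "", "name"),
               element = vapply(r$atoms, `[[`, "", "element"),
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               occ = vapply(r$atoms, `[[`, 0, "occ"),
               b = vapply(r$atoms, `[[`, 0, "b"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

# Adjacency list (by global atom index into atom_table(chain)) from the
# residue templates plus peptide bonds.  Atoms missing from the template
# (e.g. pseudo-atoms or nonstandard names) stay unbonded.
bond_adjacency <- function(at, chain) {
  n <- nrow(at)
  key <- paste(at$res_idx, at$name)
  idx <- stats::setNames(seq_len(n), key)
  adj <- vector("list", n)
  add <- function(i, j) {
    adj[[i]] <<- c(adj[[i]], j)
    adj[[j]] <<- c(adj[[j]], i)
  }
  for (ri in unique(at$res_idx)) {
    tmpl <- RESIDUE_BONDS[[chain[[ri]]$res_name]]
    if (is.null(tmpl)) next
    for (bd in tmpl) {
      i <- idx[paste(ri, bd[1L])]
      j <- idx[paste(ri, bd[2L])]
      if (!is.na(i) && !is.na(j)) add(i, j)
    }
    nx <- chain[[ri]]$nxt
    if (!is.na(nx)) {
      i <- idx[paste(ri, "C")]
      j <- idx[paste(nx, "N")]
      if (!is.na(i) && !is.na(j)) add(i, j)
    }
  }
  adj
}

# Indices within graph distance <= 2 of atom i (the 1-2/1-3 exclusion set).
excluded_partners <- function(adj, i) {
  one <- adj[[i]]
  unique(c(i, one, unlist(adj[one], use.names = FALSE)))
}
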