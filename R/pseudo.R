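# Pseudo-atom (united methyl/methylene) representation used by the
# contact analysis: every side-chain CH3/CH2 group is replaced by a single
# interaction centre at its centre of mass, with a 2.00 A van der Waals
# radius (RM for methyl, R2Q for methylene).

#' Van der Waals radii for atoms and pseudo-atoms
#'
#' H 1.20, C 1.60, N 1.50, O 1.45 Angstrom; united methyl (RM) and
#' methylene (R2Q) pseudo-atoms 2.00 Angstrom.
#'
#' @return named numeric vector of radii (Angstrom).
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.60, N = 1.50, O = 1.45, RM = 2.00, R2Q = 2.00)
}

#' Van der Waals-corrected distance
#'
#' `d - r_a - r_b`: zero or negative values indicate touching or
#' penetrating spheres.
#'
#' @param d interatomic distance (Angstrom).
#' @param a,b element or pseudo-atom classes (names of [vdw_radii()]).
#' @param vdw radius table.
#' @return corrected distance (Angstrom).
#' @export
vdw_corrected <- function(d, a, b, vdw = vdw_radii()) {
  d - unname(vdw[a]) - unname(vdw[b])
}

PSEUDO_LABELS <- c("ALA.CB" = "MB", "ILE.CG1" = "QG", "ILE.CG2" = "MG",
                   "ILE.CD1" = "MD")

#' Replace methyl and methylene groups by pseudo-atoms
#'
#' Side-chain carbons carrying two or more hydrogens are replaced, together
#' with those hydrogens, by a single pseudo-atom at the mass-weighted
#' centre of the group (C = 12, H = 1).  Alanine CB becomes MB; isoleucine
#' CG1, CG2 and CD1 become QG, MG and MD.  A group whose hydrogens are
#' absent falls back to the heavy-atom position.  Backbone atoms (and the
#' methine CB of isoleucine) are kept as ordinary atoms.
#'
#' @param chain an `ilerot_chain` with hydrogens placed.
#' @return data.frame of interaction centres (`res_idx`, `seq_num`,
#'   `res_name`, `label`, `cls` for radius lookup, `x`, `y`, `z`,
#'   `pseudo`), with the contracted bond adjacency in attribute `"adj"`.
#' @export
make_pseudo_atoms <- function(chain) {
  at <- atom_table(chain)
  adj <- bond_adjacency(at, chain)
  n <- nrow(at)
  node <- seq_len(n)          # atom -> output node (pseudo groups share one)
  is_pseudo <- rep(FALSE, n)
  drop <- rep(FALSE, n)
  coords <- as.matrix(at[, c("x", "y", "z")])
  out_xyz <- coords
  label <- at$name
  cls <- at$element
  backbone <- c("N", "CA", "C", "O", "H", "HA", "HA2", "HA3")
  # expected hydrogen count comes from the residue template, so a group
  # whose hydrogens are missing is still recognized as methyl/methylene
  expected_h <- function(res_name, name) {
    tmpl <- RESIDUE_BONDS[[res_name]]
    if (is.null(tmpl)) return(0L)
    sum(vapply(tmpl, function(bd) bd[1L] == name && startsWith(bd[2L], "H"),
               TRUE))
  }
  for (i in which(at$element == "C" & !(at$name %in% backbone))) {
    n_exp <- expected_h(at$res_name[i], at$name[i])
    if (n_exp < 2L) next
    hs <- adj[[i]][at$element[adj[[i]]] == "H"]
    key <- paste(at$res_name[i], at$name[i], sep = ".")
    label[i] <- if (key %in% names(PSEUDO_LABELS)) PSEUDO_LABELS[[key]] else
      paste0("M", at$name[i])
    cls[i] <- if (n_exp >= 3L) "RM" else "R2Q"
    is_pseudo[i] <- TRUE
    if (length(hs) > 0L) {
      out_xyz[i, ] <- (12 * coords[i, ] + colSums(coords[hs, , drop = FALSE])) /
        (12 + length(hs))
    } else {
      message("pseudo-atom group without hydrogens: using heavy-atom position")
    }
    node[hs] <- i
    drop[hs] <- TRUE
  }
  keep <- which(!drop)
  remap <- match(node, keep)          # original atom -> output row
  df <- data.frame(res_idx = at$res_idx[keep], seq_num = at$seq_num[keep],
                   res_name = at$res_name[keep], label = label[keep],
                   cls = cls[keep], x = out_xyz[keep, 1L],
                   y = out_xyz[keep, 2L], z = out_xyz[keep, 3L],
                   pseudo = is_pseudo[keep], stringsAsFactors = FALSE)
  new_adj <- vector("list", length(keep))
  for (i in seq_len(n)) {
    a <- remap[i]
    for (j in adj[[i]]) {
      b <- remap[j]
      if (a != b) new_adj[[a]] <- c(new_adj[[a]], b)
    }
  }
  attr(df, "adj") <- lapply(new_adj, unique)
  df
}

#' Minimum vdW-corrected contact of the isoleucine pseudo-atoms
#'
#' For one conformation: the minimum, over all pairs of an isoleucine
#' side-chain pseudo-atom (QG, MG, MD) and any other (pseudo-)atom
#' excluding 1-2 and 1-3 interactions, of the distance corrected by both
#' van der Waals radii; the achieving pair is reported.
#'
#' @param chain an `ilerot_chain` with hydrogens.
#' @param ile isoleucine index; found automatically when `NULL`.
#' @param vdw radius table from [vdw_radii()].
#' @return list with `min_contact` (Angstrom), `pair` (two labels,
#'   `"LABEL(seq)"`), and the full per-pseudo-atom table `detail`.
#' @export
min_contact_map <- function(chain, ile = NULL, vdw = vdw_radii()) {
  if (is.null(ile)) ile <- central_ile(chain)
  ps <- make_pseudo_atoms(chain)
  adj <- attr(ps, "adj")
  trio <- which(ps$res_idx == ile & ps$label %in% c("QG", "MG", "MD"))
  if (length(trio) == 0L) stop("no isoleucine pseudo-atoms present")
  xyz <- as.matrix(ps[, c("x", "y", "z")])
  rad <- unname(vdw[ps$cls])
  best <- Inf
  best_pair <- c(NA_character_, NA_character_)
  detail <- list()
  lab <- sprintf("%s(%d)", ps$label, ps$seq_num)
  for (t in trio) {
    excl <- excluded_partners(adj, t)
    part <- setdiff(seq_len(nrow(ps)), excl)
    if (length(part) == 0L) next
    d <- sqrt(colSums((t(xyz[part, , drop = FALSE]) - xyz[t, ])^2))
    corr <- d - rad[t] - rad[part]
    k <- which.min(corr)
    detail[[length(detail) + 1L]] <- data.frame(
      pseudo = lab[t], partner = lab[part[k]], min_contact = corr[k],
      stringsAsFactors = FALSE)
    if (corr[k] < best) {
      best <- corr[k]
      best_pair <- c(lab[t], lab[part[k]])
    }
  }
  if (!is.finite(best)) stop("no admissible contact pair")
  list(min_contact = best, pair = best_pair,
       detail = do.call(rbind, detail))
}
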