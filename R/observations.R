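# Building per-isoleucine candidate observations from parsed structures
# and applying the quality-filter criteria (experimental method, chain
# context, completeness, B factors, secondary structure, geometric
# sanity).

IDEAL_BONDS_ILE <- c("N-CA" = 1.458, "CA-C" = 1.525, "CA-CB" = 1.540,
                     "CB-CG1" = 1.530, "CB-CG2" = 1.521, "CG1-CD1" = 1.513)
CANONICAL_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Filter criteria for isoleucine observations
#'
#' Defaults mirror the published selection table: X-ray entries only, no
#' (peri-)terminal residues, no Gly/Pro/noncanonical neighbours, complete
#' side-chain and backbone atoms, every backbone/CB B factor below
#' `b_max` or below `b_rel` times the chain-average CA B factor, DSSP
#' class H, E or loop, and basic geometric sanity (bond lengths within
#' `bond_tol` of ideal, no non-bonded contact under `clash_min`).
#'
#' @param b_max absolute B-factor ceiling (A^2).
#' @param b_rel relative ceiling as a multiple of the chain CA average.
#' @param exclude_neighbors residue names that disqualify a neighbour;
#'   noncanonical (including HETATM-coded) neighbours always disqualify.
#' @param require_method experiment label required (case-insensitive
#'   prefix match); `NULL` disables the check.
#' @param ss_allowed allowed secondary-structure classes.
#' @param occupancy_min optional minimum atomic occupancy.
#' @param bond_tol,clash_min geometric sanity thresholds (Angstrom).
#' @return list of class `ilerot_filter_criteria`.
#' @export
filter_criteria <- function(b_max = 60, b_rel = 2.5,
                            exclude_neighbors = c("GLY", "PRO"),
                            require_method = "X-RAY", ss_allowed = c("H", "E", "L"),
                            occupancy_min = NULL, bond_tol = 0.2, clash_min = 1.5) {
  stopifnot(b_max > 0, b_rel > 0)
  structure(list(b_max = b_max, b_rel = b_rel,
                 exclude_neighbors = exclude_neighbors,
                 require_method = require_method, ss_allowed = ss_allowed,
                 occupancy_min = occupancy_min, bond_tol = bond_tol,
                 clash_min = clash_min),
            class = "ilerot_filter_criteria")
}

ile_geometry_flags <- function(chain, i, bond_tol, clash_min) {
  r <- chain[[i]]
  bad_bond <- FALSE
  for (bn in names(IDEAL_BONDS_ILE)) {
    nm <- strsplit(bn, "-")[[1L]]
    p1 <- res_xyz(r, nm[1L]); p2 <- res_xyz(r, nm[2L])
    if (is.null(p1) || is.null(p2)) next
    if (abs(v_norm(p2 - p1) - IDEAL_BONDS_ILE[[bn]]) > bond_tol) bad_bond <- TRUE
  }
  # non-bonded clash: side-chain atoms vs atoms of residues i-1 .. i+1
  side <- c("CB", "CG1", "CG2", "CD1")
  bonded <- list(CB = c("N", "CA", "C", "CG1", "CG2", "CD1"),
                 CG1 = c("CA", "CB", "CG2", "CD1"),
                 CG2 = c("CA", "CB", "CG1"),
                 CD1 = c("CB", "CG1"))
  clash <- FALSE
  nbr_idx <- c(if (!is.na(r$prev)) r$prev, i, if (!is.na(r$nxt)) r$nxt)
  for (s in side) {
    ps <- res_xyz(r, s)
    if (is.null(ps)) next
    for (k in nbr_idx) {
      for (a in chain[[k]]$atoms) {
        if (a$element == "H") next
        if (k == i && (a$name == s || a$name %in% bonded[[s]])) next
        if (k != i && s == "CB" && a$name == "C" && k == r$prev) next
        if (v_norm(a$xyz - ps) < clash_min) clash <- TRUE
      }
    }
  }
  list(bad_bond = bad_bond, clash = clash)
}

#' Extract isoleucine candidate observations from a parsed structure
#'
#' Collects one row per isoleucine with its torsions, secondary structure
#' (from a DSSP table when supplied, else the builtin assigner), B-factor
#' summaries, neighbour context and structure metadata.  No filtering
#' happens here; [apply_filters()] consumes the result.
#'
#' @param parsed result of [parse_pdb()] (or a compatible list with
#'   `chains` and `meta`).
#' @param dssp optional data.frame from [read_dssp()].
#' @param criteria [filter_criteria()]; only the geometric thresholds are
#'   used at extraction time.
#' @return data.frame of candidates (one row per isoleucine).
#' @export
extract_ile_observations <- function(parsed, dssp = NULL,
                                     criteria = filter_criteria()) {
  rows <- list()
  meta <- parsed$meta
  for (ch in names(parsed$chains)) {
    chain <- parsed$chains[[ch]]
    rn <- vapply(chain, `[[`, "", "res_name")
    idx <- which(rn == "ILE" & !vapply(chain, `[[`, TRUE, "het"))
    if (length(idx) == 0L) next
    ss_chain <- if (is.null(dssp)) assign_ss(chain) else NULL
    ca_b <- vapply(chain, function(r) {
      a <- r$atoms[["CA"]]
      if (is.null(a)) NA_real_ else a$b
    }, 0)
    mean_ca_b <- mean(ca_b, na.rm = TRUE)
    for (i in idx) {
      r <- chain[[i]]
      tor <- measure_torsions(chain, i)
      if (is.null(dssp)) {
        ss <- ss_chain[i]; ss_source <- "builtin"
      } else {
        m <- dssp$ss[dssp$chain_id == r$chain_id & dssp$seq_num == r$seq_num]
        ss <- if (length(m) == 1L) m else NA_character_
        ss_source <- "dssp_file"
      }
      nbrs <- c(r$prev, r$nxt)
      nbr_names <- vapply(nbrs, function(k) {
        if (is.na(k)) NA_character_ else chain[[k]]$res_name
      }, "")
      nbr_het <- vapply(nbrs, function(k) {
        if (is.na(k)) FALSE else isTRUE(chain[[k]]$het)
      }, TRUE)
      bsel <- intersect(c("N", "CA", "C", "O", "CB"), names(r$atoms))
      bvals <- vapply(r$atoms[bsel], `[[`, 0, "b")
      geo <- ile_geometry_flags(chain, i, criteria$bond_tol, criteria$clash_min)
      pp <- classify_phipsi(tor$phi, tor$psi)
      rows[[length(rows) + 1L]] <- data.frame(
        entry_id = meta$entry_id %||% NA_character_,
        chain_id = r$chain_id, seq_num = r$seq_num,
        chi1 = tor$chi1, chi2 = tor$chi2, phi = tor$phi, psi = tor$psi,
        ss = ss, ss_source = ss_source, phipsi_class = pp,
        subclass = subclassify(ss, pp),
        resolution = meta$resolution %||% NA_real_,
        program = if (length(meta$programs) == 1L) meta$programs else
          if (length(meta$programs) > 1L) "mixed" else NA_character_,
        year = meta$year %||% NA_integer_,
        method = meta$method %||% NA_character_,
        is_terminal = is.na(r$prev) || is.na(r$nxt),
        next_to_terminus = (!is.na(r$prev) && is.na(chain[[r$prev]]$prev)) ||
          (!is.na(r$nxt) && is.na(chain[[r$nxt]]$nxt)),
        neighbor_gly_pro = any(nbr_names %in% c("GLY", "PRO"), na.rm = TRUE),
        neighbor_noncanonical = any(nbr_het | !(nbr_names %in% CANONICAL_AA),
                                    na.rm = TRUE),
        complete = has_atoms(r, REQUIRED_HEAVY$ILE),
        b_max_atom = if (length(bvals)) max(bvals) else NA_real_,
        mean_ca_b = mean_ca_b,
        min_occ = min(vapply(r$atoms, `[[`, 0, "occ")),
        bad_bond = geo$bad_bond, clash = geo$clash,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  ok <- is.finite(out$chi1) & is.finite(out$chi2)
  out$section <- NA_integer_
  out$section[ok] <- section_of(out$chi1[ok], out$chi2[ok])
  out
}

#' Apply the selection criteria to candidate observations
#'
#' Every candidate is either retained or rejected with a reason; rejection
#' is data, not an error.  A residue fails the B-factor criterion when any
#' backbone or CB atom exceeds both the absolute ceiling and the relative
#' ceiling (`b_rel` times the chain CA average).  The result is
#' independent of the input row order.
#'
#' @param candidates data.frame from [extract_ile_observations()].
#' @param criteria a [filter_criteria()] object.
#' @return list with `observations` (retained rows) and `audit`
#'   (entry/chain/seq plus the first failed criterion per rejected row).
#' @export
apply_filters <- function(candidates, criteria = filter_criteria()) {
  if (nrow(candidates) == 0L) {
    return(list(observations = candidates,
                audit = data.frame(entry_id = character(0L),
                                   chain_id = character(0L),
                                   seq_num = integer(0L),
                                   reason = character(0L))))
  }
  cand <- candidates
  reason <- rep(NA_character_, nrow(cand))
  flag <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  if (!is.null(criteria$require_method)) {
    flag(is.na(cand$method) |
           !startsWith(toupper(cand$method), toupper(criteria$require_method)),
         "method")
  }
  flag(cand$is_terminal | cand$next_to_terminus, "terminal")
  nbr_bad <- cand$neighbor_noncanonical
  if ("GLY" %in% criteria$exclude_neighbors || "PRO" %in% criteria$exclude_neighbors) {
    nbr_bad <- nbr_bad | cand$neighbor_gly_pro
  }
  flag(nbr_bad, "neighbor")
  flag(!cand$complete | !is.finite(cand$chi1) | !is.finite(cand$chi2),
       "missing_atoms")
  b_ok <- cand$b_max_atom < criteria$b_max |
    cand$b_max_atom < criteria$b_rel * cand$mean_ca_b
  flag(!b_ok, "b_factor")
  flag(is.na(cand$ss) | !(cand$ss %in% criteria$ss_allowed), "ss")
  if (!is.null(criteria$occupancy_min)) {
    flag(cand$min_occ < criteria$occupancy_min, "occupancy")
  }
  flag(cand$bad_bond | cand$clash, "geometry")
  keep <- is.na(reason)
  list(
    observations = cand[keep, , drop = FALSE],
    audit = data.frame(entry_id = cand$entry_id[!keep],
                       chain_id = cand$chain_id[!keep],
                       seq_num = cand$seq_num[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  )
}
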