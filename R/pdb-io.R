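# PDB-format and DSSP-format input/output.  ATOM/HETATM records are read
# through bio3d; header metadata (REMARK 2 resolution, REMARK 3 refinement
# programs, EXPDTA, HEADER date) is parsed from the raw text since bio3d
# does not expose it.

DEFAULT_PROGRAM_MAP <- list(
  c("^REFMAC", "REFMAC"),
  c("^CNS", "CNS"),
  c("^X-?PLOR", "X-PLOR"),
  c("^PHENIX", "PHENIX"),
  c("^SHELX", "SHELX"),
  c("^BUSTER", "BUSTER"),
  c("^TNT", "TNT")
)

normalize_program <- function(x, program_map = DEFAULT_PROGRAM_MAP) {
  x <- toupper(trimws(x))
  vapply(x, function(p) {
    for (m in program_map) if (grepl(m[1L], p)) return(m[2L])
    "other"
  }, "", USE.NAMES = FALSE)
}

as_pdb_lines <- function(x) {
  if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
}

#' Extract structure-level metadata from PDB header records
#'
#' Reads the resolution (REMARK 2), refinement programs (REMARK 3 PROGRAM,
#' normalized against a configurable mapping), experimental method
#' (EXPDTA), deposition year and entry id (HEADER).
#'
#' @param x path to a PDB file or a character vector of its lines.
#' @param program_map list of `c(regex, canonical)` pairs; unmatched
#'   programs map to `"other"`.
#' @return list with `entry_id`, `resolution` (Angstrom or `NA`),
#'   `method`, `programs` (character vector), `mixed_programs`, `year`.
#' @export
extract_metadata <- function(x, program_map = DEFAULT_PROGRAM_MAP) {
  lines <- as_pdb_lines(x)
  meta <- list(entry_id = NA_character_, resolution = NA_real_,
               method = NA_character_, programs = character(0L),
               mixed_programs = FALSE, year = NA_integer_)
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) >= 1L) {
    id <- trimws(substr(hdr[1L], 63L, 66L))
    if (nzchar(id)) meta$entry_id <- id
    yy <- suppressWarnings(as.integer(substr(hdr[1L], 58L, 59L)))
    if (!is.na(yy)) meta$year <- if (yy <= 30L) 2000L + yy else 1900L + yy
  }
  r2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(r2) >= 1L) {
    num <- regmatches(r2[1L], regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)",
                                      r2[1L], perl = TRUE))
    if (length(num) == 1L) meta$resolution <- as.numeric(num)
  }
  ex <- grep("^EXPDTA", lines, value = TRUE)
  if (length(ex) >= 1L) meta$method <- trimws(substr(ex[1L], 11L, 79L))
  pr <- grep("^REMARK   3\\s+PROGRAM\\s*:", lines, value = TRUE)
  progs <- character(0L)
  for (ln in pr) {
    val <- sub("^.*PROGRAM\\s*:", "", ln)
    toks <- trimws(strsplit(val, ",")[[1L]])
    toks <- toks[nzchar(toks) & toks != "NULL"]
    progs <- c(progs, normalize_program(toks, program_map))
  }
  meta$programs <- unique(progs)
  meta$mixed_programs <- length(meta$programs) > 1L
  meta
}

#' Parse a PDB-format coordinate file into residue chains
#'
#' ATOM/HETATM records are read with bio3d.  Alternate locations are
#' resolved per residue to the conformer with the highest summed
#' occupancy (ties broken by altloc letter order).  Residues are linked to
#' their chain neighbours unless the peptide C-N distance exceeds 2.5
#' Angstrom or either atom is missing (chain break).
#'
#' @param x path to a PDB file or a character vector of its lines.
#' @param program_map passed to [extract_metadata()].
#' @return list with `chains` (named list of `ilerot_chain`) and `meta`.
#' @export
parse_pdb <- function(x, program_map = DEFAULT_PROGRAM_MAP) {
  lines <- as_pdb_lines(x)
  if (!any(grepl("^ATOM  ", lines))) stop("no ATOM records in input")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    warning(sprintf("skipped %d malformed atom records", sum(bad)))
    at <- at[!bad, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no parseable atom records")
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(rkey[at$alt != ""])) {
    sel <- which(rkey == k & at$alt != "")
    occ_by_alt <- tapply(at$o[sel], at$alt[sel], sum)
    best <- names(occ_by_alt)[order(-occ_by_alt, names(occ_by_alt))][1L]
    keep[sel[at$alt[sel] != best]] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  rkey <- rkey[keep]
  chains <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    rids <- unique(paste(sub$resno, sub$insert, sep = "|"))
    residues <- vector("list", length(rids))
    for (j in seq_along(rids)) {
      rsel <- sub[paste(sub$resno, sub$insert, sep = "|") == rids[j], , drop = FALSE]
      r <- new_residue(rsel$resid[1L], chain_id = ch, seq_num = rsel$resno[1L],
                       icode = rsel$insert[1L], het = rsel$type[1L] == "HETATM")
      for (a in seq_len(nrow(rsel))) {
        el <- trimws(rsel$elesy[a])
        if (is.na(el) || !nzchar(el)) el <- substr(gsub("[0-9]", "", rsel$elety[a]), 1L, 1L)
        r$atoms[[rsel$elety[a]]] <- new_atom(rsel$elety[a],
                                             c(rsel$x[a], rsel$y[a], rsel$z[a]),
                                             element = el, occ = rsel$o[a],
                                             b = rsel$b[a], serial = rsel$eleno[a])
      }
      residues[[j]] <- r
    }
    for (j in seq_along(residues)[-1L]) {
      cprev <- res_xyz(residues[[j - 1L]], "C")
      nthis <- res_xyz(residues[[j]], "N")
      linked <- !is.null(cprev) && !is.null(nthis) &&
        v_norm(nthis - cprev) <= 2.5
      if (linked) {
        residues[[j - 1L]]$nxt <- j
        residues[[j]]$prev <- j - 1L
      }
    }
    chains[[ch]] <- new_chain(residues)
  }
  list(chains = chains, meta = extract_metadata(lines, program_map))
}

#' Write chains to PDB format
#'
#' Emits HEADER/EXPDTA/REMARK 2/REMARK 3 records from `meta` followed by
#' fixed-column ATOM records, so the package can round-trip its own
#' synthetic structures.
#'
#' @param chains a single `ilerot_chain` or a list of them.
#' @param meta metadata list as returned by [extract_metadata()]; optional
#'   fields are skipped when `NA`.
#' @param file optional path; when `NULL` the lines are returned.
#' @param hydrogens write hydrogen atoms too (default `FALSE`: synthetic
#'   X-ray style output carries heavy atoms only).
#' @return invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(chains, meta = list(), file = NULL, hydrogens = FALSE) {
  if (inherits(chains, "ilerot_chain")) chains <- list(chains)
  if (length(chains) == 0L || all(vapply(chains, length, 0L) == 0L)) {
    stop("write_pdb: no residues to write")
  }
  lines <- character(0L)
  if (!is.null(meta$year) && !is.na(meta$year)) {
    dt <- sprintf("01-JAN-%02d", meta$year %% 100L)
    id <- if (!is.null(meta$entry_id) && !is.na(meta$entry_id)) meta$entry_id else "XXXX"
    lines <- c(lines, sprintf("%-50s%9s   %4s", "HEADER    SYNTHETIC PROTEIN", dt, id))
  }
  if (!is.null(meta$method) && !is.na(meta$method)) {
    lines <- c(lines, sprintf("EXPDTA    %s", meta$method))
  }
  if (!is.null(meta$resolution) && !is.na(meta$resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              meta$resolution))
  } else {
    lines <- c(lines, "REMARK   2 RESOLUTION. NOT APPLICABLE.")
  }
  for (p in meta$programs %||% character(0L)) {
    lines <- c(lines, sprintf("REMARK   3   PROGRAM     : %s", p))
  }
  serial <- 0L
  for (chain in chains) {
    for (r in chain) {
      for (a in r$atoms) {
        if (!hydrogens && identical(a$element, "H")) next
        if (any(abs(a$xyz) >= 10000) || any(a$xyz <= -1000)) {
          stop("coordinate exceeds PDB fixed-column field width")
        }
        serial <- serial + 1L
        nm <- if (nchar(a$name) >= 4L) a$name else sprintf(" %-3s", a$name)
        lines <- c(lines, sprintf(
          "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (isTRUE(r$het)) "HETATM" else "ATOM", serial, nm, "",
          r$res_name, r$chain_id, r$seq_num, r$icode,
          a$xyz[1L], a$xyz[2L], a$xyz[3L], a$occ, a$b, a$element))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a DSSP assignment file
#'
#' Parses the classic fixed-column DSSP output and collapses the 8-state
#' alphabet to the three classes used throughout: H (alpha helix), E
#' (extended strand) and L (everything else: G, I, T, S, B or blank).
#'
#' @param x path to a DSSP file or a character vector of its lines.
#' @return data.frame with `chain_id`, `seq_num`, `ss`.
#' @export
read_dssp <- function(x) {
  lines <- as_pdb_lines(x)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L) stop("not a DSSP file: residue table header missing")
  body <- lines[seq.int(hdr + 1L, length(lines))]
  aa <- substr(body, 14L, 14L)
  body <- body[aa != "!" & nzchar(trimws(body))]
  seq_num <- as.integer(substr(body, 6L, 10L))
  chain_id <- substr(body, 12L, 12L)
  code <- substr(body, 17L, 17L)
  ss <- ifelse(code == "H", "H", ifelse(code == "E", "E", "L"))
  data.frame(chain_id = chain_id, seq_num = seq_num, ss = ss,
             stringsAsFactors = FALSE)
}
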