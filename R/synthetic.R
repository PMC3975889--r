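# Synthetic structure sets with known rotamer distributions, resolution
# and refinement-program labels, and a configurable resolution-dependent
# pull of the observed torsions toward per-program target angles.  Every
# pipeline stage can be validated against the generated ground truth.

DEFAULT_SECTION_WEIGHTS <- c(0.004, 0.004, 0.06, 0.10, 0.12, 0.52,
                             0.03, 0.10, 0.062)
DEFAULT_SECTION_MEANS <- rbind(
  c(60, 300), c(180, 300), c(300, 300),   # sections 1-3 (chi2 g-)
  c(60, 180), c(180, 180), c(293, 162),   # sections 4-6 (chi2 t)
  c(60, 60), c(180, 60), c(300, 60)       # sections 7-9 (chi2 g+)
)
colnames(DEFAULT_SECTION_MEANS) <- c("chi1", "chi2")

#' Linear resolution-dependent bias weight
#'
#' Returns a function `lambda(resolution)` that is 0 up to `onset`
#' (refinement bias is negligible at atomic resolution), rises linearly
#' and saturates at `lambda_max` from `end` on.  The default `lambda_max`
#' makes the pull equal 10 degrees at 3.0 Angstrom for a target 20
#' degrees away from the truth.
#'
#' @param onset,end resolution (Angstrom) where the bias starts and
#'   saturates.
#' @param lambda_max plateau value in `[0, 1]`.
#' @return function mapping resolution to a weight in `[0, 1]`.
#' @export
lambda_linear <- function(onset = 1.2, end = 3.5, lambda_max = 0.639) {
  stopifnot(lambda_max >= 0, lambda_max <= 1, end > onset)
  function(resolution) {
    lambda_max * pmin(pmax((resolution - onset) / (end - onset), 0), 1)
  }
}

#' Pull a true torsion toward a refinement target
#'
#' `observed = true + lambda(res) * wrap(target - true) + noise`, the
#' generative model for refinement-software bias: negligible at high
#' resolution, approaching the program's target angle at low resolution.
#'
#' @param true_angle,target_angle degrees.
#' @param resolution Angstrom.
#' @param lambda_fn weight function, e.g. [lambda_linear()].
#' @param noise_sd Gaussian noise added after the pull (degrees).
#' @return observed angle in `[0, 360)`.
#' @export
biased_torsion <- function(true_angle, target_angle, resolution,
                           lambda_fn = lambda_linear(), noise_sd = 0) {
  lam <- lambda_fn(resolution)
  if (any(lam < 0 | lam > 1)) stop("lambda outside [0, 1]")
  n <- max(length(true_angle), length(target_angle), length(resolution))
  wrap360(true_angle + lam * wrap180(target_angle - true_angle) +
            stats::rnorm(n, 0, noise_sd))
}

#' Specification of a synthetic structure set
#'
#' The defaults describe a plausible archive-like set: helical hosts, the
#' nine sections populated very unevenly with more than half of all
#' isoleucines in section 6 (chi1 g-, chi2 t), per-section spreads of 8
#' degrees, resolutions uniform between 1.0 and 3.0 Angstrom and no
#' refinement bias.
#'
#' @param n_ile total number of isoleucines to place.
#' @param residues_per_chain chain length (one chain per structure).
#' @param section_weights probability of each of the nine sections.
#' @param section_means 9 x 2 matrix of per-section (chi1, chi2) means.
#' @param sigma per-axis Gaussian spread of the true torsions (degrees).
#' @param resolution_range range for uniform resolution sampling, or
#'   `resolutions`, an explicit pool sampled with replacement.
#' @param resolutions optional explicit resolution pool (Angstrom).
#' @param programs named numeric vector of program sampling weights.
#' @param program_offsets named list of per-program `c(dchi1, dchi2)`
#'   target offsets added to the section mean.
#' @param lambda_fn resolution-bias weight function ([lambda_linear()]).
#' @param noise_sd extra observation noise applied with the bias.
#' @param violation_rate fraction of isoleucines given a deliberate
#'   quality-filter violation (inflated B factor or missing CD1).
#' @param b_base mean atomic B factor (A^2); clean values stay below 50.
#' @return list of class `ilerot_synth_spec`.
#' @export
synthetic_spec <- function(n_ile = 2000, residues_per_chain = 24,
                           section_weights = DEFAULT_SECTION_WEIGHTS,
                           section_means = DEFAULT_SECTION_MEANS,
                           sigma = 8, resolution_range = c(1.0, 3.0),
                           resolutions = NULL,
                           programs = c(REFMAC = 0.5, CNS = 0.5),
                           program_offsets = NULL,
                           lambda_fn = lambda_linear(), noise_sd = 0,
                           violation_rate = 0, b_base = 20) {
  stopifnot(length(section_weights) == 9L, all(section_weights >= 0),
            abs(sum(section_weights) - 1) < 1e-8, sigma >= 0,
            nrow(section_means) == 9L, n_ile >= 1)
  if (is.null(program_offsets)) {
    program_offsets <- stats::setNames(rep(list(c(0, 0)), length(programs)),
                                       names(programs))
  }
  structure(list(n_ile = n_ile, residues_per_chain = residues_per_chain,
                 section_weights = section_weights,
                 section_means = section_means, sigma = sigma,
                 resolution_range = resolution_range,
                 resolutions = resolutions, programs = programs,
                 program_offsets = program_offsets, lambda_fn = lambda_fn,
                 noise_sd = noise_sd, violation_rate = violation_rate,
                 b_base = b_base),
            class = "ilerot_synth_spec")
}

#' Generate a synthetic structure set with ground truth
#'
#' Builds idealized helical hosts with isoleucines at interior positions
#' flanked by alanines, draws true rotamers from the per-section
#' distributions, poses the side chains at the bias-distorted observed
#' torsions, assigns B factors, occupancies and header metadata, and
#' optionally plants quality-filter violations.  Fully reproducible from
#' the seed; PDB output is byte-identical across runs.
#'
#' @param spec an [synthetic_spec()] object.
#' @param dir optional output directory for PDB files.
#' @param seed integer seed driving all randomness.
#' @return list with `structures` (parsed-form list per structure:
#'   `chains`, `meta`), `files` (paths or `NULL`) and `ground_truth`
#'   (one row per placed isoleucine).
#' @export
generate_dataset <- function(spec, dir = NULL, seed = 1) {
  stopifnot(inherits(spec, "ilerot_synth_spec"))
  set.seed(seed)
  len <- spec$residues_per_chain
  ile_pos <- seq(4L, len - 3L, by = 2L)
  if (length(ile_pos) == 0L) stop("chain too short to place an interior Ile")
  n_struct <- ceiling(spec$n_ile / length(ile_pos))
  gt <- list()
  structures <- vector("list", n_struct)
  files <- if (!is.null(dir)) character(n_struct) else NULL
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  placed <- 0L
  for (s in seq_len(n_struct)) {
    entry <- sprintf("S%03d", s)
    resol <- if (!is.null(spec$resolutions)) {
      spec$resolutions[sample.int(length(spec$resolutions), 1L)]
    } else {
      stats::runif(1L, spec$resolution_range[1L], spec$resolution_range[2L])
    }
    resol <- round(resol, 2L)
    program <- sample(names(spec$programs), 1L, prob = spec$programs)
    year <- sample(1995:2012, 1L)
    pos <- ile_pos[seq_len(min(length(ile_pos), spec$n_ile - placed))]
    chain <- build_multi_ile_helix(len, pos)
    b_chain <- pmin(pmax(spec$b_base * exp(stats::rnorm(1L, 0, 0.2)), 8), 35)
    for (ri in seq_along(chain)) {
      for (an in names(chain[[ri]]$atoms)) {
        chain[[ri]]$atoms[[an]]$b <-
          round(pmin(pmax(b_chain * exp(stats::rnorm(1L, 0, 0.15)), 5), 50), 2L)
      }
    }
    for (p in pos) {
      placed <- placed + 1L
      sec <- sample.int(9L, 1L, prob = spec$section_weights)
      true1 <- wrap360(stats::rnorm(1L, spec$section_means[sec, 1L], spec$sigma))
      true2 <- wrap360(stats::rnorm(1L, spec$section_means[sec, 2L], spec$sigma))
      off <- spec$program_offsets[[program]] %||% c(0, 0)
      tgt1 <- wrap360(spec$section_means[sec, 1L] + off[1L])
      tgt2 <- wrap360(spec$section_means[sec, 2L] + off[2L])
      obs1 <- biased_torsion(true1, tgt1, resol, spec$lambda_fn, spec$noise_sd)
      obs2 <- biased_torsion(true2, tgt2, resol, spec$lambda_fn, spec$noise_sd)
      chain[[p]] <- set_side_chain(chain[[p]], obs1, obs2)
      violation <- NA_character_
      if (spec$violation_rate > 0 &&
          stats::runif(1L) < spec$violation_rate) {
        violation <- sample(c("b_factor", "missing_atoms"), 1L)
        if (violation == "b_factor") {
          for (an in c("N", "CA", "C", "O", "CB")) {
            chain[[p]]$atoms[[an]]$b <- round(stats::runif(1L, 120, 200), 2L)
          }
        } else {
          chain[[p]]$atoms[["CD1"]] <- NULL
        }
      }
      gt[[length(gt) + 1L]] <- data.frame(
        entry_id = entry, chain_id = "A", seq_num = p,
        true_chi1 = true1, true_chi2 = true2,
        obs_chi1 = obs1, obs_chi2 = obs2, section = sec,
        resolution = resol, program = program, year = year,
        violation = violation, stringsAsFactors = FALSE)
    }
    meta <- list(entry_id = entry, resolution = resol,
                 method = "X-RAY DIFFRACTION", programs = program,
                 mixed_programs = FALSE, year = year)
    structures[[s]] <- list(chains = list(A = chain), meta = meta)
    if (!is.null(dir)) {
      files[s] <- file.path(dir, paste0(entry, ".pdb"))
      write_pdb(chain, meta, file = files[s])
    }
  }
  list(structures = structures, files = files,
       ground_truth = do.call(rbind, gt))
}

# Helical host with several interior isoleucines (neighbours all Ala).
build_multi_ile_helix <- function(len, ile_positions) {
  chain <- build_ideal_secondary("helix", n = len, ile_pos = ile_positions[1L])
  for (p in ile_positions[-1L]) {
    # rebuild residue p as ILE on its existing backbone frame
    r <- chain[[p]]
    r$res_name <- "ILE"
    r$atoms <- r$atoms[intersect(c("N", "CA", "C", "O", "H"), names(r$atoms))]
    chain[[p]] <- build_side_chain(r, 0, 0)
  }
  chain
}
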