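# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of (seed, parameters): identical inputs give identical data,
# and the planted truth ships with each dataset so downstream recovery can be
# asserted.

#' Generate a toy receptor-ligand complex with a planted interface
#'
#' The receptor is an idealized backbone trace (CA spacing 3.8 Angstrom along
#' x, with N, C, O atoms at fixed local offsets); the ligand is a chain of
#' single-atom residues. A seeded subset of receptor residues is pulled
#' towards a ligand contact plane so that the nearest ligand atom sits at
#' exactly `contact_distance`, while every other receptor residue stays more
#' than 8 Angstrom (the guard band) away from all ligand atoms. Interface
#' detection at a 6 Angstrom cutoff therefore recovers exactly the planted
#' set.
#'
#' @param seed Integer seed.
#' @param n_receptor_res,n_ligand_res Residue counts (ligand needs at least
#'   one residue per planted contact).
#' @param n_interface Number of planted interface residues.
#' @param contact_distance Planted receptor-ligand contact distance in
#'   Angstrom (must be < 6).
#' @param receptor_chain,ligand_chain Chain ids.
#' @param resname_seed Seed for the receptor residue identities (defaults to
#'   `seed`); hold it fixed across seeds to emulate crystallographically
#'   distinct copies of one and the same receptor molecule.
#' @param path Optional path; when given, the complex is also written as PDB.
#' @return List with `structure` (a `complex_structure`), `truth` (planted
#'   interface residue numbers and generator parameters) and `path`.
#' @export
make_toy_complex <- function(seed = 1, n_receptor_res = 60, n_ligand_res = 30,
                             n_interface = 12, contact_distance = 4.5,
                             receptor_chain = "R", ligand_chain = "L",
                             resname_seed = seed, path = NULL) {
  if (n_interface > n_receptor_res)
    abort_generation("more interface residues than receptor residues")
  if (n_interface > n_ligand_res)
    abort_generation("need at least one ligand residue per planted contact")
  if (contact_distance >= 6 || contact_distance <= 1.5)
    abort_generation("'contact_distance' must lie in (1.5, 6) Angstrom")
  guard_y <- 8.5   # ligand contact plane height; baseline residues stay > 8 A

  planted <- if (n_interface > 0)
    sort(with_seed(child_seed(seed, 1L),
                   sample.int(n_receptor_res, n_interface)))
  else integer()
  resnames <- with_seed(child_seed(resname_seed, 2L),
                        sample(AA3, n_receptor_res, replace = TRUE))

  rows <- list()
  for (i in seq_len(n_receptor_res)) {
    ca_y <- if (i %in% planted) guard_y - contact_distance else 0
    ca <- c(3.8 * i, ca_y, 0)
    offs <- list(N = c(-1.2, 0.4, 0), CA = c(0, 0, 0), C = c(1.2, 0.4, 0),
                 O = c(1.4, -0.8, 0))
    for (nm in names(offs)) {
      p <- ca + offs[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = receptor_chain, resno = i, insert = "", resname = resnames[i],
        atom = nm, element = substr(nm, 1L, 1L), altloc = "", occ = 1,
        x = p[1L], y = p[2L], z = p[3L], het = FALSE, hydrogen = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  # ligand: one contact atom above each planted residue, decoys far away
  lig_x <- c(3.8 * planted, 3.8 * seq_len(n_ligand_res - n_interface))
  lig_y <- c(rep(guard_y, n_interface),
             rep(20, n_ligand_res - n_interface))
  for (j in seq_len(n_ligand_res)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chain = ligand_chain, resno = j, insert = "", resname = "GLY",
      atom = "CA", element = "C", altloc = "", occ = 1,
      x = lig_x[j], y = lig_y[j], z = 0, het = FALSE, hydrogen = FALSE,
      stringsAsFactors = FALSE)
  }
  s <- new_structure(sprintf("TOY%04d", seed %% 10000L), do.call(rbind, rows))
  truth <- list(interface_resno = planted, receptor_chain = receptor_chain,
                ligand_chain = ligand_chain,
                contact_distance = contact_distance, guard_distance = 8,
                seed = seed)
  if (!is.null(path)) write_structure_pdb(s, path)
  list(structure = s, truth = truth, path = path)
}

#' Write a `complex_structure` as PDB
#' @param s A `complex_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  at <- s$atoms
  n <- nrow(at)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(n), elety = at$atom,
                   chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   alt = ifelse(at$altloc == "", NA, at$altloc),
                   o = at$occ, b = rep(0, n), elesy = at$element)
  invisible(path)
}

#' Generate an alignment with planted per-column conservation
#'
#' Builds `n_seq` gapless sequences aligned to a reference such that column
#' `j` matches the reference residue in `round(identity_j * n_seq)` sequences
#' (clamped to at least the reference itself). Which sequences match, and the
#' substituted residues elsewhere, are seeded draws.
#'
#' @param seed Integer seed.
#' @param n_seq Number of sequences (reference included).
#' @param ref_sequence Reference amino-acid string (no gaps).
#' @param per_position_identity Planted identity fraction(s), recycled to the
#'   reference length.
#' @param ref_id Id of the reference record.
#' @return List with `alignment` (an `msa_alignment`) and `truth` (realized
#'   per-column match counts and fractions).
#' @export
make_msa <- function(seed = 1, n_seq = 32, ref_sequence,
                     per_position_identity = 0.5, ref_id = "REF") {
  ref <- strsplit(toupper(ref_sequence), "")[[1L]]
  if (!all(ref %in% AA1))
    abort_generation("'ref_sequence' must use one-letter amino-acid codes")
  L <- length(ref)
  frac <- rep_len(per_position_identity, L)
  if (any(frac < 0 | frac > 1))
    abort_generation("identity fractions must be in [0, 1]")
  n_match <- pmin(pmax(round(frac * n_seq), 1L), n_seq)

  m <- matrix("", nrow = n_seq, ncol = L)
  m[1L, ] <- ref
  with_seed(child_seed(seed, 3L), {
    for (j in seq_len(L)) {
      extra <- n_match[j] - 1L   # matches besides the reference
      others <- 2:n_seq
      who <- if (extra > 0) sample(others, extra) else integer()
      m[who, j] <- ref[j]
      rest <- setdiff(others, who)
      if (length(rest)) {
        alt <- setdiff(AA1, ref[j])
        m[rest, j] <- sample(alt, length(rest), replace = TRUE)
      }
    }
  })
  ids <- c(ref_id, sprintf("seq%02d", 2:n_seq))
  aln <- new_alignment(ids, apply(m, 1L, paste, collapse = ""))
  list(alignment = aln,
       truth = list(n_match = n_match, fraction = n_match / n_seq,
                    seed = seed))
}

#' Generate a ddG matrix with planted favorable/unfavorable mutations
#'
#' Background mutations draw both energy types from a mildly destabilizing
#' Gaussian (sign-unconstrained). Planted stabilizing mutations are strictly
#' negative for both stability and affinity on every interface with a margin
#' of at least `3 * noise_sd` below zero; planted destabilizing mutations have
#' strictly positive affinity and strictly negative stability on every
#' interface with the same margin.
#'
#' @param seed Integer seed.
#' @param positions Data frame with columns `position` and `wt` (one-letter
#'   codes) listing the scanned positions.
#' @param n_interfaces Number of crystallographic interfaces (default 4).
#' @param planted_stabilizing,planted_destabilizing Character vectors of
#'   mutation labels (must lie on scanned positions).
#' @param noise_sd Interface-to-interface spread in kJ/mol.
#' @param n_mut_per_position Number of mutant residues generated per position
#'   (default 19, i.e. the full scan). The scanned subset is drawn from
#'   `subset_seed` only — not from `seed` — so matrices generated with
#'   different seeds (e.g. snapshot ensembles) share one key set; planted
#'   mutations are always included.
#' @param subset_seed Seed controlling which mutant residues are scanned.
#' @return List with `matrix` (a `ddg_matrix`) and `truth`.
#' @export
make_ddg_matrix <- function(seed = 1, positions,
                            n_interfaces = 4,
                            planted_stabilizing = character(),
                            planted_destabilizing = character(),
                            noise_sd = 1, n_mut_per_position = 19,
                            subset_seed = 0) {
  stopifnot(is.data.frame(positions),
            all(c("position", "wt") %in% names(positions)))
  margin <- 3 * noise_sd + 0.5
  ifs <- sprintf("interface_%d", seq_len(n_interfaces))
  plant_s <- if (length(planted_stabilizing))
    do.call(rbind, lapply(planted_stabilizing, parse_mutation)) else NULL
  plant_d <- if (length(planted_destabilizing))
    do.call(rbind, lapply(planted_destabilizing, parse_mutation)) else NULL
  for (pl in list(plant_s, plant_d)) {
    if (!is.null(pl) &&
        !all(paste(pl$position, pl$wt) %in%
             paste(positions$position, positions$wt)))
      abort_generation("planted mutations must lie on scanned positions")
  }
  mut_sets <- with_seed(child_seed(subset_seed, 5L),
    lapply(seq_len(nrow(positions)), function(r) {
      pos <- positions$position[r]; wt <- positions$wt[r]
      muts <- setdiff(AA1, wt)
      forced <- character()
      for (pl in list(plant_s, plant_d))
        if (!is.null(pl)) forced <- c(forced, pl$mut[pl$position == pos])
      if (n_mut_per_position < 19) {
        free <- setdiff(muts, forced)
        muts <- sort(c(forced,
                       sample(free, max(n_mut_per_position - length(forced),
                                        0L))))
      }
      unique(muts)
    }))
  rows <- with_seed(child_seed(seed, 4L), {
    out <- list()
    for (r in seq_len(nrow(positions))) {
      pos <- positions$position[r]; wt <- positions$wt[r]
      for (mut in mut_sets[[r]]) {
        lbl_s <- !is.null(plant_s) &&
          any(plant_s$position == pos & plant_s$mut == mut)
        lbl_d <- !is.null(plant_d) &&
          any(plant_d$position == pos & plant_d$mut == mut)
        for (ty in c("stability", "affinity")) {
          v <- if (lbl_s) {
            -(margin + abs(stats::rnorm(n_interfaces, 0, noise_sd)))
          } else if (lbl_d) {
            sgn <- if (ty == "affinity") 1 else -1
            sgn * (margin + abs(stats::rnorm(n_interfaces, 0, noise_sd)))
          } else {
            stats::rnorm(n_interfaces, mean = 4, sd = max(noise_sd, 1.5))
          }
          out[[length(out) + 1L]] <- data.frame(
            position = pos, wt = wt, mut = mut, interface = ifs,
            type = ty, ddg = v, stringsAsFactors = FALSE)
        }
      }
    }
    out
  })
  m <- new_ddg_matrix(do.call(rbind, rows), ifs)
  list(matrix = m,
       truth = list(stabilizing = sort(planted_stabilizing),
                    destabilizing = sort(planted_destabilizing),
                    margin = margin, seed = seed))
}

#' Default SPR analyte concentration series
#'
#' Three-fold dilutions from 99 nM down to 1.2 nM, in M.
#' @param top Top concentration in M.
#' @param dilution Dilution factor.
#' @param n Number of concentrations.
#' @return Numeric vector of concentrations in M.
#' @export
concentration_series <- function(top = 99e-9, dilution = 3, n = 5)
  top / dilution^(seq_len(n) - 1L)

#' Generate a referenced sensorgram set at a concentration series
#'
#' One active curve per concentration via [simulate_sensorgram()], plus a
#' non-binding reference-channel curve (drift only) and a flat interspot
#' curve, each with independent seeded noise — the raw material for double
#' referencing and global kinetic fitting.
#'
#' @param seed Integer seed.
#' @param p A [kinetic_params()] object (the planted truth).
#' @param concentrations Analyte concentrations in M.
#' @param noise_sd Gaussian noise sd in RU.
#' @param t_assoc,t_dissoc,dt Time grid, seconds.
#' @return List with `curves` (per concentration: `active`, `reference`,
#'   `interspot`) and `truth`.
#' @export
make_sensorgram_set <- function(seed = 1, p, concentrations = concentration_series(),
                                noise_sd = 0, t_assoc = 90, t_dissoc = 600,
                                dt = 0.1) {
  stopifnot(inherits(p, "kinetic_params"))
  ref_p <- kinetic_params(p$ka, p$kd_rate, p$Rmax, drift = p$drift, R0 = p$R0)
  curves <- lapply(seq_along(concentrations), function(i) {
    base <- child_seed(seed, 10L + 3L * i)
    ref <- simulate_sensorgram(ref_p, 0, t_assoc, t_dissoc, dt, noise_sd,
                               seed = base + 1L, channel = "reference")
    isp <- simulate_sensorgram(
      kinetic_params(p$ka, p$kd_rate, p$Rmax, drift = 0, R0 = 0), 0,
      t_assoc, t_dissoc, dt, noise_sd, seed = base + 2L,
      channel = "interspot")
    # non-binding channels are acquired at the same analyte concentration
    attr(ref, "concentration") <- concentrations[i]
    attr(isp, "concentration") <- concentrations[i]
    list(active = simulate_sensorgram(p, concentrations[i], t_assoc,
                                      t_dissoc, dt, noise_sd, seed = base,
                                      channel = "active"),
         reference = ref, interspot = isp)
  })
  names(curves) <- sprintf("%.4gnM", concentrations * 1e9)
  list(curves = curves,
       truth = list(params = p, concentrations = concentrations,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a two-state melt curve with planted Tm
#'
#' Fluorescence model: sigmoid `amplitude / (1 + exp((tm - T)/slope))` plus
#' optional linear pre/post baselines and Gaussian noise, on a regular
#' temperature grid (default 20-75 C in 0.5 C steps).
#'
#' @param seed Integer seed.
#' @param tm Planted melting temperature, degrees C.
#' @param slope Transition width parameter, degrees C (default 1.5).
#' @param t_min,t_max,dt Temperature grid, degrees C.
#' @param baseline_slope Linear baseline slope, AU per degree C.
#' @param amplitude Transition amplitude, AU.
#' @param noise_sd Gaussian noise sd, AU.
#' @return List with `curve` (a `melt_curve`) and `truth`.
#' @export
make_melt_curve <- function(seed = 1, tm = 55, slope = 1.5, t_min = 20,
                            t_max = 75, dt = 0.5, baseline_slope = 0,
                            amplitude = 1, noise_sd = 0) {
  stopifnot_scalar_positive(slope, "slope")
  temp <- seq(t_min, t_max, by = dt)
  f <- amplitude / (1 + exp((tm - temp) / slope)) + baseline_slope * temp
  if (noise_sd > 0)
    f <- f + with_seed(child_seed(seed, 7L),
                       stats::rnorm(length(temp), sd = noise_sd))
  list(curve = melt_curve(temp, f),
       truth = list(tm = tm, slope = slope, noise_sd = noise_sd, seed = seed))
}
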