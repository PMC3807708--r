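#' Parse a protein complex structure from PDB or mmCIF
#'
#' Reads a crystal structure and returns a light-weight atom table restricted
#' to the first model. Alternate-location duplicates are resolved by keeping
#' the highest-occupancy conformer (ties broken by altloc letter). Hydrogen
#' atoms, if deposited, are retained but flagged so that distance-based
#' operations can exclude them.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"cif"`.
#' @return An object of class `complex_structure`: a list with `entry_id`,
#'   `model_index` (always 1) and `atoms`, a data frame with one row per atom
#'   (columns `chain`, `resno`, `insert`, `resname`, `atom`, `element`,
#'   `altloc`, `occ`, `x`, `y`, `z`, `het`, `hydrogen`).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_io(sprintf("cannot read structure file '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) abort_io(sprintf("failed to parse '%s': %s", path,
                                         conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    abort_format(sprintf("'%s' contains no atoms", path))

  chain <- as.character(at$chain)
  chain[is.na(chain)] <- ""
  insert <- as.character(at$insert)
  insert[is.na(insert)] <- ""
  altloc <- as.character(at$alt)
  altloc[is.na(altloc)] <- ""
  occ <- suppressWarnings(as.numeric(at$o))
  occ[is.na(occ)] <- 1
  element <- toupper(as.character(at$elesy))
  element[is.na(element) | element == ""] <-
    guess_element(at$elety[is.na(element) | element == ""])

  atoms <- data.frame(
    chain = chain,
    resno = as.integer(at$resno),
    insert = insert,
    resname = toupper(as.character(at$resid)),
    atom = toupper(as.character(at$elety)),
    element = element,
    altloc = altloc,
    occ = occ,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE)
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    abort_format(sprintf("'%s' contains non-finite coordinates", path))

  atoms <- resolve_altloc(atoms)
  if (all(atoms$chain == ""))
    abort_format(sprintf("'%s' declares no chains", path))

  new_structure(entry_id = toupper(sub("\\.[^.]*$", "", basename(path))),
                atoms = atoms)
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", toupper(as.character(atom_name)))
  one <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  # two-letter elements that appear as full atom names (metals, halides);
  # "CA" is deliberately absent — in polymer records it is the alpha carbon
  out <- ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA"), two, one)
  out[out == ""] <- "X"
  out
}

# keep the highest-occupancy altloc conformer per atom site; ties broken by
# altloc letter (blank sorts first)
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$chain, atoms$resno, atoms$insert, atoms$atom), ,
        drop = FALSE]
}

new_structure <- function(entry_id, atoms, model_index = 1L) {
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, model_index = as.integer(model_index),
                 atoms = atoms),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  ch <- table(x$atoms$chain[!x$atoms$het])
  cat(sprintf("<complex_structure> %s, model %d\n", x$entry_id, x$model_index))
  for (cid in names(ch)) {
    n_res <- nrow(unique(x$atoms[x$atoms$chain == cid & !x$atoms$het,
                                 c("resno", "insert")]))
    cat(sprintf("  chain %s: %d residues, %d atoms\n", cid, n_res, ch[[cid]]))
  }
  invisible(x)
}

structure_chains <- function(s) unique(s$atoms$chain)

#' Construct a residue selection
#'
#' An ordered, duplicate-free set of residue identities on named chains — the
#' unit in which interfaces and control sets are expressed. Ordering is
#' deterministic: chain, then residue number, then insertion code.
#'
#' @param chain,resno,insert,resname Parallel vectors of chain id, author
#'   residue number, insertion code (`""` if none) and 3-letter residue name
#'   (`NA` allowed).
#' @param label Free-text label describing the selection.
#' @param structure_ref Identifier of the structure the selection refers to.
#' @return A `residue_selection`, a data frame with the columns above.
#' @export
residue_selection <- function(chain, resno, insert = "", resname = NA_character_,
                              label = "", structure_ref = "") {
  n <- length(resno)
  df <- data.frame(chain = rep_len(as.character(chain), n),
                   resno = as.integer(resno),
                   insert = rep_len(as.character(insert), n),
                   resname = rep_len(as.character(resname), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chain, df$resno, df$insert), , drop = FALSE]
  key <- paste(df$chain, df$resno, df$insert, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- tapply(df$resname, key, function(v) length(unique(v[!is.na(v)])))
    if (any(clash > 1L, na.rm = TRUE))
      abort_argument("duplicate residues with conflicting residue names")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("residue_selection", "data.frame"),
            label = label, structure_ref = structure_ref)
}

selection_key <- function(sel) paste(sel$chain, sel$resno, sel$insert, sep = "\r")

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("<residue_selection> %d residues%s\n", nrow(x),
              if (nzchar(attr(x, "label"))) paste0(" [", attr(x, "label"), "]")
              else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Identify receptor residues at a protein-protein interface
#'
#' A receptor residue belongs to the interface when the minimum distance
#' between any of its atoms and any atom of the ligand chains is less than or
#' equal to `cutoff` (boundary inclusive). By default only non-hydrogen,
#' non-hetero (i.e. polymer) atoms enter the distance computation, which makes
#' the result independent of whether hydrogens or waters were deposited.
#'
#' @param s A `complex_structure`.
#' @param receptor_chain Chain id of the receptor.
#' @param ligand_chains Character vector of ligand chain ids.
#' @param cutoff Distance cutoff in Angstrom (default 6.0).
#' @param include_hydrogens,include_hetero Include hydrogen / HETATM records in
#'   the distance scan (default `FALSE`).
#' @param label Label stored on the returned selection.
#' @return A `residue_selection` of interface residues on the receptor chain.
#' @export
interface_residues <- function(s, receptor_chain, ligand_chains, cutoff = 6.0,
                               include_hydrogens = FALSE,
                               include_hetero = FALSE,
                               label = sprintf("interface<=%.1fA", cutoff)) {
  stopifnot(inherits(s, "complex_structure"))
  stopifnot_scalar_positive(cutoff, "cutoff")
  chains <- structure_chains(s)
  missing <- setdiff(c(receptor_chain, ligand_chains), chains)
  if (length(missing))
    abort_argument(sprintf("chain(s) not in structure: %s",
                           paste(missing, collapse = ", ")))
  at <- s$atoms
  keep <- rep(TRUE, nrow(at))
  if (!include_hydrogens) keep <- keep & !at$hydrogen
  if (!include_hetero) keep <- keep & !at$het
  rec <- at[keep & at$chain == receptor_chain, , drop = FALSE]
  lig <- at[keep & at$chain %in% ligand_chains, , drop = FALSE]
  if (nrow(rec) == 0L || nrow(lig) == 0L)
    return(residue_selection(character(), integer(), character(),
                             label = label, structure_ref = s$entry_id))

  dmin <- min_dist_per_group(
    as.matrix(rec[, c("x", "y", "z")]),
    as.matrix(lig[, c("x", "y", "z")]),
    group = paste(rec$resno, rec$insert, sep = "\r"))
  hit <- names(dmin)[dmin <= cutoff]
  idx <- match(hit, paste(rec$resno, rec$insert, sep = "\r"))
  residue_selection(chain = receptor_chain, resno = rec$resno[idx],
                    insert = rec$insert[idx], resname = rec$resname[idx],
                    label = label, structure_ref = s$entry_id)
}

# minimum Euclidean distance from each group of rows in A to any row of B
min_dist_per_group <- function(A, B, group) {
  # squared-distance matrix via the usual expansion; sizes here are small
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  dmin2 <- apply(d2, 1L, min)
  sqrt(tapply(dmin2, group, min))
}

#' Union of residue selections on a common numbering
#'
#' Set union with deterministic ordering. All selections must refer to
#' equivalent chains through a shared reference numbering (use
#' [remap_selection()] to move selections from crystallographically distinct
#' chains onto one reference chain id first). Residues with the same
#' (chain, number, insertion code) but conflicting residue names indicate an
#' incompatible numbering map and raise an error.
#'
#' @param selections A list of `residue_selection` objects.
#' @param label Label for the combined selection.
#' @return A `residue_selection`.
#' @export
union_selections <- function(selections, label = "union") {
  if (!length(selections)) abort_argument("no selections given")
  stopifnot(all(vapply(selections, inherits, TRUE, "residue_selection")))
  all <- do.call(rbind, lapply(selections, as.data.frame))
  tryCatch(
    residue_selection(all$chain, all$resno, all$insert, all$resname,
                      label = label,
                      structure_ref = paste(unique(unlist(
                        lapply(selections, attr, "structure_ref"))),
                        collapse = "+")),
    affidesign_argument_error = function(e)
      abort_argument("incompatible numbering: same residue key maps to different residue names"))
}

#' Re-label a selection onto a reference chain id
#'
#' Crystal structures often contain several copies of the same molecule under
#' different chain ids; to union their interfaces the residues must share one
#' numbering frame. All four receptor copies in this system carry identical
#' author numbering, so remapping amounts to renaming the chain.
#'
#' @param sel A `residue_selection`.
#' @param chain Reference chain id to assign.
#' @param offset Optional residue-number offset to add.
#' @return A `residue_selection` on the reference chain.
#' @export
remap_selection <- function(sel, chain, offset = 0L) {
  residue_selection(chain, sel$resno + as.integer(offset), sel$insert,
                    sel$resname, label = attr(sel, "label"),
                    structure_ref = attr(sel, "structure_ref"))
}

#' Least-squares superposition and RMSD over paired residues
#'
#' Residues of the two selections are paired one-to-one by shared residue
#' number and insertion code; the requested atoms (default main-chain N, CA,
#' C, O) of each pair are collected and the optimal rigid-body superposition
#' (Kabsch, via singular value decomposition) of the mobile onto the target
#' coordinates is computed. With `fit_on_same_atoms = TRUE` (default) the fit
#' uses exactly the atoms the RMSD is evaluated on; otherwise the fit uses all
#' residues common to the two chains and only the evaluation is restricted to
#' the selection.
#'
#' @param mobile,target `complex_structure` objects.
#' @param mobile_sel,target_sel `residue_selection` objects on one chain each.
#' @param atom_names Atom names entering the superposition (default main chain).
#' @param fit_on_same_atoms Fit on the evaluated atoms (default) or on all
#'   common residues.
#' @return A `superposition` object: list with `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (Angstrom), `n_atoms`.
#' @export
superpose_rmsd <- function(mobile, mobile_sel, target, target_sel,
                           atom_names = c("N", "CA", "C", "O"),
                           fit_on_same_atoms = TRUE) {
  eval_pair <- paired_coords(mobile, mobile_sel, target, target_sel, atom_names)
  fit_pair <- eval_pair
  if (!fit_on_same_atoms) {
    mob_all <- chain_selection(mobile, unique(mobile_sel$chain))
    tar_all <- chain_selection(target, unique(target_sel$chain))
    common <- intersect(paste(mob_all$resno, mob_all$insert, sep = "\r"),
                        paste(tar_all$resno, tar_all$insert, sep = "\r"))
    keep_m <- paste(mob_all$resno, mob_all$insert, sep = "\r") %in% common
    keep_t <- paste(tar_all$resno, tar_all$insert, sep = "\r") %in% common
    fit_pair <- paired_coords(mobile, mob_all[keep_m, , drop = FALSE],
                              target, tar_all[keep_t, , drop = FALSE],
                              atom_names, drop_incomplete = TRUE)
  }
  if (nrow(fit_pair$P) < 3L)
    abort_degenerate("fewer than 3 paired atoms for superposition")

  k <- kabsch(fit_pair$P, fit_pair$Q)
  moved <- sweep(eval_pair$P, 2L, k$center_p) %*% t(k$rotation)
  moved <- sweep(moved, 2L, k$center_q, "+")
  rmsd <- sqrt(mean(rowSums((moved - eval_pair$Q)^2)))
  structure(list(rotation = k$rotation,
                 translation = as.numeric(k$center_q - k$rotation %*% k$center_p),
                 rmsd = rmsd, n_atoms = nrow(eval_pair$P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

chain_selection <- function(s, chain) {
  at <- s$atoms[s$atoms$chain %in% chain & !s$atoms$het, , drop = FALSE]
  res <- unique(at[, c("chain", "resno", "insert", "resname")])
  residue_selection(res$chain, res$resno, res$insert, res$resname,
                    structure_ref = s$entry_id)
}

paired_coords <- function(mobile, mobile_sel, target, target_sel, atom_names,
                          drop_incomplete = FALSE) {
  km <- paste(mobile_sel$resno, mobile_sel$insert, sep = "\r")
  kt <- paste(target_sel$resno, target_sel$insert, sep = "\r")
  if (!setequal(km, kt) || length(km) != length(kt))
    abort(sprintf("selections do not pair 1:1 (%d vs %d residues)",
                  length(km), length(kt)), "affidesign_pairing_error")
  grab <- function(s, sel) {
    at <- s$atoms[s$atoms$chain %in% unique(sel$chain) &
                    s$atoms$atom %in% atom_names, , drop = FALSE]
    key <- paste(at$resno, at$insert, at$atom, sep = "\r")
    want <- as.vector(outer(paste(sel$resno, sel$insert, sep = "\r"),
                            atom_names, paste, sep = "\r"))
    idx <- match(want, key)
    list(idx = idx, at = at, want = want)
  }
  gm <- grab(mobile, mobile_sel)
  gt <- grab(target, target_sel)
  ok <- !is.na(gm$idx) & !is.na(gt$idx)
  if (!drop_incomplete && any(!ok)) {
    missing <- unique(sub("\r[^\r]*$", "",
                          gm$want[!ok]))
    abort(sprintf("%d residue(s) lack requested atoms (e.g. residue %s)",
                  length(missing), gsub("\r", ":", missing[1L])),
          "affidesign_pairing_error")
  }
  list(P = as.matrix(gm$at[gm$idx[ok], c("x", "y", "z")]),
       Q = as.matrix(gt$at[gt$idx[ok], c("x", "y", "z")]))
}

# Kabsch: optimal proper rotation mapping centred P onto centred Q
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))          # H = P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, center_p = cp, center_q = cq)
}

#' Apply a rigid transform to a structure
#'
#' @param s A `complex_structure`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation in Angstrom.
#' @return The transformed `complex_structure`.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  s$atoms$x <- xyz[, 1L]; s$atoms$y <- xyz[, 2L]; s$atoms$z <- xyz[, 3L]
  s
}

#' Random control selection outside an excluded set
#'
#' Uniform sample, without replacement, of residues on the excluded set's
#' chain(s) that are not part of the excluded set — used to contrast interface
#' RMSDs with randomly chosen non-interface residues.
#'
#' @param s A `complex_structure`.
#' @param exclude A `residue_selection` to exclude (its chains define the
#'   eligible pool unless `chain` is given).
#' @param n Number of residues to draw.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @param chain Optional chain id(s) restricting the pool.
#' @return A `residue_selection` of `n` control residues.
#' @export
random_control_selection <- function(s, exclude, n, seed,
                                     chain = unique(exclude$chain)) {
  stopifnot(inherits(s, "complex_structure"))
  pool <- chain_selection(s, chain)
  pool <- pool[!(selection_key(pool) %in% selection_key(exclude)), ,
               drop = FALSE]
  if (n > nrow(pool))
    abort_argument(sprintf("requested %d residues but only %d eligible",
                           n, nrow(pool)))
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  residue_selection(pool$chain[idx], pool$resno[idx], pool$insert[idx],
                    pool$resname[idx],
                    label = sprintf("random_control_n%d_seed%d", n, seed),
                    structure_ref = s$entry_id)
}

#' Per-residue root-mean-square fluctuation over an ensemble
#'
#' For every residue in `selection`, the RMSF of each selected atom about its
#' ensemble-mean position is computed over the coordinate frames and averaged
#' over the residue's atoms.
#'
#' @param frames List (length >= 2) of `complex_structure` objects with
#'   identical topology.
#' @param selection A `residue_selection`.
#' @param atom_names Optional atom-name filter (default: all atoms present).
#' @return A data frame `chain`, `resno`, `insert`, `rmsf` (Angstrom).
#' @export
ensemble_rmsf <- function(frames, selection, atom_names = NULL) {
  if (length(frames) < 2L) abort_argument("need at least 2 frames")
  stopifnot(all(vapply(frames, inherits, TRUE, "complex_structure")))
  pick <- function(s) {
    at <- s$atoms[paste(s$atoms$chain, s$atoms$resno, s$atoms$insert,
                        sep = "\r") %in% selection_key(selection), ,
                  drop = FALSE]
    if (!is.null(atom_names)) at <- at[at$atom %in% atom_names, , drop = FALSE]
    at[order(at$chain, at$resno, at$insert, at$atom), , drop = FALSE]
  }
  ref <- pick(frames[[1L]])
  if (nrow(ref) == 0L) abort_argument("selection matches no atoms")
  coords <- vapply(frames, function(s) {
    at <- pick(s)
    if (nrow(at) != nrow(ref) ||
        !identical(paste(at$chain, at$resno, at$insert, at$atom),
                   paste(ref$chain, ref$resno, ref$insert, ref$atom)))
      abort_argument("frames differ in atom content for the selection")
    as.matrix(at[, c("x", "y", "z")])
  }, matrix(0, nrow(ref), 3L))
  mean_xyz <- apply(coords, c(1L, 2L), mean)
  dev2 <- apply((coords - as.vector(mean_xyz))^2, c(1L, 3L), sum)
  atom_rmsf <- sqrt(rowMeans(dev2))
  res_key <- paste(ref$chain, ref$resno, ref$insert, sep = "\r")
  per_res <- tapply(atom_rmsf, res_key, mean)
  first <- ref[!duplicated(res_key), , drop = FALSE]
  out <- data.frame(chain = first$chain, resno = first$resno,
                    insert = first$insert,
                    rmsf = as.numeric(per_res[res_key[!duplicated(res_key)]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a residue selection as TSV
#'
#' Serialized as a BED-like TSV with columns `chain`, `resno`, `icode`,
#' `resname`, `label`.
#' @param sel A `residue_selection`.
#' @param path Output path.
#' @return `write_selection_tsv` returns `path` invisibly;
#'   `read_selection_tsv` returns a `residue_selection`.
#' @export
write_selection_tsv <- function(sel, path) {
  df <- data.frame(chain = sel$chain, resno = sel$resno, icode = sel$insert,
                   resname = sel$resname, label = attr(sel, "label"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection_tsv
#' @export
read_selection_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(icode = "character"))
  need <- c("chain", "resno", "icode", "resname")
  if (!all(need %in% names(df)))
    abort_format(sprintf("selection TSV must have columns %s",
                         paste(need, collapse = ", ")))
  df$icode[is.na(df$icode)] <- ""
  residue_selection(df$chain, df$resno, df$icode, df$resname,
                    label = if ("label" %in% names(df) && nrow(df))
                      df$label[1L] else "")
}

#' Serialize a superposition result as JSON
#'
#' Rotation is written row-major.
#' @param sp A `superposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superposition_json <- function(sp, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(sp$rotation)), translation = sp$translation,
         rmsd = sp$rmsd, n_atoms = sp$n_atoms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
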