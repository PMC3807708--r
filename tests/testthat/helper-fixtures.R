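# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# Format an atom table as PDB text (one MODEL when model is given).
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, bfac = 0, altloc = " ", icode = " ",
                          element = substr(name, 1L, 1L)) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, altloc, resname, chain, resno, icode, x, y, z,
          occ, bfac, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Structure with a handful of CA atoms at given coordinates (one residue per
# row of xyz), used for superposition tests.
ca_cloud_pdb <- function(xyz, chain = "A", path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    pdb_atom_line(i, "CA", "GLY", chain, i, xyz[i, 1L], xyz[i, 2L],
                  xyz[i, 3L], element = "C"), "")
  write_pdb_text(lines, path)
}

ca_cloud_structure <- function(xyz, chain = "A") {
  parse_structure(ca_cloud_pdb(xyz, chain))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

# Exhaustive all-pairs interface oracle: residue included iff any non-H,
# non-het receptor atom is within cutoff of any such ligand atom.
brute_force_interface <- function(s, receptor_chain, ligand_chains, cutoff) {
  at <- s$atoms[!s$atoms$hydrogen & !s$atoms$het, , drop = FALSE]
  rec <- at[at$chain == receptor_chain, , drop = FALSE]
  lig <- at[at$chain %in% ligand_chains, , drop = FALSE]
  keys <- unique(paste(rec$resno, rec$insert, sep = "/"))
  hit <- vapply(keys, function(k) {
    r <- rec[paste(rec$resno, rec$insert, sep = "/") == k, , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(lig))) {
      d <- sqrt((r$x[i] - lig$x[j])^2 + (r$y[i] - lig$y[j])^2 +
                  (r$z[i] - lig$z[j])^2)
      if (d <= cutoff) { found <- TRUE; break }
    }
    found
  }, TRUE)
  sort(as.integer(sub("/.*", "", keys[hit])))
}

# Exhaustive filter oracle for candidate selection (stabilize mode,
# all-interface criteria, conservation veto).
brute_force_select <- function(m, profile, aff_thr = 0, stab_thr = 0,
                               cons_thr = 0.65, offset = 0L) {
  muts <- unique(m[, c("position", "wt", "mut")])
  sel <- character()
  for (i in seq_len(nrow(muts))) {
    rows <- m[m$position == muts$position[i] & m$wt == muts$wt[i] &
                m$mut == muts$mut[i], , drop = FALSE]
    ok <- all(rows$ddg[rows$type == "affinity"] < aff_thr) &&
      all(rows$ddg[rows$type == "stability"] < stab_thr)
    frac <- profile$fraction[profile$position == muts$position[i] + offset]
    if (ok && length(frac) == 1L && frac <= cons_thr)
      sel <- c(sel, mutation_label(muts$wt[i], muts$position[i], muts$mut[i]))
  }
  sort(sel)
}

# Published kinetic parameters of the wild-type receptor (SPR, 25 C).
wt_kinetics <- function(Rmax = 120, drift = 0)
  kinetic_params(ka = 1.24e6, kd_rate = 3.78e-2, Rmax = Rmax, drift = drift)
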