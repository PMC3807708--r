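test_that("parsing round-trips generator output and flags hydrogens", {
  tc <- make_toy_complex(seed = 11, n_receptor_res = 20, n_ligand_res = 10,
                         n_interface = 4, path = tempfile(fileext = ".pdb"))
  s <- parse_structure(tc$path)
  expect_s3_class(s, "complex_structure")
  expect_setequal(unique(s$atoms$chain), c("R", "L"))
  expect_equal(sum(s$atoms$chain == "R"), 20 * 4)   # N, CA, C, O per residue
  expect_equal(sum(s$atoms$chain == "L"), 10)
  expect_false(any(s$atoms$hydrogen))
  expect_error(parse_structure(tempfile()), class = "affidesign_io_error")
})

test_that("only model 1 is read and the highest-occupancy altloc wins", {
  lines <- c(
    "MODEL        1",
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6, altloc = "A",
                  element = "C"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 9.0, 0, 0, occ = 0.4, altloc = "B",
                  element = "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "N", "ALA", "A", 1, 99, 99, 99),
    "ENDMDL")
  s <- parse_structure(write_pdb_text(lines))
  expect_equal(nrow(s$atoms), 2L)              # model 2 dropped, one CA kept
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_equal(ca$occ, 0.6)
  expect_equal(ca$x, 1.0)
  # occupancy tie: altloc letter breaks it
  lines2 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.5,
                            altloc = "A", element = "C"),
              pdb_atom_line(2, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.5,
                            altloc = "B", element = "C"))
  s2 <- parse_structure(write_pdb_text(lines2))
  expect_equal(s2$atoms$x, 1)
})

test_that("interface cutoff boundary is inclusive", {
  mk <- function(d) {
    lines <- c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
               pdb_atom_line(2, "CA", "GLY", "B", 1, d, 0, 0, element = "C"))
    parse_structure(write_pdb_text(lines))
  }
  expect_equal(interface_residues(mk(5.9), "A", "B", 6.0)$resno, 1L)
  expect_equal(interface_residues(mk(6.0), "A", "B", 6.0)$resno, 1L)
  expect_equal(nrow(interface_residues(mk(6.1), "A", "B", 6.0)), 0L)
  expect_error(interface_residues(mk(5), "A", "Z", 6.0),
               class = "affidesign_argument_error")
})

test_that("interface detection equals the exhaustive all-pairs oracle", {
  for (seed in 1:20) {
    tc <- make_toy_complex(seed = seed, n_receptor_res = 40,
                           n_ligand_res = 20, n_interface = (seed %% 8) + 1,
                           contact_distance = 3 + (seed %% 3))
    got <- interface_residues(tc$structure, "R", "L", 6.0)$resno
    expect_equal(got, brute_force_interface(tc$structure, "R", "L", 6.0),
                 info = sprintf("seed %d", seed))
  }
})

test_that("interface size is monotonically non-decreasing in the cutoff", {
  tc <- make_toy_complex(seed = 5, n_receptor_res = 40, n_ligand_res = 25,
                         n_interface = 8)
  sizes <- vapply(c(2, 4, 5, 6, 8, 12, 25),
                  function(cf) nrow(interface_residues(tc$structure, "R", "L",
                                                       cf)), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("selection union is a set union: commutative, associative, idempotent", {
  a <- residue_selection("R", c(10L, 12L))
  b <- residue_selection("R", c(12L, 14L))
  c3 <- residue_selection("R", 99L)
  expect_equal(union_selections(list(a, a))$resno, c(10L, 12L))
  expect_equal(union_selections(list(a, b))$resno, c(10L, 12L, 14L))
  expect_equal(union_selections(list(a, b))$resno,
               union_selections(list(b, a))$resno)
  expect_equal(
    union_selections(list(union_selections(list(a, b)), c3))$resno,
    union_selections(list(a, union_selections(list(b, c3))))$resno)
  # random small sets vs sorted-concat-dedup oracle
  for (seed in 1:10) {
    set.seed(seed)
    xs <- lapply(1:3, function(i) sample(1:30, sample(1:8, 1)))
    sels <- lapply(xs, function(v) residue_selection("R", v))
    expect_equal(union_selections(sels)$resno, sort(unique(unlist(xs))))
  }
  # conflicting residue names under one key = incompatible numbering
  bad1 <- residue_selection("R", 5L, resname = "ALA")
  bad2 <- residue_selection("R", 5L, resname = "TRP")
  expect_error(union_selections(list(bad1, bad2)),
               class = "affidesign_argument_error")
})

test_that("superposition RMSD is zero for identical and rigidly moved copies", {
  set.seed(7)
  xyz <- matrix(rnorm(30, sd = 8), ncol = 3)
  s <- ca_cloud_structure(xyz)
  sel <- residue_selection("A", 1:10)
  expect_equal(superpose_rmsd(s, sel, s, sel, atom_names = "CA")$rmsd, 0,
               tolerance = 1e-12)
  for (seed in 1:10) {
    set.seed(seed)
    moved <- transform_structure(s, random_rotation(), rnorm(3, sd = 20))
    sp <- superpose_rmsd(moved, sel, s, sel, atom_names = "CA")
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition matches the independent bio3d least-squares fit", {
  for (seed in 1:8) {
    set.seed(seed)
    # round to PDB coordinate precision so structure and oracle see the
    # exact same numbers
    P <- round(matrix(rnorm(36, sd = 6), ncol = 3), 3)
    Q <- round(P %*% t(random_rotation()) + rnorm(3)[col(P)] +
                 matrix(rnorm(36, sd = 0.4), ncol = 3), 3)
    sp <- superpose_rmsd(ca_cloud_structure(P), residue_selection("A", 1:12),
                         ca_cloud_structure(Q), residue_selection("A", 1:12),
                         atom_names = "CA")
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                              mobile = as.vector(t(P))))
    oracle <- sqrt(mean(colSums(
      (matrix(fitted, nrow = 3) - t(Q))^2)))
    expect_equal(sp$rmsd, oracle, tolerance = 1e-6)
  }
})

test_that("superposition rejects unpairable or degenerate input", {
  set.seed(1)
  s <- ca_cloud_structure(matrix(rnorm(30), ncol = 3))
  expect_error(
    superpose_rmsd(s, residue_selection("A", 1:5), s,
                   residue_selection("A", 2:7), atom_names = "CA"),
    class = "affidesign_pairing_error")
  expect_error(
    superpose_rmsd(s, residue_selection("A", 1:2), s,
                   residue_selection("A", 1:2), atom_names = "CA"),
    class = "affidesign_degenerate_error")
  # main-chain atoms requested but only CA present
  expect_error(
    superpose_rmsd(s, residue_selection("A", 1:5), s,
                   residue_selection("A", 1:5)),
    class = "affidesign_pairing_error")
})

test_that("random control selections are reproducible, exhaustive and uniform", {
  tc <- make_toy_complex(seed = 2, n_receptor_res = 20, n_ligand_res = 10,
                         n_interface = 5)
  excl <- interface_residues(tc$structure, "R", "L", 6.0)
  a <- random_control_selection(tc$structure, excl, 6, seed = 42)
  b <- random_control_selection(tc$structure, excl, 6, seed = 42)
  expect_identical(a$resno, b$resno)
  expect_false(any(a$resno %in% excl$resno))
  # drawing the whole pool returns exactly the complement
  full <- random_control_selection(tc$structure, excl, 15, seed = 1)
  expect_setequal(full$resno, setdiff(1:20, excl$resno))
  expect_error(random_control_selection(tc$structure, excl, 16, seed = 1),
               class = "affidesign_argument_error")
  # uniformity: each of the 15 eligible residues appears in a size-3 draw
  # with p = 3/15 over many seeds, within 3 sigma binomial bounds
  n_draw <- 2000L
  counts <- table(factor(unlist(lapply(seq_len(n_draw), function(sd)
    random_control_selection(tc$structure, excl, 3, seed = sd)$resno)),
    levels = setdiff(1:20, excl$resno)))
  p <- 3 / 15
  bound <- 3 * sqrt(n_draw * p * (1 - p))
  expect_true(all(abs(counts - n_draw * p) <= bound))
})

test_that("ensemble RMSF matches closed forms and the two-pass oracle", {
  tc <- make_toy_complex(seed = 9, n_receptor_res = 10, n_ligand_res = 5,
                         n_interface = 2)
  sel <- residue_selection("R", 1:10)
  # identical frames: zero fluctuation
  r0 <- ensemble_rmsf(list(tc$structure, tc$structure, tc$structure), sel)
  expect_equal(r0$rmsf, rep(0, 10))
  # one atom displaced +/- d about the mean: RMSF = d for its residue
  d <- 0.8
  up <- tc$structure; up$atoms$z[1L] <- up$atoms$z[1L] + d
  dn <- tc$structure; dn$atoms$z[1L] <- dn$atoms$z[1L] - d
  r1 <- ensemble_rmsf(list(up, dn), sel, atom_names = "N")
  expect_equal(r1$rmsf[r1$resno == 1], d, tolerance = 1e-12)
  expect_equal(r1$rmsf[r1$resno != 1], rep(0, 9))
  # random ensemble vs direct two-pass computation (CA atoms only)
  set.seed(3)
  frames <- lapply(1:6, function(i) {
    f <- tc$structure
    f$atoms$x <- f$atoms$x + rnorm(nrow(f$atoms), sd = 0.3)
    f$atoms$y <- f$atoms$y + rnorm(nrow(f$atoms), sd = 0.3)
    f$atoms$z <- f$atoms$z + rnorm(nrow(f$atoms), sd = 0.3)
    f
  })
  got <- ensemble_rmsf(frames, sel, atom_names = "CA")
  for (rn in 1:10) {
    xyz <- t(vapply(frames, function(f) {
      i <- which(f$atoms$chain == "R" & f$atoms$resno == rn &
                   f$atoms$atom == "CA")
      c(f$atoms$x[i], f$atoms$y[i], f$atoms$z[i])
    }, numeric(3)))
    mu <- colMeans(xyz)
    oracle <- sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
    expect_equal(got$rmsf[got$resno == rn], oracle, tolerance = 1e-12)
  }
  expect_error(ensemble_rmsf(list(tc$structure), sel),
               class = "affidesign_argument_error")
})

test_that("selection TSV and superposition JSON round-trip", {
  sel <- residue_selection("R", c(3L, 1L, 7L), resname = c("ALA", "GLY", "TRP"),
                           label = "demo")
  path <- tempfile(fileext = ".tsv")
  write_selection_tsv(sel, path)
  back <- read_selection_tsv(path)
  expect_equal(back$resno, sort(sel$resno))
  set.seed(2)
  s <- ca_cloud_structure(matrix(rnorm(30), ncol = 3))
  sp <- superpose_rmsd(s, residue_selection("A", 1:10), s,
                       residue_selection("A", 1:10), atom_names = "CA")
  jp <- tempfile(fileext = ".json")
  write_superposition_json(sp, jp)
  parsed <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(parsed$rmsd, sp$rmsd)
  expect_equal(matrix(parsed$rotation, 3, 3, byrow = TRUE), sp$rotation)
})
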