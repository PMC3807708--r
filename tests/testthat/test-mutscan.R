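make_small_matrix <- function() {
  # two mutations x two interfaces, both energy types, hand-written values
  df <- expand.grid(interface_id = c("i1", "i2"),
                    energy_type = c("stability", "affinity"),
                    stringsAsFactors = FALSE)
  rows <- rbind(cbind(position = 10, wt = "N", mut = "W", df,
                      ddg_kj_mol = c(-1, -2, -3, -4)),
                cbind(position = 20, wt = "S", mut = "R", df,
                      ddg_kj_mol = c(1, 2, 3, 4)))
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("ddG TSV loading counts, validates and converts units", {
  path <- make_small_matrix()
  m <- load_ddg_tsv(path)
  expect_s3_class(m, "ddg_matrix")
  expect_equal(nrow(m), 8L)
  expect_equal(attr(m, "interfaces"), c("i1", "i2"))
  # kcal/mol conversion by 4.184
  m2 <- load_ddg_tsv(path, units = "kcal")
  expect_equal(m2$ddg, m$ddg * 4.184)
  # duplicate row rejected
  txt <- readLines(path)
  writeLines(c(txt, txt[2L]), path)
  expect_error(load_ddg_tsv(path), class = "affidesign_format_error")
  # unknown energy type rejected
  writeLines(gsub("stability", "entropy", txt), path)
  expect_error(load_ddg_tsv(path), class = "affidesign_format_error")
})

test_that("generated matrices round-trip through TSV bit-exactly", {
  gen <- make_ddg_matrix(seed = 6,
                         positions = data.frame(position = c(70, 95, 222),
                                                wt = c("N", "S", "H")),
                         planted_stabilizing = "N70G", noise_sd = 0.5,
                         n_mut_per_position = 6)
  path <- tempfile(fileext = ".tsv")
  write_ddg_tsv(gen$matrix, path)
  back <- load_ddg_tsv(path)
  expect_identical(back$ddg, gen$matrix$ddg)
  expect_identical(back$mut, gen$matrix$mut)
  # same seed regenerates the identical matrix
  gen2 <- make_ddg_matrix(seed = 6,
                          positions = data.frame(position = c(70, 95, 222),
                                                 wt = c("N", "S", "H")),
                          planted_stabilizing = "N70G", noise_sd = 0.5,
                          n_mut_per_position = 6)
  expect_identical(gen$matrix$ddg, gen2$matrix$ddg)
})

test_that("ensemble averaging matches the two-pass oracle and is linear", {
  pos <- data.frame(position = c(10, 50), wt = c("A", "G"))
  snaps <- lapply(1:20, function(i)
    make_ddg_matrix(seed = 100 + i, positions = pos,
                    n_mut_per_position = 4)$matrix)
  avg <- ensemble_average(snaps)
  vals <- sapply(snaps, function(m) m$ddg)
  expect_equal(avg$ddg, rowMeans(vals))
  expect_equal(avg$sd, apply(vals, 1, sd))
  # identical snapshots: mean = input, sd = 0
  same <- ensemble_average(list(snaps[[1]], snaps[[1]]))
  expect_equal(same$ddg, snaps[[1]]$ddg)
  expect_equal(same$sd, rep(0, nrow(snaps[[1]])))
  # two snapshots with -5 and +17 average to +6
  a <- snaps[[1]]; a$ddg[] <- -5
  b <- snaps[[1]]; b$ddg[] <- 17
  expect_equal(unique(ensemble_average(list(a, b))$ddg), 6)
  # linearity: scaling every snapshot scales the mean
  scaled <- lapply(snaps, function(m) { m$ddg <- 2.5 * m$ddg; m })
  expect_equal(ensemble_average(scaled)$ddg, 2.5 * avg$ddg)
  # mismatching key sets rejected
  short <- snaps[[2]][-1, ]
  class(short) <- class(snaps[[2]])
  attr(short, "interfaces") <- attr(snaps[[2]], "interfaces")
  expect_error(ensemble_average(list(snaps[[1]], short)),
               class = "affidesign_argument_error")
})

test_that("best/worst summarization follows the most/least stabilizing rules", {
  df <- data.frame(position = 96, wt = "N", mut = "W",
                   interface = sprintf("i%d", 1:4), type = "affinity",
                   ddg = c(-9.9, -8.0, -7.2, -6.5))
  m <- affidesign:::new_ddg_matrix(df)
  bw <- summarize_best_worst(m, "N96W", "affinity")
  expect_equal(unname(bw["best"]), -9.9)
  expect_equal(unname(bw["worst"]), -6.5)
  # all equal: best = worst
  m2 <- m; m2$ddg <- rep(1.5, 4)
  bw2 <- summarize_best_worst(m2, "N96W", "affinity", mode = "destabilize")
  expect_equal(unname(bw2["best"]), unname(bw2["worst"]))
  # destabilize mode: least positive value among mixed signs
  m3 <- m; m3$ddg <- c(6.7, 9.1, -0.3, 8.2)
  expect_equal(unname(summarize_best_worst(m3, "N96W", "affinity",
                                           mode = "destabilize")["best"]), 6.7)
  # random vectors vs sort oracle
  for (seed in 1:10) {
    set.seed(seed)
    v <- round(rnorm(4, 0, 6), 2)
    m$ddg <- v
    bw <- summarize_best_worst(m, "N96W", "affinity")
    expect_equal(unname(bw), c(sort(v)[1], sort(v)[4]))
  }
  # missing interface
  m4 <- m[-1, ]; class(m4) <- class(m); attr(m4, "interfaces") <- attr(m, "interfaces")
  expect_error(summarize_best_worst(m4, "N96W", "affinity"),
               class = "affidesign_argument_error")
})

planted_profile <- function(positions, fractions) {
  structure(data.frame(position = positions,
                       ref_residue = rep("N", length(positions)),
                       fraction = fractions,
                       consensus = rep("N", length(positions))),
            class = c("conservation_profile", "data.frame"),
            reference_id = "REF")
}

test_that("candidate selection applies energy and conservation criteria", {
  df <- expand.grid(interface = sprintf("i%d", 1:4),
                    type = c("stability", "affinity"),
                    stringsAsFactors = FALSE)
  mk <- function(pos, wt, mut, vals) cbind(position = pos, wt = wt, mut = mut,
                                           df, ddg = vals)
  m <- affidesign:::new_ddg_matrix(rbind(
    mk(96, "N", "W", rep(-2, 8)),          # favorable everywhere
    mk(50, "A", "R", c(rep(-2, 7), 0.5)),  # favorable on 3 of 4 interfaces
    mk(60, "G", "K", rep(-2, 8))))         # favorable but conserved position
  prof <- planted_profile(c(96, 50, 60), c(0.30, 0.10, 0.70))
  rep1 <- select_candidates(m, prof, selection_criteria("stabilize"))
  expect_equal(rep1$mutation[rep1$selected], "N96W")
  r60 <- rep1[rep1$mutation == "G60K", ]
  expect_true(r60$pass_affinity && r60$pass_stability && !r60$pass_conservation)
  r50 <- rep1[rep1$mutation == "A50R", ]
  expect_false(r50$pass_affinity)
  # rank is a total order starting at the selected candidates
  expect_equal(rep1$rank, 1:3)
  # unmapped position is an error
  expect_error(select_candidates(m, planted_profile(96, 0.3),
                                 selection_criteria()),
               class = "affidesign_argument_error")
})

test_that("selection equals the brute-force filter and recovers planted truth", {
  pos <- data.frame(position = c(65, 70, 95, 96, 222),
                    wt = c("N", "N", "S", "N", "H"))
  for (seed in c(1, 7, 23)) {
    gen <- make_ddg_matrix(seed = seed, positions = pos,
                           planted_stabilizing = c("N70G", "N96W", "H222R"),
                           planted_destabilizing = "S95E",
                           noise_sd = 1, n_mut_per_position = 8)
    prof <- planted_profile(pos$position, c(0.9, 0.2, 0.3, 0.1, 0.5))
    rep1 <- select_candidates(gen$matrix, prof, selection_criteria("stabilize"))
    expect_setequal(rep1$mutation[rep1$selected],
                    brute_force_select(gen$matrix, prof))
    expect_setequal(rep1$mutation[rep1$selected], c("N70G", "N96W", "H222R"))
    # destabilize mode recovers the planted destabilizing mutation
    rep2 <- select_candidates(gen$matrix, prof,
                              selection_criteria("destabilize"))
    expect_equal(rep2$mutation[rep2$selected], "S95E")
  }
})

test_that("selection is invariant to row order and monotone in thresholds", {
  pos <- data.frame(position = c(10, 40, 80), wt = c("A", "C", "D"))
  gen <- make_ddg_matrix(seed = 12, positions = pos,
                         planted_stabilizing = c("A10G", "C40S"),
                         n_mut_per_position = 6)
  prof <- planted_profile(pos$position, c(0.2, 0.2, 0.9))
  base <- select_candidates(gen$matrix, prof, selection_criteria())
  # permute rows of the matrix
  perm <- gen$matrix[sample(nrow(gen$matrix)), ]
  class(perm) <- class(gen$matrix)
  attr(perm, "interfaces") <- attr(gen$matrix, "interfaces")
  redo <- select_candidates(perm, prof, selection_criteria())
  expect_identical(as.data.frame(base), as.data.frame(redo))
  # loosening thresholds never shrinks the candidate set
  sel0 <- base$mutation[base$selected]
  for (loose in c(1, 3, 10)) {
    crit <- selection_criteria(affinity_threshold = loose,
                               stability_threshold = loose,
                               conservation_threshold = 0.95)
    sel1 <- select_candidates(gen$matrix, prof, crit)
    expect_true(all(sel0 %in% sel1$mutation[sel1$selected]))
    sel0 <- sel1$mutation[sel1$selected]
  }
})

test_that("multi-mutant design enforces sequence and spatial separation", {
  # backbone trace: residue i at x = 3.8 i, so positions 25 residues apart
  # are ~95 Angstrom apart in space
  tc <- make_toy_complex(seed = 1, n_receptor_res = 230, n_ligand_res = 5,
                         n_interface = 0)
  singles <- c("N70G", "S95R", "H222R")
  combos <- design_combinations(singles, tc$structure, chain = "R",
                                numbering_offset = 17)
  expect_equal(nrow(combos), 4L)                  # 3 doubles + 1 triple
  expect_setequal(combos$label[combos$order == 2],
                  c("N70G;S95R", "N70G;H222R", "S95R;H222R"))
  expect_equal(combos$label[combos$order == 3], "N70G;S95R;H222R")
  # two singles close in space are never combined
  near <- design_combinations(c("N70G", "N75R"), tc$structure, chain = "R",
                              numbering_offset = 17)
  expect_equal(nrow(near), 0L)
  # position absent from the structure
  expect_error(design_combinations(c("N70G", "S999R"), tc$structure,
                                   chain = "R", numbering_offset = 17),
               class = "affidesign_argument_error")
})

test_that("combination enumeration equals the power-set oracle", {
  tc <- make_toy_complex(seed = 2, n_receptor_res = 300, n_ligand_res = 5,
                         n_interface = 0)
  set.seed(4)
  for (rep in 1:5) {
    posns <- sort(sample(seq(10, 290, by = 4), 5))
    singles <- paste0("A", posns, "G")
    combos <- design_combinations(singles, tc$structure, chain = "R",
                                  min_seq_sep = 25, min_spatial_sep = 20,
                                  max_order = 3)
    # oracle: explicit power-set scan with pairwise checks on the trace
    ca <- tc$structure$atoms[tc$structure$atoms$atom == "CA" &
                               tc$structure$atoms$chain == "R", ]
    compat <- function(i, j) {
      abs(posns[i] - posns[j]) >= 25 &&
        sqrt(sum((unlist(ca[ca$resno == posns[i], c("x", "y", "z")]) -
                    unlist(ca[ca$resno == posns[j], c("x", "y", "z")]))^2)) > 20
    }
    want <- character()
    for (k in 2:3) {
      cb <- combn(5, k)
      for (ci in seq_len(ncol(cb))) {
        sel <- cb[, ci]
        if (all(apply(combn(sel, 2), 2, function(p) compat(p[1], p[2]))))
          want <- c(want, paste(singles[sel], collapse = ";"))
      }
    }
    expect_setequal(combos$label, want)
  }
})

test_that("mutation labels parse and reject malformed input", {
  mu <- parse_mutation("N96W")
  expect_equal(mu$position, 96L)
  multi <- parse_mutation("N70G + S95R + H222R")
  expect_equal(nrow(multi), 3L)
  expect_equal(multi$mut, c("G", "R", "R"))
  expect_error(parse_mutation("N96N"), class = "affidesign_format_error")
  expect_error(parse_mutation("X96W"), class = "affidesign_format_error")
  expect_error(parse_mutation("garbage"), class = "affidesign_format_error")
})
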