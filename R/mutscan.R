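#' Mutation labels
#'
#' Single mutations are written `N96W` (wild-type residue, reference position,
#' mutant residue); multi-mutations join singles with `+`.
#'
#' @param label Character label, e.g. `"N96W"` or `"N70G + S95R"`.
#' @return `parse_mutation` returns a data frame `wt`, `position`, `mut` (one
#'   row per constituent single); `mutation_label` the canonical label.
#' @export
parse_mutation <- function(label) {
  parts <- trimws(strsplit(label, "[+;]")[[1L]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    abort_format(sprintf("cannot parse mutation label '%s'", label))
  wt <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  mut <- vapply(m, `[[`, "", 4L)
  if (any(wt == mut))
    abort_format(sprintf("wild-type equals mutant in '%s'", label))
  if (any(!wt %in% AA1) || any(!mut %in% AA1))
    abort_format(sprintf("invalid amino acid code in '%s'", label))
  data.frame(wt = wt, position = pos, mut = mut, stringsAsFactors = FALSE)
}

#' @rdname parse_mutation
#' @param wt,position,mut Vectors of wild-type residue, position, mutant.
#' @export
mutation_label <- function(wt, position, mut) paste0(wt, position, mut)

new_ddg_matrix <- function(df, interfaces = NULL) {
  df <- df[order(df$position, df$wt, df$mut, df$interface, df$type), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ddg_matrix", "data.frame"),
            interfaces = if (is.null(interfaces)) unique(df$interface)
            else interfaces)
}

ddg_key <- function(m) paste(m$position, m$wt, m$mut, m$interface, m$type,
                             sep = "\r")

#' Load a ddG matrix from TSV
#'
#' Expected columns: `position`, `wt`, `mut`, `interface_id`, `energy_type`
#' (`stability` or `affinity`), `ddg_kj_mol`. Values are stored in kJ/mol;
#' set `units = "kcal"` to convert kcal/mol input by the factor 4.184.
#'
#' @param path Path to the TSV file.
#' @param units `"kJ"` (default) or `"kcal"`.
#' @return A `ddg_matrix`: long-format data frame `position`, `wt`, `mut`,
#'   `interface`, `type`, `ddg` with attribute `interfaces`.
#' @export
load_ddg_tsv <- function(path, units = c("kJ", "kcal")) {
  units <- match.arg(units)
  if (!file.exists(path)) abort_io(sprintf("cannot read ddG TSV '%s'", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "wt", "mut", "interface_id", "energy_type",
            "ddg_kj_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(sprintf("ddG TSV missing column(s): %s",
                         paste(miss, collapse = ", ")))
  if (!all(df$energy_type %in% c("stability", "affinity")))
    abort_format(sprintf("unknown energy_type: %s",
                         paste(setdiff(unique(df$energy_type),
                                       c("stability", "affinity")),
                               collapse = ", ")))
  ddg <- suppressWarnings(as.numeric(df$ddg_kj_mol))
  if (any(is.na(ddg)))
    abort_format("non-numeric ddg_kj_mol value(s)")
  out <- data.frame(position = as.integer(df$position), wt = df$wt,
                    mut = df$mut, interface = as.character(df$interface_id),
                    type = df$energy_type,
                    ddg = if (units == "kcal") ddg * 4.184 else ddg,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ddg_key(out)))
    abort_format("duplicate (mutation, interface, energy_type) rows")
  new_ddg_matrix(out)
}

#' Write a ddG matrix as TSV
#' @param m A `ddg_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddg_tsv <- function(m, path) {
  df <- data.frame(position = m$position, wt = m$wt, mut = m$mut,
                   interface_id = m$interface, energy_type = m$type,
                   # full double precision so matrices round-trip bit-exactly
                   ddg_kj_mol = sprintf("%.17g", m$ddg))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average ddG matrices over a snapshot ensemble
#'
#' Arithmetic mean per (mutation, interface, energy type) key over matrices
#' computed on individual conformational snapshots, with the per-key standard
#' deviation carried in an `sd` column (0 for a single snapshot).
#'
#' @param matrices List of `ddg_matrix` objects with identical key sets.
#' @return A `ddg_matrix` with `ddg` = mean and an additional `sd` column.
#' @export
ensemble_average <- function(matrices) {
  if (!length(matrices)) abort_argument("no matrices given")
  stopifnot(all(vapply(matrices, inherits, TRUE, "ddg_matrix")))
  ref <- matrices[[1L]]
  keys <- ddg_key(ref)
  vals <- vapply(matrices, function(m) {
    idx <- match(keys, ddg_key(m))
    if (anyNA(idx) || nrow(m) != length(keys))
      abort_argument("snapshot matrices have mismatching key sets")
    m$ddg[idx]
  }, numeric(length(keys)))
  vals <- matrix(vals, nrow = length(keys))
  out <- ref
  out$ddg <- rowMeans(vals)
  out$sd <- apply(vals, 1L, stats::sd)
  if (length(matrices) == 1L) out$sd <- 0
  new_ddg_matrix(out, attr(ref, "interfaces"))
}

#' Best and worst ddG of a mutation across interfaces
#'
#' "Best" is the most stabilizing (most negative) value over the interfaces;
#' "worst" the maximum. For mutations designed to destabilize, the reported
#' best is instead the least positive (least destabilizing) value among the
#' positive ones.
#'
#' @param m A `ddg_matrix`.
#' @param mutation A mutation label, e.g. `"N96W"`.
#' @param energy_type `"affinity"` or `"stability"`.
#' @param mode `"stabilize"` (default) or `"destabilize"`.
#' @return Named numeric vector `c(best=, worst=)` in kJ/mol.
#' @export
summarize_best_worst <- function(m, mutation,
                                 energy_type = c("affinity", "stability"),
                                 mode = c("stabilize", "destabilize")) {
  energy_type <- match.arg(energy_type)
  mode <- match.arg(mode)
  mu <- parse_mutation(mutation)
  rows <- m[m$position == mu$position & m$wt == mu$wt & m$mut == mu$mut &
              m$type == energy_type, , drop = FALSE]
  ifs <- attr(m, "interfaces")
  if (!setequal(rows$interface, ifs))
    abort_argument(sprintf("'%s' (%s) missing for interface(s): %s", mutation,
                           energy_type,
                           paste(setdiff(ifs, rows$interface), collapse = ", ")))
  v <- rows$ddg
  best <- if (mode == "stabilize") min(v) else {
    pos <- v[v > 0]
    if (length(pos)) min(pos) else min(v)
  }
  c(best = best, worst = max(v))
}

#' Selection criteria for mutation candidates
#'
#' @param mode `"stabilize"`: keep mutations with affinity ddG below
#'   `affinity_threshold` and stability ddG below `stability_threshold` on the
#'   required interfaces, at positions not conserved above
#'   `conservation_threshold`. `"destabilize"`: affinity ddG > 0 and stability
#'   ddG < 0 on all interfaces (the conservation veto is not applied).
#' @param require_all_interfaces Demand the energy criteria on every interface
#'   (default `TRUE`); otherwise the best interface value decides.
#' @param affinity_threshold,stability_threshold kJ/mol, default 0 (strictly
#'   negative = favorable).
#' @param conservation_threshold Fraction above which a position is vetoed
#'   (default 0.65).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(mode = c("stabilize", "destabilize"),
                               require_all_interfaces = TRUE,
                               affinity_threshold = 0,
                               stability_threshold = 0,
                               conservation_threshold = 0.65) {
  mode <- match.arg(mode)
  stopifnot(is_scalar_number(affinity_threshold),
            is_scalar_number(stability_threshold),
            is_scalar_number(conservation_threshold))
  structure(list(mode = mode,
                 require_all_interfaces = isTRUE(require_all_interfaces),
                 affinity_threshold = affinity_threshold,
                 stability_threshold = stability_threshold,
                 conservation_threshold = conservation_threshold),
            class = "selection_criteria")
}

#' Select candidate mutations from a ddG matrix
#'
#' Applies the energy and conservation criteria to every mutation of the
#' matrix and returns a fully ranked report with per-criterion provenance.
#' Stabilize mode ranks by best (most negative) affinity ddG ascending;
#' destabilize mode descending. Ties are broken by position, then mutant
#' residue alphabetically; non-selected mutations follow the selected ones in
#' the same ordering, so the rank is a total order.
#'
#' @param m A `ddg_matrix` (positions in matrix numbering).
#' @param profile A `conservation_profile` in reference numbering.
#' @param criteria A [selection_criteria()] object.
#' @param numbering_offset Offset added to matrix positions to obtain profile
#'   (reference) positions; 0 when both already share reference numbering.
#' @return A `candidate_report` data frame: `mutation`, `position`, `wt`,
#'   `mut`, best/worst affinity and stability ddG, `conservation`, logical
#'   `pass_affinity`, `pass_stability`, `pass_conservation`, `selected`,
#'   `rank`.
#' @export
select_candidates <- function(m, profile, criteria = selection_criteria(),
                              numbering_offset = 0L) {
  stopifnot(inherits(m, "ddg_matrix"), inherits(profile, "conservation_profile"),
            inherits(criteria, "selection_criteria"))
  ifs <- attr(m, "interfaces")
  muts <- unique(m[, c("position", "wt", "mut")])
  ref_pos <- muts$position + as.integer(numbering_offset)
  pidx <- match(ref_pos, profile$position)
  if (anyNA(pidx))
    abort_argument(sprintf("position(s) not mapped in conservation profile: %s",
                           paste(unique(muts$position[is.na(pidx)]),
                                 collapse = ", ")))
  n <- nrow(muts)
  rep_df <- data.frame(
    mutation = mutation_label(muts$wt, muts$position, muts$mut),
    position = muts$position, wt = muts$wt, mut = muts$mut,
    best_affinity = NA_real_, worst_affinity = NA_real_,
    best_stability = NA_real_, worst_stability = NA_real_,
    conservation = profile$fraction[pidx],
    pass_affinity = FALSE, pass_stability = FALSE, pass_conservation = FALSE,
    stringsAsFactors = FALSE)

  mkey <- paste(m$position, m$wt, m$mut, sep = "\r")
  ukey <- paste(muts$position, muts$wt, muts$mut, sep = "\r")
  for (i in seq_len(n)) {
    rows <- m[mkey == ukey[i], , drop = FALSE]
    for (ty in c("affinity", "stability")) {
      v <- rows$ddg[rows$type == ty]
      present <- rows$interface[rows$type == ty]
      if (!setequal(present, ifs))
        abort_argument(sprintf("'%s' lacks %s values for some interfaces",
                               rep_df$mutation[i], ty))
      thr <- if (criteria$mode == "destabilize") {
        if (ty == "affinity") 0 else 0
      } else if (ty == "affinity") criteria$affinity_threshold
      else criteria$stability_threshold
      pass <- if (criteria$mode == "destabilize" && ty == "affinity") {
        if (criteria$require_all_interfaces) all(v > 0) else any(v > 0)
      } else {
        if (criteria$require_all_interfaces) all(v < thr) else min(v) < thr
      }
      if (ty == "affinity") {
        rep_df$best_affinity[i] <- min(v); rep_df$worst_affinity[i] <- max(v)
        rep_df$pass_affinity[i] <- pass
      } else {
        rep_df$best_stability[i] <- min(v); rep_df$worst_stability[i] <- max(v)
        rep_df$pass_stability[i] <- pass
      }
    }
  }
  rep_df$pass_conservation <-
    rep_df$conservation <= criteria$conservation_threshold
  rep_df$selected <- rep_df$pass_affinity & rep_df$pass_stability &
    (if (criteria$mode == "stabilize") rep_df$pass_conservation else TRUE)

  sgn <- if (criteria$mode == "stabilize") 1 else -1
  ord <- order(!rep_df$selected, sgn * rep_df$best_affinity,
               rep_df$position, rep_df$mut)
  rep_df <- rep_df[ord, , drop = FALSE]
  rep_df$rank <- seq_len(n)
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("candidate_report", "data.frame"),
            criteria = criteria, interfaces = ifs)
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> %d mutations, %d selected (%s mode)\n",
              nrow(x), sum(x$selected), attr(x, "criteria")$mode))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write a candidate report as TSV and JSON
#' @param report A `candidate_report`.
#' @param path Output path (TSV); the JSON variant writes full provenance.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(criteria = unclass(attr(report, "criteria")),
         interfaces = attr(report, "interfaces"),
         candidates = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Design multi-mutants from compatible single mutations
#'
#' Enumerates every subset of size 2..`max_order` of the given single
#' mutations in which all pairs are simultaneously (i) at least
#' `min_seq_sep` residues apart in sequence and (ii) more than
#' `min_spatial_sep` Angstrom apart in space, measured between the CA atoms of
#' the wild-type residues in the structure. Three mutually compatible singles
#' with `max_order = 3` yield three doubles and one triple.
#'
#' @param singles Character vector of single-mutation labels (reference
#'   numbering), e.g. `c("N70G", "S95R", "H222R")`.
#' @param s A `complex_structure` providing CA coordinates.
#' @param chain Receptor chain id in `s`.
#' @param min_seq_sep Minimum sequence separation in residues (default 25).
#' @param min_spatial_sep Minimum CA-CA distance in Angstrom, exclusive
#'   (default 20).
#' @param max_order Largest multi-mutant size (default 3).
#' @param numbering_offset Offset subtracted from reference positions to get
#'   structure numbering (default 0).
#' @return Data frame `label` (semicolon-joined singles) and `order`.
#' @export
design_combinations <- function(singles, s, chain, min_seq_sep = 25,
                                min_spatial_sep = 20, max_order = 3,
                                numbering_offset = 0L) {
  stopifnot(inherits(s, "complex_structure"))
  mu <- do.call(rbind, lapply(singles, parse_mutation))
  if (anyDuplicated(mu$position))
    abort_argument("single mutations must be at distinct positions")
  st_pos <- mu$position - as.integer(numbering_offset)
  at <- s$atoms[s$atoms$chain == chain & s$atoms$atom == "CA" & !s$atoms$het, ,
                drop = FALSE]
  idx <- match(st_pos, at$resno)
  if (anyNA(idx))
    abort_argument(sprintf("position(s) absent from structure chain %s: %s",
                           chain,
                           paste(mu$position[is.na(idx)], collapse = ", ")))
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  n <- nrow(mu)
  ok <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    ok[i, j] <- abs(mu$position[i] - mu$position[j]) >= min_seq_sep &&
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)) > min_spatial_sep
  }
  labels <- character(); orders <- integer()
  for (k in seq(2L, min(max_order, n))) {
    if (k < 2L || n < k) next
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      sel <- combs[, ci]
      if (all(ok[sel, sel][upper.tri(matrix(0, k, k))])) {
        labels <- c(labels, paste(singles[sel], collapse = ";"))
        orders <- c(orders, k)
      }
    }
  }
  data.frame(label = labels, order = orders, stringsAsFactors = FALSE)
}
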