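# Config-driven orchestration of the design and analysis stages. The YAML
# config is the single declarative input; every run writes a TSV/JSON report
# bundle plus a provenance log (package version, config values, input file
# digests) into the output directory. Reports contain no timestamps so that
# re-running an identical config reproduces them byte for byte.

PIPELINE_KEYS <- c(
  "structures", "alignment", "reference_id", "ddg", "ddg_units",
  "cutoff", "conservation_threshold", "numbering_offset", "mode",
  "affinity_threshold", "stability_threshold",
  "combine_singles", "min_seq_sep", "min_spatial_sep", "max_order",
  "affinity_csv", "wt_label", "temperature",
  "sensorgram_csv", "melt_csv", "melt_reference",
  "seed", "outdir")

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file (or an equivalent named list).
#' Unknown keys are rejected; numeric thresholds are validated on load, before
#' any computation. Defaults: `cutoff` 6.0 Angstrom,
#' `conservation_threshold` 0.65, `numbering_offset` 17, `min_spatial_sep`
#' 20 Angstrom, `min_seq_sep` 25 residues, `temperature` 298.15 K, `mode`
#' `"stabilize"`, `seed` 1.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort_io(sprintf("config '%s' not found", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else abort_argument("'config' must be a file path or a named list")
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    abort_argument(sprintf("unknown config key(s): %s",
                           paste(unknown, collapse = ", ")))
  defaults <- list(cutoff = 6.0, conservation_threshold = 0.65,
                   numbering_offset = 17L, mode = "stabilize",
                   affinity_threshold = 0, stability_threshold = 0,
                   min_seq_sep = 25, min_spatial_sep = 20, max_order = 3,
                   ddg_units = "kJ", wt_label = "WT", temperature = 298.15,
                   seed = 1L, outdir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!is_scalar_number(cfg$cutoff) || cfg$cutoff <= 0)
    abort_argument("'cutoff' must be positive")
  if (!is_scalar_number(cfg$conservation_threshold) ||
      cfg$conservation_threshold <= 0 || cfg$conservation_threshold >= 1)
    abort_argument("'conservation_threshold' must be in (0, 1)")
  if (!cfg$mode %in% c("stabilize", "destabilize"))
    abort_argument("'mode' must be 'stabilize' or 'destabilize'")
  if (!is_scalar_number(cfg$temperature) || cfg$temperature <= 0)
    abort_argument("'temperature' must be positive")
  structure(cfg, class = "pipeline_config")
}

provenance_log <- function(cfg, inputs, path) {
  lines <- c(sprintf("package: affidesign %s",
                     as.character(utils::packageVersion("affidesign"))),
             sprintf("R: %s", R.version.string),
             "config:",
             vapply(names(cfg), function(k)
               sprintf("  %s: %s", k, paste(format(cfg[[k]]), collapse = ", ")),
               ""),
             "inputs:")
  for (f in inputs) {
    if (is.character(f) && file.exists(f))
      lines <- c(lines, sprintf("  %s md5:%s", f, unname(tools::md5sum(f))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the mutation-design stage
#'
#' Executes interface identification on each configured structure, unions the
#' interfaces onto a common numbering, computes the conservation profile,
#' applies the selection criteria to the ddG matrix and designs multi-mutant
#' combinations from the selected singles. Writes `interface.tsv`,
#' `profile.tsv`, `candidates.tsv`, `candidates.json`, `combinations.tsv`
#' and `provenance.log` into `outdir`.
#'
#' Config keys used: `structures` (list of
#' `{path, receptor_chain, ligand_chains}`), `alignment`, `reference_id`,
#' `ddg`, `ddg_units`, `cutoff`, `conservation_threshold`,
#' `numbering_offset`, `mode`, `affinity_threshold`, `stability_threshold`,
#' `min_seq_sep`, `min_spatial_sep`, `max_order`, `outdir`.
#'
#' @param config Path to a YAML config or a named list.
#' @return Invisibly, a list with `interface`, `profile`, `report`,
#'   `combinations`.
#' @export
run_design <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$structures) || is.null(cfg$alignment) || is.null(cfg$ddg) ||
      is.null(cfg$reference_id))
    abort_argument("design stage needs 'structures', 'alignment', 'reference_id' and 'ddg'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  selections <- lapply(cfg$structures, function(st) {
    s <- parse_structure(st$path)
    lapply(st$ligand_chains, function(lc)
      remap_selection(
        interface_residues(s, st$receptor_chain, lc, cutoff = cfg$cutoff),
        chain = "REF"))
  })
  iface <- union_selections(unlist(selections, recursive = FALSE),
                            label = sprintf("interface_union<=%.1fA",
                                            cfg$cutoff))
  aln <- read_alignment(cfg$alignment)
  profile <- column_conservation(aln, cfg$reference_id)
  ddg <- load_ddg_tsv(cfg$ddg, units = cfg$ddg_units)
  crit <- selection_criteria(
    mode = cfg$mode, affinity_threshold = cfg$affinity_threshold,
    stability_threshold = cfg$stability_threshold,
    conservation_threshold = cfg$conservation_threshold)
  report <- select_candidates(ddg, profile, crit,
                              numbering_offset = cfg$numbering_offset)

  singles <- report$mutation[report$selected]
  combos <- data.frame(label = character(), order = integer())
  if (length(singles) >= 2L) {
    s1 <- parse_structure(cfg$structures[[1L]]$path)
    combos <- design_combinations(
      singles, s1, chain = cfg$structures[[1L]]$receptor_chain,
      min_seq_sep = cfg$min_seq_sep, min_spatial_sep = cfg$min_spatial_sep,
      max_order = cfg$max_order, numbering_offset = cfg$numbering_offset)
  }

  write_selection_tsv(iface, file.path(cfg$outdir, "interface.tsv"))
  write_profile_tsv(profile, file.path(cfg$outdir, "profile.tsv"))
  write_report_tsv(report, file.path(cfg$outdir, "candidates.tsv"))
  write_report_json(report, file.path(cfg$outdir, "candidates.json"))
  utils::write.table(combos, file.path(cfg$outdir, "combinations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  provenance_log(cfg, c(vapply(cfg$structures, `[[`, "", "path"),
                        cfg$alignment, cfg$ddg),
                 file.path(cfg$outdir, "provenance.log"))
  invisible(list(interface = iface, profile = profile, report = report,
                 combinations = combos))
}

#' Run the affinity analysis stage
#'
#' From a kinetic affinity table (CSV, SI units), computes per-variant
#' experimental ddG relative to the wild type, fold changes, Student-t 95%
#' confidence half-widths, and additivity records for every multi-mutant
#' whose constituent singles are present. Writes `affinity_report.tsv` and
#' `additivity.tsv` into `outdir`.
#'
#' @param config Path to a YAML config or a named list (keys `affinity_csv`,
#'   `wt_label`, `temperature`, `outdir`).
#' @return Invisibly, a list with `report` and `additivity`.
#' @export
run_affinity_analysis <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$affinity_csv))
    abort_argument("affinity stage needs 'affinity_csv'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  meas <- read_affinity_csv(cfg$affinity_csv)
  report <- affinity_report(meas, wt_label = cfg$wt_label,
                            temperature = cfg$temperature)
  is_multi <- grepl("\\+", meas$variant)
  addv <- NULL
  if (any(is_multi)) {
    singles <- data.frame(variant = report$variant[!is_multi &
                                                     report$variant != cfg$wt_label],
                          ddg = report$ddg_kj_mol[!is_multi &
                                                    report$variant != cfg$wt_label])
    multis <- data.frame(variant = report$variant[is_multi],
                         ddg = report$ddg_kj_mol[is_multi])
    addv <- additivity_table(singles, multis)
    utils::write.table(addv, file.path(cfg$outdir, "additivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report, file.path(cfg$outdir, "affinity_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  provenance_log(cfg, cfg$affinity_csv,
                 file.path(cfg$outdir, "provenance.log"))
  invisible(list(report = report, additivity = addv))
}

#' Run the SPR kinetic fitting stage
#'
#' Reads a sensorgram CSV, double-references active curves when reference and
#' interspot channels are present, fits the 1:1 Langmuir-with-drift model
#' globally across the concentration series and writes `spr_fit.json`.
#'
#' @param config Path to a YAML config or a named list (keys
#'   `sensorgram_csv`, `seed`, `outdir`).
#' @return Invisibly, the `langmuir_fit`.
#' @export
run_spr <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$sensorgram_csv))
    abort_argument("spr stage needs 'sensorgram_csv'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  curves <- read_sensorgram_csv(cfg$sensorgram_csv)
  chans <- vapply(curves, attr, "", "channel")
  actives <- curves[chans == "active"]
  if (!length(actives)) actives <- curves[chans == "corrected"]
  if (!length(actives)) abort_argument("no active/corrected curves in CSV")
  fitted_input <- lapply(actives, function(a) {
    conc <- attr(a, "concentration")
    same_conc <- vapply(curves, function(cv)
      isTRUE(all.equal(attr(cv, "concentration"), conc)), TRUE)
    ref <- curves[chans == "reference" & same_conc]
    isp <- curves[chans == "interspot" & same_conc]
    if (!length(ref)) ref <- curves[chans == "reference"]
    if (!length(isp)) isp <- curves[chans == "interspot"]
    if (length(ref) && length(isp))
      double_reference(a, ref[[1L]], isp[[1L]])
    else a
  })
  fit <- fit_langmuir_drift(fitted_input, seed = cfg$seed)
  write_fit_json(fit, file.path(cfg$outdir, "spr_fit.json"))
  provenance_log(cfg, cfg$sensorgram_csv,
                 file.path(cfg$outdir, "provenance.log"))
  invisible(fit)
}

#' Run the thermal shift analysis stage
#'
#' Reads a melt-curve CSV, subtracts the configured reference curve (if any),
#' normalizes each variant curve and estimates its Tm from the first
#' derivative. Writes `tsa.json`.
#'
#' @param config Path to a YAML config or a named list (keys `melt_csv`,
#'   optional `melt_reference` naming the reference variant, `outdir`).
#' @return Invisibly, a named list of `tm_estimate` objects.
#' @export
run_tsa <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$melt_csv)) abort_argument("tsa stage needs 'melt_csv'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  curves <- read_melt_csv(cfg$melt_csv)
  ref <- NULL
  if (!is.null(cfg$melt_reference)) {
    if (!cfg$melt_reference %in% names(curves))
      abort_argument(sprintf("reference variant '%s' not in melt CSV",
                             cfg$melt_reference))
    ref <- curves[[cfg$melt_reference]]
    curves <- curves[names(curves) != cfg$melt_reference]
  }
  ests <- lapply(curves, function(cv) estimate_tm(normalize_melt(cv, ref)))
  write_tm_json(ests, file.path(cfg$outdir, "tsa.json"))
  provenance_log(cfg, cfg$melt_csv, file.path(cfg$outdir, "provenance.log"))
  invisible(ests)
}

#' Bundled example data: SPR affinities of IFN-gamma receptor 1 variants
#'
#' Published SPR kinetic constants for the wild-type extracellular domain of
#' human IFN-gamma receptor 1 and fourteen designed interface variants
#' (association rate `ka` in 1/(M s), dissociation rate `kd_rate` in 1/s,
#' `Kd` in M, replicate count `N`, and the estimated standard deviation of
#' Kd where `N` >= 3), together with the published free-energy summary per
#' variant (best force-field ddG across the four crystallographic interfaces,
#' MD-snapshot-averaged ddG, and the SPR-derived experimental ddG, all in
#' kJ/mol). The force-field and MD columns are carried as input data only —
#' this package does not recompute them.
#'
#' @return `ifng_affinity()`: the kinetic table as from
#'   [read_affinity_csv()]. `ifng_ddg_summary()`: the free-energy summary
#'   data frame.
#' @export
ifng_affinity <- function() {
  read_affinity_csv(system.file("extdata", "ifng_affinity_spr.csv",
                                package = "affidesign", mustWork = TRUE))
}

#' @rdname ifng_affinity
#' @export
ifng_ddg_summary <- function() {
  utils::read.delim(system.file("extdata", "ifng_ddg_summary.tsv",
                                package = "affidesign", mustWork = TRUE),
                    stringsAsFactors = FALSE,
                    na.strings = c("NA", "na"))
}
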