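#' Binding free-energy change from dissociation constants
#'
#' The change in Gibbs free energy of binding of a mutant relative to the
#' wild type follows from the ratio of their equilibrium dissociation
#' constants:
#' \deqn{\Delta\Delta G = -RT\,\ln\{(K_d)_{WT}/(K_d)_{mut}\}}
#' with R = 8.314 J/(mol K). A negative value means the mutant binds tighter
#' than the wild type.
#'
#' @param kd_mut,kd_wt Dissociation constants in M (both > 0).
#' @param temperature Temperature in K (default 298.15, i.e. 25 C at which
#'   the SPR affinities are measured).
#' @return ddG in kJ/mol.
#' @export
ddg_from_kd <- function(kd_mut, kd_wt, temperature = 298.15) {
  if (any(!is.finite(kd_mut)) || any(!is.finite(kd_wt)) ||
      any(kd_mut <= 0) || any(kd_wt <= 0))
    abort_domain("dissociation constants must be positive and finite")
  stopifnot_scalar_positive(temperature, "temperature")
  -RGAS * temperature * log(kd_wt / kd_mut) / 1000
}

#' Solve Eq. for the mutant Kd given a ddG
#'
#' Inverse of [ddg_from_kd()]: `kd_mut = kd_wt * exp(ddg * 1000 / (R T))`.
#' @param ddg ddG in kJ/mol.
#' @param kd_wt Wild-type Kd in M.
#' @param temperature Temperature in K.
#' @return Mutant Kd in M.
#' @export
kd_from_ddg <- function(ddg, kd_wt, temperature = 298.15) {
  if (any(kd_wt <= 0)) abort_domain("kd_wt must be positive")
  kd_wt * exp(ddg * 1000 / (RGAS * temperature))
}

#' Equilibrium dissociation constant from kinetic rates
#'
#' `Kd = kd / ka` for a 1:1 interaction.
#' @param ka Association rate constant, 1/(M s).
#' @param kd_rate Dissociation rate constant, 1/s.
#' @return Kd in M.
#' @export
kd_from_rates <- function(ka, kd_rate) {
  if (any(!is.finite(ka)) || any(!is.finite(kd_rate)) ||
      any(ka <= 0) || any(kd_rate <= 0))
    abort_domain("rate constants must be positive and finite")
  kd_rate / ka
}

#' Affinity fold change
#'
#' Ratio `kd_wt / kd_mut`; values above 1 mean the mutant binds tighter.
#' @param kd_wt,kd_mut Dissociation constants in M.
#' @return Dimensionless fold change.
#' @export
fold_change <- function(kd_wt, kd_mut) {
  if (any(kd_wt <= 0) || any(kd_mut <= 0))
    abort_domain("dissociation constants must be positive")
  kd_wt / kd_mut
}

#' Student-t confidence half-width for replicate measurements
#'
#' Half-width of the two-sided confidence interval of the mean of `n`
#' replicates with estimated standard deviation `esd`:
#' `t_{(1+level)/2, n-1} * esd / sqrt(n)`.
#'
#' @param esd Estimated standard deviation of the replicates (any unit).
#' @param n Number of replicates (>= 2).
#' @param level Confidence level, default 0.95.
#' @return Half-width in the units of `esd`.
#' @export
t_confidence_halfwidth <- function(esd, n, level = 0.95) {
  if (any(n < 2L)) abort_argument("need at least 2 replicates")
  if (any(esd <= 0)) abort_argument("'esd' must be positive")
  if (!is_scalar_number(level) || level <= 0 || level >= 1)
    abort_argument("'level' must be in (0, 1)")
  stats::qt((1 + level) / 2, df = n - 1L) * esd / sqrt(n)
}

#' Additivity analysis of multi-mutants
#'
#' For each multi-mutant, compares its measured ddG with the sum of the
#' measured ddG values of its constituent single mutations. A deviation of
#' zero means perfectly additive energetics.
#'
#' @param singles Data frame with columns `variant` (single-mutation labels)
#'   and `ddg` (kJ/mol).
#' @param multis Data frame with columns `variant` (labels joining singles
#'   with `+`, e.g. `"N70G + S95R"`) and `ddg`.
#' @return Data frame `multi`, `sum_of_singles`, `measured`, `deviation`
#'   (all kJ/mol).
#' @export
additivity_table <- function(singles, multis) {
  stopifnot(is.data.frame(singles), is.data.frame(multis),
            all(c("variant", "ddg") %in% names(singles)),
            all(c("variant", "ddg") %in% names(multis)))
  canon <- function(lbl) {
    mu <- parse_mutation(lbl)
    mutation_label(mu$wt, mu$position, mu$mut)
  }
  single_map <- stats::setNames(singles$ddg,
                                vapply(singles$variant, canon, ""))
  out <- lapply(seq_len(nrow(multis)), function(i) {
    parts <- parse_mutation(multis$variant[i])
    labs <- mutation_label(parts$wt, parts$position, parts$mut)
    missing <- setdiff(labs, names(single_map))
    if (length(missing))
      abort_argument(sprintf("constituent single(s) missing for '%s': %s",
                             multis$variant[i],
                             paste(missing, collapse = ", ")))
    s <- sum(single_map[labs])
    data.frame(multi = multis$variant[i], sum_of_singles = s,
               measured = multis$ddg[i], deviation = multis$ddg[i] - s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write affinity measurement tables
#'
#' CSV schema (SI units): `variant`, `ka` (1/(M s)), `kd_rate` (1/s), `Kd`
#' (M), `N` (replicates), `esd` (M; empty or `na` when `N` < 3).
#'
#' @param path CSV path.
#' @return A data frame with the columns above (`esd` is `NA` where absent).
#' @export
read_affinity_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "na", ""))
  need <- c("variant", "ka", "kd_rate", "Kd", "N", "esd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(sprintf("affinity CSV missing column(s): %s",
                         paste(miss, collapse = ", ")))
  for (col in c("ka", "kd_rate", "Kd"))
    if (any(!is.finite(df[[col]]) | df[[col]] <= 0))
      abort_format(sprintf("column '%s' must be positive", col))
  df$N <- as.integer(df$N)
  df
}

#' @rdname read_affinity_csv
#' @param df Affinity data frame.
#' @return `write_affinity_csv` returns `path` invisibly.
#' @export
write_affinity_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "na")
  invisible(path)
}

#' Per-variant affinity report relative to wild type
#'
#' From a kinetic affinity table, computes for each variant the experimental
#' ddG relative to the wild-type row (via [ddg_from_kd()]), the affinity fold
#' change, the Kd reconstructed from the kinetic rates, and the Student-t 95%
#' confidence half-width of Kd where three or more replicates exist.
#'
#' @param meas Affinity data frame as from [read_affinity_csv()].
#' @param wt_label Label of the wild-type row (default `"WT"`).
#' @param temperature Temperature in K.
#' @param level Confidence level for the half-widths.
#' @return Data frame `variant`, `Kd`, `kd_from_rates`, `ddg_kj_mol`,
#'   `fold_change`, `N`, `esd`, `ci_halfwidth`.
#' @export
affinity_report <- function(meas, wt_label = "WT", temperature = 298.15,
                            level = 0.95) {
  wi <- match(wt_label, meas$variant)
  if (is.na(wi))
    abort_argument(sprintf("wild-type row '%s' not found", wt_label))
  kd_wt <- meas$Kd[wi]
  ci <- ifelse(!is.na(meas$esd) & meas$N >= 2L,
               t_confidence_halfwidth(ifelse(is.na(meas$esd), 1, meas$esd),
                                      pmax(meas$N, 2L), level),
               NA_real_)
  data.frame(variant = meas$variant,
             Kd = meas$Kd,
             kd_from_rates = kd_from_rates(meas$ka, meas$kd_rate),
             ddg_kj_mol = ddg_from_kd(meas$Kd, kd_wt, temperature),
             fold_change = fold_change(kd_wt, meas$Kd),
             N = meas$N, esd = meas$esd, ci_halfwidth = ci,
             stringsAsFactors = FALSE)
}
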