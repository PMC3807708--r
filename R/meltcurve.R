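#' Construct a thermal-shift melt curve
#'
#' @param temperature Temperature grid in degrees C, strictly increasing.
#' @param fluorescence Fluorescence readings (arbitrary units), same length.
#' @param normalized,reference_subtracted Bookkeeping flags.
#' @return A `melt_curve` data frame.
#' @export
melt_curve <- function(temperature, fluorescence, normalized = FALSE,
                       reference_subtracted = FALSE) {
  if (length(temperature) != length(fluorescence))
    abort_argument("temperature and fluorescence must have equal length")
  if (is.unsorted(temperature, strictly = TRUE))
    abort_argument("temperature grid must be strictly increasing")
  structure(data.frame(temperature = temperature,
                       fluorescence = fluorescence),
            class = c("melt_curve", "data.frame"),
            normalized = normalized,
            reference_subtracted = reference_subtracted)
}

#' Reference-subtract and min-max normalize a melt curve
#'
#' Subtracts a no-protein reference curve (linearly resampled onto the raw
#' grid when the grids differ) and rescales the result to the unit interval.
#'
#' @param raw A `melt_curve`.
#' @param reference Optional reference `melt_curve` (dye in buffer, no
#'   protein).
#' @return A normalized `melt_curve` on `[0, 1]`.
#' @export
normalize_melt <- function(raw, reference = NULL) {
  stopifnot(inherits(raw, "melt_curve"))
  f <- raw$fluorescence
  if (!is.null(reference)) {
    if (min(reference$temperature) > min(raw$temperature) + 1e-9 ||
        max(reference$temperature) < max(raw$temperature) - 1e-9)
      abort_argument("reference curve does not cover the raw temperature range")
    f <- f - stats::approx(reference$temperature, reference$fluorescence,
                           xout = raw$temperature)$y
  }
  rng <- range(f)
  if (diff(rng) <= 0)
    abort_degenerate("constant fluorescence signal; cannot normalize")
  melt_curve(raw$temperature, (f - rng[1L]) / diff(rng), normalized = TRUE,
             reference_subtracted = !is.null(reference))
}

#' Estimate the melting temperature from the first derivative
#'
#' Computes the central-difference first derivative of the (normalized)
#' fluorescence with respect to temperature and takes Tm as the derivative
#' maximum, refined by quadratic interpolation through the peak point and its
#' two neighbours. If the maximum falls on the grid boundary, the grid
#' maximum is returned with a warning; if the derivative is nowhere positive
#' (no unfolding transition), an error is raised.
#'
#' @param c A `melt_curve` with at least 7 points.
#' @param refine Quadratic sub-grid refinement (default `TRUE`).
#' @param smooth_window Optional odd moving-average window (in points)
#'   applied to the fluorescence before differentiation; `NULL` (default)
#'   disables smoothing.
#' @return A `tm_estimate`: list with `tm` (degrees C),
#'   `derivative_peak_height` (AU per degree C), `method`.
#' @export
estimate_tm <- function(c, refine = TRUE, smooth_window = NULL) {
  stopifnot(inherits(c, "melt_curve"))
  if (nrow(c) < 7L) abort_argument("need at least 7 points")
  f <- c$fluorescence
  if (!is.null(smooth_window)) {
    k <- as.integer(smooth_window)
    if (k %% 2L != 1L || k < 3L)
      abort_argument("'smooth_window' must be an odd integer >= 3")
    f <- stats::filter(f, rep(1 / k, k), sides = 2L)
    keep <- !is.na(f)
    f <- as.numeric(f[keep]); temp <- c$temperature[keep]
  } else temp <- c$temperature
  n <- length(f)
  i <- 2:(n - 1L)
  d <- (f[i + 1L] - f[i - 1L]) / (temp[i + 1L] - temp[i - 1L])
  td <- temp[i]
  if (all(d <= 0))
    abort(paste("no positive first derivative: curve shows no unfolding",
                "transition"), "affidesign_no_transition_error")
  pk <- which.max(d)
  if (pk == 1L || pk == length(d)) {
    warning("derivative maximum at the grid boundary; returning grid maximum")
    return(structure(list(tm = td[pk], derivative_peak_height = d[pk],
                          method = "grid-max"), class = "tm_estimate"))
  }
  tm <- td[pk]; method <- "grid-max"
  if (refine) {
    # vertex of the parabola through the peak and its neighbours
    x <- td[(pk - 1L):(pk + 1L)]; y <- d[(pk - 1L):(pk + 1L)]
    denom <- (y[1L] - 2 * y[2L] + y[3L])
    if (abs(denom) > .Machine$double.eps) {
      tm <- x[2L] + 0.5 * (x[3L] - x[2L]) * (y[1L] - y[3L]) / denom
      method <- "quadratic-refined"
    }
  }
  structure(list(tm = tm, derivative_peak_height = d[pk], method = method),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("<tm_estimate> Tm = %.2f C (%s), peak %.3g AU/C\n",
              x$tm, x$method, x$derivative_peak_height))
  invisible(x)
}

#' Read / write melt curves as CSV
#'
#' CSV schema: `temperature_C`, `fluorescence_AU`, `variant`; one file can
#' hold several curves distinguished by `variant`.
#'
#' @param path CSV path.
#' @return `read_melt_csv` returns a named list of `melt_curve` objects.
#' @export
read_melt_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "fluorescence_AU", "variant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(sprintf("melt CSV missing column(s): %s",
                         paste(miss, collapse = ", ")))
  lapply(split(df, df$variant), function(d)
    melt_curve(d$temperature_C, d$fluorescence_AU))
}

#' @rdname read_melt_csv
#' @param curves Named list of `melt_curve` objects.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curve = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm)
    data.frame(temperature_C = curves[[nm]]$temperature,
               fluorescence_AU = curves[[nm]]$fluorescence, variant = nm)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Tm estimate as JSON
#' @param est A `tm_estimate` (or named list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tm_json <- function(est, path) {
  if (inherits(est, "tm_estimate")) est <- list(curve = est)
  jsonlite::write_json(lapply(est, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
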