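#' Kinetic parameters of a 1:1 Langmuir-with-drift binding model
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd_rate Dissociation rate constant, 1/s.
#' @param Rmax Maximum analyte binding capacity, response units (RU).
#' @param drift Linear baseline drift, RU/s (one slope per curve, continuous
#'   across phases).
#' @param R0 Baseline response at the start of the association phase, RU.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(ka, kd_rate, Rmax, drift = 0, R0 = 0) {
  stopifnot_scalar_positive(ka, "ka")
  stopifnot_scalar_positive(kd_rate, "kd_rate")
  stopifnot_scalar_positive(Rmax, "Rmax")
  structure(list(ka = ka, kd_rate = kd_rate, Rmax = Rmax, drift = drift,
                 R0 = R0),
            class = "kinetic_params")
}

# Closed-form noise-free response of the 1:1 pseudo-first-order model with a
# linear drift term, continuous at the phase boundary:
#   association (0 <= t <= t_assoc):
#     R(t) = Req (1 - exp(-(ka C + kd) t)) + drift t + R0,
#     Req  = ka C Rmax / (ka C + kd)
#   dissociation (t > t_assoc):
#     R(t) = R_end exp(-kd (t - t_assoc)) + drift t + R0,
#     R_end = binding component at the end of association
langmuir_response <- function(t, conc, ka, kd_rate, Rmax, drift, R0, t_assoc) {
  kobs <- ka * conc + kd_rate
  req <- if (conc > 0) ka * conc * Rmax / kobs else 0
  r_end <- req * (1 - exp(-kobs * t_assoc))
  assoc <- t <= t_assoc
  out <- numeric(length(t))
  out[assoc] <- req * (1 - exp(-kobs * t[assoc]))
  out[!assoc] <- r_end * exp(-kd_rate * (t[!assoc] - t_assoc))
  out + drift * t + R0
}

#' Simulate an SPR sensorgram
#'
#' Generates a noise-free 1:1 Langmuir-with-drift response on a regular time
#' grid (association followed by dissociation) and adds i.i.d. Gaussian noise.
#' Defaults mirror a typical short-contact experiment: 90 s association,
#' 10 min dissociation.
#'
#' @param p A [kinetic_params()] object.
#' @param conc Analyte concentration in M (>= 0).
#' @param t_assoc,t_dissoc Phase durations in s.
#' @param dt Sampling interval in s (default 0.1).
#' @param noise_sd Gaussian noise standard deviation in RU.
#' @param seed Integer seed for the noise (reproducible; `NULL` uses the
#'   current RNG stream).
#' @param channel `"active"`, `"reference"` or `"interspot"`.
#' @return A `sensorgram`: data frame `time`, `response`, `phase` with
#'   attributes `concentration` and `channel`.
#' @export
simulate_sensorgram <- function(p, conc, t_assoc = 90, t_dissoc = 600,
                                dt = 0.1, noise_sd = 0, seed = NULL,
                                channel = "active") {
  stopifnot(inherits(p, "kinetic_params"))
  if (conc < 0) abort_argument("'conc' must be >= 0")
  stopifnot_scalar_positive(t_assoc, "t_assoc")
  stopifnot_scalar_positive(t_dissoc, "t_dissoc")
  stopifnot_scalar_positive(dt, "dt")
  if (dt >= t_assoc || dt >= t_dissoc)
    abort_argument("'dt' must be smaller than both phase durations")
  t_a <- seq(0, t_assoc, by = dt)
  t_d <- seq(t_assoc + dt, t_assoc + t_dissoc, by = dt)
  t <- c(t_a, t_d)
  r <- langmuir_response(t, conc, p$ka, p$kd_rate, p$Rmax, p$drift, p$R0,
                         t_assoc)
  if (noise_sd > 0)
    r <- r + with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  new_sensorgram(t, r,
                 phase = c(rep("association", length(t_a)),
                           rep("dissociation", length(t_d))),
                 concentration = conc, channel = channel, t_assoc = t_assoc)
}

new_sensorgram <- function(time, response, phase, concentration, channel,
                           t_assoc = NULL) {
  if (is.unsorted(time, strictly = TRUE))
    abort_argument("time grid must be strictly increasing")
  if (is.null(t_assoc))
    t_assoc <- max(time[phase == "association"])
  structure(data.frame(time = time, response = response, phase = phase,
                       stringsAsFactors = FALSE),
            class = c("sensorgram", "data.frame"),
            concentration = concentration, channel = channel,
            t_assoc = t_assoc)
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> %s, C = %.3g nM, %d points (%.0f s assoc / %.0f s dissoc)\n",
              attr(x, "channel"), attr(x, "concentration") * 1e9, nrow(x),
              attr(x, "t_assoc"), max(x$time) - attr(x, "t_assoc")))
  invisible(x)
}

resample_onto <- function(sg, time) {
  if (min(sg$time) > min(time) + 1e-9 || max(sg$time) < max(time) - 1e-9)
    abort_argument("sensorgram time ranges do not overlap for resampling")
  stats::approx(sg$time, sg$response, xout = time)$y
}

#' Double referencing of SPR sensorgrams
#'
#' Removes bulk refractive-index and nonspecific contributions:
#' `corrected = active - interspot - (reference - reference_interspot)`.
#' When the reference channel's own interspot is not given, the active
#' interspot is used for both subtractions. Curves on different time grids
#' are linearly resampled onto the active grid.
#'
#' @param active,reference_channel,interspot `sensorgram` objects.
#' @param reference_interspot Optional interspot of the reference channel.
#' @return The corrected `sensorgram` (channel `"corrected"`).
#' @export
double_reference <- function(active, reference_channel, interspot,
                             reference_interspot = interspot) {
  stopifnot(inherits(active, "sensorgram"))
  corr <- active$response -
    resample_onto(interspot, active$time) -
    (resample_onto(reference_channel, active$time) -
       resample_onto(reference_interspot, active$time))
  out <- new_sensorgram(active$time, corr, active$phase,
                        attr(active, "concentration"), "corrected",
                        attr(active, "t_assoc"))
  attr(out, "referencing") <- "double (interspot + reference channel)"
  out
}

#' Globally fit a concentration series to the 1:1 Langmuir-with-drift model
#'
#' Nonlinear least squares over all curves simultaneously with `ka`,
#' `kd_rate` and `Rmax` shared globally and one drift slope per curve
#' (optionally plus a per-curve baseline offset `R0`). Rate and capacity
#' parameters are optimized on the log scale. Initial guesses are data
#' driven: `kd` from a log-linear regression of the dissociation tail, `ka`
#' from the regression of observed association rates on concentration;
#' additional multi-starts jitter these log-uniformly under a fixed seed.
#' Standard errors come from the Jacobian at the optimum.
#'
#' @param curves List of `sensorgram` objects at distinct concentrations.
#' @param fit_r0 Also fit a per-curve baseline offset (default `FALSE`).
#' @param multistart Number of starts (default 5; the first is the heuristic
#'   guess).
#' @param seed Seed for the multi-start jitter.
#' @param per_curve Fit each curve independently instead of globally
#'   (default `FALSE`); returns a list of fits.
#' @return A `langmuir_fit`: list with `ka`, `kd_rate`, `Rmax`, `drift`
#'   (per curve), `Kd` (= kd_rate/ka), `residual_rms`, `se` (standard errors
#'   of ka, kd_rate, Rmax), `converged`, `n_points`.
#' @export
fit_langmuir_drift <- function(curves, fit_r0 = FALSE, multistart = 5,
                               seed = 1, per_curve = FALSE) {
  if (inherits(curves, "sensorgram")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, TRUE, "sensorgram")))
  if (per_curve)
    return(lapply(curves, function(cv)
      fit_langmuir_drift(list(cv), fit_r0 = fit_r0, multistart = multistart,
                         seed = seed)))
  concs <- vapply(curves, attr, 0, "concentration")
  if (length(curves) < 2L)
    warning("fitting a single concentration; rate constants may be poorly determined")
  if (anyDuplicated(concs))
    abort_argument("curves must be at distinct concentrations")
  nc <- length(curves)
  t_assoc <- vapply(curves, attr, 0, "t_assoc")

  model_vec <- function(lka, lkd, lRmax, drifts, r0s) {
    unlist(lapply(seq_len(nc), function(i)
      langmuir_response(curves[[i]]$time, concs[i], exp(lka), exp(lkd),
                        exp(lRmax), drifts[i], r0s[i], t_assoc[i])),
      use.names = FALSE)
  }
  obs <- unlist(lapply(curves, `[[`, "response"), use.names = FALSE)
  resid_fn <- function(par) {
    drifts <- par[4:(3 + nc)]
    r0s <- if (fit_r0) par[(4 + nc):(3 + 2 * nc)] else rep(0, nc)
    model_vec(par[1L], par[2L], par[3L], drifts, r0s) - obs
  }

  guess <- initial_guess(curves, concs, t_assoc)
  starts <- list(c(log(guess$ka), log(guess$kd), log(guess$Rmax),
                   guess$drift, if (fit_r0) rep(0, nc)))
  if (multistart > 1L) {
    jit <- with_seed(seed,
                     matrix(stats::runif(3L * (multistart - 1L), -0.5, 0.5),
                            ncol = 3L))
    for (i in seq_len(multistart - 1L))
      starts[[i + 1L]] <- c(log(guess$ka) + jit[i, 1L] * log(10),
                            log(guess$kd) + jit[i, 2L] * log(10),
                            log(guess$Rmax) + jit[i, 3L] * log(10),
                            guess$drift, if (fit_r0) rep(0, nc))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12 * (1 + best$ssr))
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    abort_fit(sprintf("Langmuir fit failed to converge after %d start(s)",
                      length(starts)))
  fit <- best$fit
  par <- fit$par
  ka <- exp(par[1L]); kd <- exp(par[2L]); Rmax <- exp(par[3L])
  n_points <- length(obs)
  dof <- max(n_points - length(par), 1L)
  sigma2 <- best$ssr / dof
  se_log <- tryCatch(sqrt(diag(sigma2 * solve(fit$hessian))[1:3]),
                     error = function(e) rep(NA_real_, 3L))
  converged <- fit$info %in% 1:3
  if (!converged)
    warning(sprintf("nls.lm stopped with info=%d (%s)", fit$info, fit$message))

  structure(list(
    ka = ka, kd_rate = kd, Rmax = Rmax,
    drift = par[4:(3 + nc)],
    R0 = if (fit_r0) par[(4 + nc):(3 + 2 * nc)] else rep(0, nc),
    Kd = kd / ka,
    concentrations = concs,
    residual_rms = sqrt(best$ssr / n_points),
    se = list(ka = ka * se_log[1L], kd_rate = kd * se_log[2L],
              Rmax = Rmax * se_log[3L]),
    converged = converged, n_points = n_points,
    starts = length(starts)),
    class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf(paste0("<langmuir_fit> ka = %.3g 1/(M s), kd = %.3g 1/s, ",
                     "Kd = %.3g nM\n  Rmax = %.3g RU, rms = %.3g RU over %d ",
                     "points (%d curves)%s\n"),
              x$ka, x$kd_rate, x$Kd * 1e9, x$Rmax, x$residual_rms, x$n_points,
              length(x$drift), if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# data-driven initial guesses; robustness matters more than accuracy here
initial_guess <- function(curves, concs, t_assoc) {
  nc <- length(curves)
  drifts <- numeric(nc)
  for (i in seq_len(nc)) {
    dis <- curves[[i]][curves[[i]]$phase == "dissociation", , drop = FALSE]
    tail <- dis[dis$time >= stats::quantile(dis$time, 0.75), , drop = FALSE]
    drifts[i] <- if (nrow(tail) >= 2L)
      stats::coef(stats::lm(response ~ time, tail))[2L] else 0
    if (!is.finite(drifts[i])) drifts[i] <- 0
  }
  # kd from log-linear decay of the highest-concentration curve
  hi <- which.max(concs)
  dis <- curves[[hi]][curves[[hi]]$phase == "dissociation", , drop = FALSE]
  y <- dis$response - drifts[hi] * dis$time
  y <- y - min(y)
  keep <- y > 0.05 * max(y) & seq_len(nrow(dis)) <= 0.6 * nrow(dis)
  kd0 <- if (sum(keep) >= 3L) {
    sl <- stats::coef(stats::lm(log(y[keep]) ~ dis$time[keep]))[2L]
    max(min(-sl, 10), 1e-5)
  } else 1e-2
  # ka from kobs vs concentration via half-rise times of the association phase
  kobs <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    if (concs[i] <= 0) next
    asc <- curves[[i]][curves[[i]]$phase == "association", , drop = FALSE]
    y <- asc$response - drifts[i] * asc$time
    plateau <- stats::median(utils::tail(y, max(3L, nrow(asc) %/% 10L)))
    if (plateau <= 0) next
    ih <- which(y >= plateau / 2)[1L]
    if (!is.na(ih) && asc$time[ih] > 0) kobs[i] <- log(2) / asc$time[ih]
  }
  ok <- is.finite(kobs) & concs > 0
  ka0 <- if (sum(ok) >= 2L) {
    sl <- stats::coef(stats::lm(kobs[ok] ~ concs[ok]))[2L]
    if (is.finite(sl) && sl > 0) sl else kd0 / stats::median(concs[ok])
  } else if (any(ok)) {
    max((kobs[ok][1L] - kd0) / concs[ok][1L], kd0 / concs[ok][1L])
  } else 1e5
  rmax0 <- max(vapply(curves, function(cv) max(cv$response), 0), 1e-3)
  list(ka = max(ka0, 1), kd = kd0, Rmax = rmax0 * 1.2, drift = drifts)
}

#' Read / write sensorgrams as CSV
#'
#' CSV schema: `time_s`, `response_RU`, `phase`, `concentration_M`,
#' `channel`; one file can hold several curves distinguished by
#' (concentration, channel).
#'
#' @param path CSV path.
#' @return `read_sensorgram_csv` returns a list of `sensorgram` objects.
#' @export
read_sensorgram_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response_RU", "phase", "concentration_M", "channel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(sprintf("sensorgram CSV missing column(s): %s",
                         paste(miss, collapse = ", ")))
  key <- paste(df$concentration_M, df$channel, sep = "\r")
  lapply(split(df, key), function(d)
    new_sensorgram(d$time_s, d$response_RU, d$phase, d$concentration_M[1L],
                   d$channel[1L]))
}

#' @rdname read_sensorgram_csv
#' @param curves List of `sensorgram` objects.
#' @export
write_sensorgram_csv <- function(curves, path) {
  if (inherits(curves, "sensorgram")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(time_s = cv$time, response_RU = cv$response, phase = cv$phase,
               concentration_M = attr(cv, "concentration"),
               channel = attr(cv, "channel"))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Langmuir fit result as JSON
#' @param fit A `langmuir_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
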