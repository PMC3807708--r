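# Internal helpers shared across modules.

# Gas constant, J/(mol K)
RGAS <- 8.314

# Three- and one-letter amino acid codes (20 standard residues)
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

aa_three_to_one <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(x) {
  out <- AA3[match(toupper(x), AA1)]
  out[is.na(out)] <- "UNK"
  out
}

# classed conditions so callers/tests can discriminate failure modes
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "affidesign_error")))
}

abort_io        <- function(msg) abort(msg, "affidesign_io_error")
abort_format    <- function(msg) abort(msg, "affidesign_format_error")
abort_argument  <- function(msg) abort(msg, "affidesign_argument_error")
abort_domain    <- function(msg) abort(msg, "affidesign_domain_error")
abort_fit       <- function(msg) abort(msg, "affidesign_fit_error")
abort_degenerate <- function(msg) abort(msg, "affidesign_degenerate_error")
abort_generation <- function(msg) abort(msg, "affidesign_generation_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; every stochastic operation in the package funnels through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a master seed; fixed documented offsets
# keep each generated dataset individually reproducible. Kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    abort_argument(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}
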