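#' Read a multiple sequence alignment in aligned-FASTA format
#'
#' @param path Path to an aligned FASTA file (gaps as `-`).
#' @return An `msa_alignment`: list with `ids`, `seqs` (upper-case gapped
#'   strings), `length` (number of columns).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read alignment '%s'", path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE),
    error = function(e) abort_format(sprintf("failed to parse FASTA: %s",
                                             conditionMessage(e))))
  if (length(recs) < 2L) abort_format("alignment needs at least 2 records")
  ids <- names(recs)
  if (anyDuplicated(ids))
    abort_format(sprintf("duplicate sequence id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(vapply(recs, `[[`, "", 1L))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    abort_format(sprintf("ragged alignment: record lengths %s",
                         paste(unique(widths), collapse = ", ")))
  new_alignment(ids, unname(seqs))
}

new_alignment <- function(ids, seqs) {
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 length = nchar(seqs[1L])),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Write an alignment as aligned FASTA
#' @param a An `msa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  seqinr::write.fasta(as.list(a$seqs), names = a$ids, file.out = path,
                      nbchar = 60)
  invisible(path)
}

alignment_matrix <- function(a) {
  do.call(rbind, strsplit(a$seqs, "", fixed = TRUE))
}

#' Per-position conservation relative to a reference sequence
#'
#' For each ungapped position of the reference sequence, the conservation
#' fraction is the share of aligned sequences (reference included by default)
#' whose residue at that column is identical to the reference residue; gaps
#' count as mismatches. The modal (consensus) residue of the column is also
#' reported, ties broken alphabetically. Positions are numbered 1..L along the
#' ungapped reference.
#'
#' @param a An `msa_alignment`.
#' @param reference_id Id of the reference record (the sequence being mutated).
#' @param include_reference Count the reference in the denominator (default
#'   `TRUE`, i.e. the n-of-n convention).
#' @return A `conservation_profile`: data frame with `position`,
#'   `ref_residue`, `fraction`, `consensus`.
#' @export
column_conservation <- function(a, reference_id, include_reference = TRUE) {
  stopifnot(inherits(a, "msa_alignment"))
  ri <- match(reference_id, a$ids)
  if (is.na(ri))
    abort_argument(sprintf("reference id '%s' not in alignment", reference_id))
  m <- alignment_matrix(a)
  ref <- m[ri, ]
  cols <- which(ref != "-")
  n <- nrow(m)
  frac <- vapply(cols, function(j) {
    matches <- sum(m[, j] == ref[j])
    if (include_reference) matches / n else (matches - 1L) / (n - 1L)
  }, 0)
  consensus <- vapply(cols, function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1L]   # modal, ties alphabetical
  }, "")
  structure(data.frame(position = seq_along(cols), ref_residue = ref[cols],
                       fraction = frac, consensus = consensus,
                       stringsAsFactors = FALSE),
            class = c("conservation_profile", "data.frame"),
            reference_id = reference_id,
            include_reference = include_reference)
}

#' Conserved positions above a threshold
#'
#' A position is vetoed as conserved when its fraction is strictly greater
#' than the threshold; a fraction exactly at the threshold is not conserved.
#'
#' @param p A `conservation_profile`.
#' @param threshold Conservation fraction in (0, 1); default 0.65.
#' @return Integer vector of conserved reference positions.
#' @export
conserved_positions <- function(p, threshold = 0.65) {
  stopifnot(inherits(p, "conservation_profile"))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    abort_argument("'threshold' must be in (0, 1)")
  p$position[p$fraction > threshold]
}

#' Map positions between reference and structure numbering
#'
#' The two numbering frames differ by a constant offset (17 for this
#' receptor: structure numbering = UniProt numbering - 17).
#'
#' @param pos Integer position(s).
#' @param offset Offset between reference and structure numbering.
#' @param direction `"ref_to_structure"` (subtracts the offset) or
#'   `"structure_to_ref"` (adds it).
#' @param range Optional length-2 integer vector of valid *input* positions;
#'   out-of-range input raises an error.
#' @return Mapped integer position(s).
#' @export
map_numbering <- function(pos, offset = 17L,
                          direction = c("ref_to_structure", "structure_to_ref"),
                          range = NULL) {
  direction <- match.arg(direction)
  pos <- as.integer(pos)
  if (!is.null(range) && any(pos < range[1L] | pos > range[2L]))
    abort_argument("position outside the mapped range")
  if (direction == "ref_to_structure") pos - as.integer(offset)
  else pos + as.integer(offset)
}

#' Write a conservation profile as TSV, and the veto set as JSON
#'
#' @param p A `conservation_profile`.
#' @param path Output path.
#' @param threshold Conservation threshold for the JSON veto set.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
write_conserved_json <- function(p, path, threshold = 0.65) {
  jsonlite::write_json(
    list(reference_id = attr(p, "reference_id"), threshold = threshold,
         conserved_positions = conserved_positions(p, threshold)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
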