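#' Alignment parameters
#'
#' Scoring for the banded global affine-gap alignment of inserts against
#' their reference amplicon. Penalties are positive numbers; a gap of length
#' k costs `gap_open + k * gap_ext`. The band allows paths within
#' `band` diagonals of the main diagonal (automatically widened by the
#' length difference of the two sequences), so it must be at least the
#' largest expected indel. Alignments with identity (matches / reference
#' length) below `min_identity` are rejected and contribute no site
#' observations.
#'
#' @param match match score (default 1).
#' @param mismatch mismatch penalty (default 1).
#' @param gap_open,gap_ext gap open/extension penalties (default 2 and 1).
#' @param band band half-width in diagonals (default 10).
#' @param min_identity minimum identity to accept an alignment (default 0.9).
#' @return object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = 1, gap_open = 2, gap_ext = 1,
                         band = 10L, min_identity = 0.9) {
  stopifnot(mismatch >= 0, gap_open >= 0, gap_ext >= 0, band >= 1,
            min_identity >= 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, band = as.integer(band),
                 min_identity = min_identity), class = "align_params")
}

#' Align one read to a reference sequence
#'
#' Banded global alignment with affine gaps; deterministic under a fixed
#' tie-break (diagonal preferred over gap-in-read over gap-in-reference).
#'
#' @param insert_sequence read sequence (prefix/suffix segments already
#'   trimmed).
#' @param reference reference sequence to align against.
#' @param params an [align_params()].
#' @return list with `score`, `identity` (matches / reference length),
#'   `ref_row` (one character per reference position: the aligned read base,
#'   or `-` where the read has a gap) and `accepted` (identity >=
#'   `min_identity`).
#' @export
align_read <- function(insert_sequence, reference, params = align_params()) {
  stopifnot(nzchar(insert_sequence), nzchar(reference))
  a <- cpp_align_batch(insert_sequence, reference, params$match,
                       params$mismatch, params$gap_open, params$gap_ext,
                       params$band)
  list(score = a$score[[1L]], identity = a$identity[[1L]],
       ref_row = a$ref_row[[1L]],
       accepted = a$identity[[1L]] >= params$min_identity)
}

#' Extract per-site base observations from a marker's sorted reads
#'
#' Each insert is aligned to the marker's reference insert region (the
#' reference amplicon with both primer spans removed; sorted reads no longer
#' carry primers). For every annotated variant site of the marker, the read
#' base aligned to the site's reference position is recorded; a gap or an
#' uncovered position is recorded as `N` (null allele or deletion). Reads
#' whose alignment identity falls below the acceptance threshold contribute
#' no observations.
#'
#' @param inserts character vector of insert sequences (one per read).
#' @param marker an `amp_marker`.
#' @param params an [align_params()].
#' @return data.frame with columns read, site_id, observed (A/C/G/T/N) and
#'   identity; attribute `n_rejected` counts rejected reads.
#' @export
observe_sites <- function(inserts, marker, params = align_params()) {
  fp <- nchar(marker$forward_primer)
  rp <- nchar(marker$reverse_primer)
  ref <- substr(marker$reference_amplicon, fp + 1L,
                nchar(marker$reference_amplicon) - rp)
  empty <- data.frame(read = character(), site_id = character(),
                      observed = character(), identity = numeric(),
                      stringsAsFactors = FALSE)
  if (length(inserts) == 0L || nrow(marker$sites) == 0L) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  keep <- nzchar(inserts)
  inserts <- inserts[keep]
  if (length(inserts) == 0L) {
    attr(empty, "n_rejected") <- sum(!keep)
    return(empty)
  }
  a <- cpp_align_batch(unname(inserts), ref, params$match, params$mismatch,
                       params$gap_open, params$gap_ext, params$band)
  ok <- a$identity >= params$min_identity
  if (!any(ok)) {
    attr(empty, "n_rejected") <- length(inserts) + sum(!keep)
    return(empty)
  }
  pos_in_insert <- marker$sites$position - fp
  ids <- names(inserts) %||% as.character(seq_along(inserts))
  rows <- lapply(seq_len(nrow(marker$sites)), function(r) {
    obs <- substring(a$ref_row[ok], pos_in_insert[r], pos_in_insert[r])
    obs[!obs %in% DNA_BASES] <- "N"
    data.frame(read = ids[ok], site_id = marker$sites$site_id[r],
               observed = obs, identity = a$identity[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_rejected") <- sum(!ok) + sum(!keep)
  out
}

# full-matrix dynamic-programming reference implementation, used as an
# internal cross-check: identical recursion without the band restriction
full_dp_align <- function(read, ref, params = align_params()) {
  a <- cpp_align_batch(read, ref, params$match, params$mismatch,
                       params$gap_open, params$gap_ext,
                       band = nchar(read) + nchar(ref))
  list(score = a$score[[1L]], identity = a$identity[[1L]],
       ref_row = a$ref_row[[1L]])
}
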