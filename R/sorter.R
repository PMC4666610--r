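#' Demultiplex reads into samples by barcode
#'
#' Each read's prefix is compared against every barcode (each at its own
#' length) by Hamming distance; the read is assigned to the unique best match
#' with at most `max_barcode_mismatch` mismatches and the barcode prefix is
#' removed. Ties at equal mismatch count are broken toward the longer
#' barcode; an exact tie leaves the read unassigned. Barcodes must be
#' separable at the chosen tolerance, otherwise assignment would be
#' systematically ambiguous and a configuration error is raised.
#'
#' @param reads character vector of read sequences (or a `DNAStringSet`),
#'   or a FASTQ path.
#' @param samples sample sheet data.frame (sample_id, barcode).
#' @param max_barcode_mismatch Hamming tolerance, default 1.
#' @return list with `reads` (named list: sample_id -> named character vector
#'   of barcode-trimmed reads) and `stats` (n_in, per_sample, unassigned,
#'   ambiguous; counts conserve n_in).
#' @export
demultiplex <- function(reads, samples, max_barcode_mismatch = 1L) {
  reads <- as_read_vector(reads)
  bc <- samples$barcode
  dmin <- min_pairwise_distance(bc)
  if (length(bc) > 1L && dmin <= max_barcode_mismatch)
    stop_validation("barcode tolerance ", max_barcode_mismatch,
                    " >= minimum pairwise barcode distance ", dmin)
  hit <- cpp_best_prefix_match(unname(reads), bc, as.integer(max_barcode_mismatch))
  idx <- hit[, 1L]
  out <- vector("list", nrow(samples))
  names(out) <- samples$sample_id
  for (k in seq_len(nrow(samples))) {
    sel <- which(idx == k)
    r <- reads[sel]
    out[[k]] <- setNames(substring(r, nchar(bc[k]) + 1L), names(r))
  }
  stats <- list(n_in = length(reads),
                per_sample = setNames(tabulate(idx[idx > 0], nrow(samples)),
                                      samples$sample_id),
                unassigned = sum(idx == 0L),
                ambiguous = sum(idx == -1L))
  list(reads = out, stats = stats)
}

#' Assign one sample's reads to markers by forward-primer match
#'
#' After demultiplexing, the next expected read segment is the M13 tail
#' followed by the marker's forward primer. That expected prefix is compared
#' per marker by Hamming distance (substitutions only, no indels); the read
#' goes to the unique best match within `max_primer_mismatch`, the prefix is
#' stripped, and a trailing reverse-primer-complement + P1/B adapter segment
#' is trimmed when present (within 25% mismatches of its length). Reads
#' matching no marker are unassigned; ambiguous best matches are discarded
#' and counted.
#'
#' @param sample_reads named character vector of barcode-trimmed reads.
#' @param p an `amp_panel`.
#' @param max_primer_mismatch Hamming tolerance over the tail+primer prefix,
#'   default 2.
#' @return list with `reads` (marker_id -> named character vector of insert
#'   sequences) and `stats` (n_in, per_marker, unassigned, ambiguous).
#' @export
assign_marker <- function(sample_reads, p, max_primer_mismatch = 2L) {
  ids <- marker_ids(p)
  prefixes <- paste0(p$adapters$m13_tail,
                     vapply(p$markers, `[[`, "", "forward_primer"))
  tails <- vapply(p$markers, function(m)
    paste0(revcomp(m$reverse_primer), p$adapters$trp1_adapter), "")
  out <- setNames(vector("list", length(ids)), ids)
  if (length(sample_reads) == 0L) {
    for (k in seq_along(ids)) out[[k]] <- character(0)
    return(list(reads = out,
                stats = list(n_in = 0L,
                             per_marker = setNames(integer(length(ids)), ids),
                             unassigned = 0L, ambiguous = 0L)))
  }
  hit <- cpp_best_prefix_match(unname(sample_reads), prefixes,
                               as.integer(max_primer_mismatch))
  idx <- hit[, 1L]
  for (k in seq_along(ids)) {
    sel <- which(idx == k)
    r <- setNames(substring(sample_reads[sel], nchar(prefixes[k]) + 1L),
                  names(sample_reads)[sel])
    out[[k]] <- trim_tail(r, tails[k])
  }
  list(reads = out,
       stats = list(n_in = length(sample_reads),
                    per_marker = setNames(tabulate(idx[idx > 0], length(ids)), ids),
                    unassigned = sum(idx == 0L),
                    ambiguous = sum(idx == -1L)))
}

# strip the expected trailing segment when it matches within 25% mismatches
trim_tail <- function(reads, tail) {
  if (length(reads) == 0L) return(reads)
  lt <- nchar(tail)
  ln <- nchar(reads)
  cand <- which(ln > lt)
  if (length(cand)) {
    suf <- substring(reads[cand], ln[cand] - lt + 1L, ln[cand])
    mm <- cpp_best_prefix_match(suf, tail, as.integer(ceiling(0.25 * lt)))
    ok <- cand[mm[, 1L] == 1L]
    reads[ok] <- substring(reads[ok], 1L, ln[ok] - lt)
  }
  reads
}

#' Sort a whole run: demultiplex then assign markers
#'
#' Convenience wrapper running both sorting stages and collecting
#' conservation statistics.
#'
#' @inheritParams demultiplex
#' @inheritParams assign_marker
#' @return list with `reads` (nested: sample_id -> marker_id -> insert
#'   vector) and `stats` (combined two-stage statistics).
#' @export
sort_reads <- function(reads, p, max_barcode_mismatch = 1L,
                       max_primer_mismatch = 2L) {
  dm <- demultiplex(reads, p$samples, max_barcode_mismatch)
  sorted <- vector("list", nrow(p$samples))
  names(sorted) <- p$samples$sample_id
  per_pair <- list()
  unassigned_marker <- 0L
  ambiguous_marker <- 0L
  for (sid in p$samples$sample_id) {
    am <- assign_marker(dm$reads[[sid]], p, max_primer_mismatch)
    sorted[[sid]] <- am$reads
    unassigned_marker <- unassigned_marker + am$stats$unassigned
    ambiguous_marker <- ambiguous_marker + am$stats$ambiguous
    per_pair[[sid]] <- am$stats$per_marker
  }
  list(reads = sorted,
       stats = list(n_in = dm$stats$n_in,
                    per_sample = dm$stats$per_sample,
                    per_pair = per_pair,
                    unassigned_barcode = dm$stats$unassigned,
                    ambiguous_barcode = dm$stats$ambiguous,
                    unassigned_marker = unassigned_marker,
                    ambiguous_marker = ambiguous_marker))
}

min_pairwise_distance <- function(keys) {
  n <- length(keys)
  if (n < 2L) return(Inf)
  d <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d <- min(d, hamming(keys[i], keys[j]))
  d
}

# accept a FASTQ/FASTA path, DNAStringSet or character vector
as_read_vector <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fasta|fa)(\\.gz)?$", reads)) "fasta" else "fastq"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (methods::is(reads, "DNAStringSet")) {
    out <- as.character(reads)
    names(out) <- sub(" .*", "", names(reads) %||% as.character(seq_along(out)))
    return(out)
  }
  if (is.null(names(reads))) names(reads) <- as.character(seq_along(reads))
  reads
}
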