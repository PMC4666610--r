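#' Adapter sequences for the two-round fusion-primer library build
#'
#' Defaults are the Ion Torrent sequences used throughout: the M13-derived
#' universal tail that links the two PCR rounds, the truncated P1/B adapter,
#' and the A adapter that precedes the sample barcode.
#'
#' @param m13_tail,trp1_adapter,ion_a_adapter DNA strings.
#' @return object of class `adapter_set`.
#' @export
adapter_set <- function(m13_tail = "GATGTAAAACGACGGCCAGTG",
                        trp1_adapter = "CCTCTCTATGGGCAGTCGGTGAT",
                        ion_a_adapter = "CCATCTCATCCCTGCGTGTCTCCGACTCAG") {
  m13_tail <- toupper(m13_tail)
  trp1_adapter <- toupper(trp1_adapter)
  ion_a_adapter <- toupper(ion_a_adapter)
  for (x in c(m13_tail, trp1_adapter, ion_a_adapter))
    if (!is_dna(x)) stop_validation("adapter is not a non-empty DNA string")
  structure(list(m13_tail = m13_tail, trp1_adapter = trp1_adapter,
                 ion_a_adapter = ion_a_adapter), class = "adapter_set")
}

#' First-round tailed PCR primers for a marker
#'
#' The first PCR uses the locus-specific primers tailed with universal
#' sequences: the forward primer gets the M13 tail at its 5' end (so barcoded
#' adapters can be added in the second round), the reverse primer gets the
#' truncated P1/B adapter. Pure concatenation; the locus primer is an exact
#' suffix of each product.
#'
#' @param marker an `amp_marker`.
#' @param adapters an [adapter_set()].
#' @return list with elements `forward` and `reverse`.
#' @export
build_pcr1_primers <- function(marker, adapters = adapter_set()) {
  if (!nzchar(marker$forward_primer) || !nzchar(marker$reverse_primer))
    stop_validation("empty locus primer")
  list(forward = paste0(adapters$m13_tail, marker$forward_primer),
       reverse = paste0(adapters$trp1_adapter, marker$reverse_primer))
}

#' Second-round barcoded forward fusion primer
#'
#' 5' to 3': Ion A adapter, the sample barcode (10-12 nt), then the M13 tail.
#' The shared second-round reverse primer is the truncated P1/B adapter
#' itself.
#'
#' @param barcode sample barcode, 10-12 nt.
#' @param adapters an [adapter_set()].
#' @return fusion primer string.
#' @export
build_pcr2_forward <- function(barcode, adapters = adapter_set()) {
  barcode <- toupper(barcode)
  if (!is_dna(barcode) || nchar(barcode) < 10 || nchar(barcode) > 12)
    stop_validation("barcode length outside [10,12]")
  paste0(adapters$ion_a_adapter, barcode, adapters$m13_tail)
}

#' Segment structure of a sequenced read
#'
#' After the instrument strips the A adapter (the default basecalling
#' behavior), a read runs 5' to 3' through: barcode, M13 tail, forward
#' primer, insert, reverse-complemented reverse primer, truncated P1/B
#' adapter. Dominant null-allele markers share the same layout; the null
#' manifests as absent reads, not a different structure. Both the simulator
#' and the read sorter use this to know what to emit and trim.
#'
#' @param marker an `amp_marker`.
#' @param barcode sample barcode.
#' @param adapters an [adapter_set()].
#' @return named character vector of the six segments in read order; the
#'   attribute `degenerate_insert` is TRUE when the insert is empty.
#' @export
expected_read_layout <- function(marker, barcode, adapters = adapter_set()) {
  barcode <- toupper(barcode)
  fp <- marker$forward_primer; rp <- marker$reverse_primer
  len <- nchar(marker$reference_amplicon)
  insert <- substr(marker$reference_amplicon, nchar(fp) + 1L, len - nchar(rp))
  out <- c(barcode = barcode,
           m13_tail = adapters$m13_tail,
           forward_primer = fp,
           insert = insert,
           reverse_primer_rc = revcomp(rp),
           trp1_adapter = adapters$trp1_adapter)
  attr(out, "degenerate_insert") <- !nzchar(insert)
  out
}

#' Fusion-primer order sheet for a panel
#'
#' One row per first-round primer (two per marker) and per second-round
#' barcoded forward primer (one per sample), plus the shared second-round
#' reverse primer.
#'
#' @param p an `amp_panel` (samples required for the second-round primers).
#' @param tsv_path optional path; when given the sheet is written as TSV.
#' @return data.frame with columns `name` and `sequence`.
#' @export
build_fusion_primers <- function(p, tsv_path = NULL) {
  rows <- list()
  for (m in p$markers) {
    pr <- build_pcr1_primers(m, p$adapters)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(m$marker_id, c("_PCR1_F", "_PCR1_R")),
      sequence = c(pr$forward, pr$reverse), stringsAsFactors = FALSE)
  }
  if (!is.null(p$samples)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(p$samples$sample_id, "_PCR2_F"),
      sequence = vapply(p$samples$barcode, build_pcr2_forward, "",
                        adapters = p$adapters),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = "PCR2_R", sequence = p$adapters$trp1_adapter, stringsAsFactors = FALSE)
  sheet <- do.call(rbind, rows)
  rownames(sheet) <- NULL
  if (!is.null(tsv_path))
    write.table(sheet, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet
}
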