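#' Construct a variant-site table for a marker
#'
#' Variant sites are annotated positions on the reference amplicon where the
#' favorable (trait-associated) base differs from the wild-type base.
#' Positions are 1-based on the full reference amplicon (which includes both
#' locus-specific primers) and must not fall inside either primer region.
#'
#' @param position integer vector, 1-based positions on the reference amplicon.
#' @param favorable_base,wild_type_base character vectors over A/C/G/T.
#' @param site_id optional site labels; default `S<position>`.
#' @param trait_label optional free-text gene/QTL labels.
#' @return data.frame with columns site_id, position, favorable_base,
#'   wild_type_base, trait_label.
#' @export
variant_sites <- function(position, favorable_base, wild_type_base,
                          site_id = paste0("S", position), trait_label = "") {
  df <- data.frame(site_id = as.character(site_id),
                   position = as.integer(position),
                   favorable_base = toupper(favorable_base),
                   wild_type_base = toupper(wild_type_base),
                   trait_label = trait_label,
                   stringsAsFactors = FALSE)
  if (any(is.na(df$position)) || any(df$position < 1L))
    stop_validation("position must be >=1")
  df
}

SPECIFICITY_COPIES <- c(genome_specific = 1L, semi_specific = 2L, non_specific = 3L)

#' Define an amplicon marker
#'
#' A marker is one locus-specific primer pair with its reference amplicon
#' (the known favorable accession's sequence, primer to primer) and its
#' annotated variant sites. The genome-specificity class records how many
#' wheat subgenomes the primer pair co-amplifies: a genome-specific pair
#' amplifies only the target genome, a semi-genome-specific pair co-amplifies
#' one homoeolog, and a non-genome-specific pair all three, which dilutes the
#' favorable-allele read fraction accordingly (see
#' [expected_allele_fraction()]).
#'
#' @param marker_id unique marker name.
#' @param forward_primer,reverse_primer locus-specific primers, 17-21 nt.
#' @param reference_amplicon reference amplicon sequence, 80-200 nt; must
#'   start with `forward_primer` and end with the reverse complement of
#'   `reverse_primer`.
#' @param sites a [variant_sites()] data.frame (may have zero rows for
#'   dominant null-allele markers with pure presence/absence semantics).
#' @param mode `"codominant"` (SNP read-fraction calling) or `"dominant_null"`
#'   (one allele yields no amplicon; absence of reads signals the null).
#' @param specificity `"genome_specific"`, `"semi_specific"` or
#'   `"non_specific"` (1, 2 or 3 co-amplified genomes).
#' @return object of class `amp_marker`.
#' @export
marker_definition <- function(marker_id, forward_primer, reverse_primer,
                              reference_amplicon,
                              sites = variant_sites(integer(), character(), character()),
                              mode = c("codominant", "dominant_null"),
                              specificity = c("genome_specific", "semi_specific",
                                              "non_specific")) {
  mode <- match.arg(mode)
  specificity <- match.arg(specificity)
  m <- structure(list(
    marker_id = as.character(marker_id),
    forward_primer = toupper(forward_primer),
    reverse_primer = toupper(reverse_primer),
    reference_amplicon = toupper(reference_amplicon),
    sites = sites,
    mode = mode,
    specificity = specificity,
    copies_coamplified = unname(SPECIFICITY_COPIES[[specificity]])
  ), class = "amp_marker")
  bad <- validate_marker(m)
  if (length(bad))
    stop_validation("marker '", m$marker_id, "': ", paste(bad, collapse = "; "))
  m
}

#' @export
print.amp_marker <- function(x, ...) {
  cat(sprintf("<amp_marker> %s: %s, %s (%d genome%s), %d nt amplicon, %d site%s\n",
              x$marker_id, x$mode, x$specificity, x$copies_coamplified,
              if (x$copies_coamplified > 1) "s" else "",
              nchar(x$reference_amplicon), nrow(x$sites),
              if (nrow(x$sites) == 1) "" else "s"))
  invisible(x)
}

# all invariant checks for one marker; returns character vector of findings
validate_marker <- function(m) {
  f <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) f <<- c(f, msg)
  chk(is_dna(m$forward_primer), "forward primer is not a DNA string")
  chk(is_dna(m$reverse_primer), "reverse primer is not a DNA string")
  chk(is_dna(m$reference_amplicon), "reference amplicon is not a DNA string")
  if (length(f)) return(f)
  chk(nchar(m$forward_primer) >= 17 && nchar(m$forward_primer) <= 21,
      "forward primer length outside [17,21]")
  chk(nchar(m$reverse_primer) >= 17 && nchar(m$reverse_primer) <= 21,
      "reverse primer length outside [17,21]")
  len <- nchar(m$reference_amplicon)
  chk(len >= 80 && len <= 200, "amplicon length outside [80,200]")
  chk(startsWith(m$reference_amplicon, m$forward_primer),
      "reference amplicon does not start with the forward primer")
  chk(endsWith(m$reference_amplicon, revcomp(m$reverse_primer)),
      "reference amplicon does not end with the reverse-complemented reverse primer")
  if (m$mode == "codominant")
    chk(nrow(m$sites) >= 1L, "codominant marker needs at least one variant site")
  if (nrow(m$sites)) {
    s <- m$sites
    chk(all(s$position >= 1L), "position must be >=1")
    chk(all(s$position <= len), "site position beyond amplicon end")
    chk(!anyDuplicated(s$position), "duplicate site positions")
    chk(all(s$favorable_base %in% DNA_BASES), "favorable base not in {A,C,G,T}")
    chk(all(s$wild_type_base %in% DNA_BASES), "wild-type base not in {A,C,G,T}")
    chk(all(s$favorable_base != s$wild_type_base),
        "favorable and wild-type base identical")
    fp <- nchar(m$forward_primer); rp <- nchar(m$reverse_primer)
    chk(all(s$position > fp & s$position <= len - rp),
        "site position inside a primer region")
  }
  f
}

#' Assemble a marker panel
#'
#' @param markers list of [marker_definition()] objects.
#' @param samples sample sheet data.frame (see [load_sample_sheet()]), or NULL.
#' @param adapters an [adapter_set()].
#' @return object of class `amp_panel`.
#' @export
panel <- function(markers, samples = NULL, adapters = adapter_set()) {
  if (inherits(markers, "amp_marker")) markers <- list(markers)
  names(markers) <- vapply(markers, `[[`, "", "marker_id")
  structure(list(markers = markers, samples = samples, adapters = adapters),
            class = "amp_panel")
}

#' @export
print.amp_panel <- function(x, ...) {
  cat(sprintf("<amp_panel> %d marker(s), %s sample(s)\n", length(x$markers),
              if (is.null(x$samples)) "no" else nrow(x$samples)))
  invisible(x)
}

marker_ids <- function(p) names(p$markers)

#' Validate a panel against all invariants
#'
#' Runs every marker-level and panel-level invariant and returns the findings
#' as data; an empty character vector means the panel is valid. Never mutates
#' or rejects its input, so it can be used as a pre-flight report.
#'
#' Panel-level checks: unique marker ids; forward-primer prefixes (M13 tail +
#' primer) pairwise distinguishable at the marker-assignment mismatch
#' tolerance (a primer that is within tolerance of another's prefix would
#' make read assignment systematically ambiguous); barcode separability at
#' the demultiplexing tolerance; control annotations referencing only known
#' markers.
#'
#' @param p an `amp_panel`.
#' @param max_primer_mismatch marker-assignment Hamming tolerance (default 2).
#' @param max_barcode_mismatch demultiplexing Hamming tolerance (default 1).
#' @return character vector of findings (empty when valid).
#' @export
validate_panel <- function(p, max_primer_mismatch = 2L, max_barcode_mismatch = 1L) {
  stopifnot(inherits(p, "amp_panel"))
  f <- character()
  for (m in p$markers) {
    mf <- validate_marker(m)
    if (length(mf)) f <- c(f, paste0("marker '", m$marker_id, "': ", mf))
  }
  ids <- vapply(p$markers, `[[`, "", "marker_id")
  if (anyDuplicated(ids))
    f <- c(f, paste0("duplicate marker_id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  # assignment prefixes must not collide within tolerance (prefix comparison)
  pref <- paste0(p$adapters$m13_tail, vapply(p$markers, `[[`, "", "forward_primer"))
  if (length(pref) > 1) {
    for (i in seq_len(length(pref) - 1)) for (j in (i + 1):length(pref)) {
      if (hamming(pref[i], pref[j]) <= max_primer_mismatch)
        f <- c(f, paste0("ambiguous primer pair: '", ids[i], "' vs '", ids[j], "'"))
    }
  }
  if (!is.null(p$samples)) {
    f <- c(f, validate_samples(p$samples, max_barcode_mismatch))
    ctl <- c(control_markers(p$samples$pos_control_for),
             control_markers(p$samples$neg_control_for))
    unknown <- setdiff(ctl, ids)
    if (length(unknown))
      f <- c(f, paste0("control list references unknown marker: ",
                       paste(unknown, collapse = ", ")))
  }
  f
}

control_markers <- function(x) {
  x <- x[!is.na(x) & nzchar(x) & x != "."]
  unique(unlist(strsplit(x, ",", fixed = TRUE)))
}

# sample-sheet invariant checks; findings as character vector
validate_samples <- function(s, max_barcode_mismatch = 1L) {
  f <- character()
  need <- c("sample_id", "barcode")
  miss <- setdiff(need, names(s))
  if (length(miss)) return(paste0("sample sheet missing column: ", miss))
  if (anyDuplicated(s$sample_id))
    f <- c(f, "duplicate sample_id in sample sheet")
  bad <- !vapply(s$barcode, is_dna, TRUE)
  if (any(bad))
    f <- c(f, paste0("barcode is not a DNA string: sample ", s$sample_id[bad]))
  ln <- nchar(s$barcode)
  if (any(ln < 10 | ln > 12))
    f <- c(f, paste0("barcode length outside [10,12]: sample ",
                     s$sample_id[ln < 10 | ln > 12]))
  n <- nrow(s)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- hamming(s$barcode[i], s$barcode[j])
      if (d <= max_barcode_mismatch)
        f <- c(f, sprintf("barcodes within tolerance (%d mismatches): '%s' vs '%s'",
                          d, s$sample_id[i], s$sample_id[j]))
    }
  }
  f
}

#' Read a marker panel from TSV + FASTA
#'
#' The TSV (tab-delimited, header row) needs columns `marker_id`,
#' `fwd_primer`, `rev_primer`, `mode`, `specificity` and `sites`; `sites`
#' holds comma-separated `pos:fav:wt[:site_id[:trait]]` triplets (empty or
#' `.` for a dominant marker without annotated sites). Reference amplicons
#' come from the FASTA, keyed by `marker_id`. All marker and panel invariants
#' are checked; any violation is an error naming the marker and rule.
#'
#' @param panel_tsv_path path to the panel TSV.
#' @param reference_fasta_path path to the reference-amplicon FASTA.
#' @param samples optional sample sheet to attach.
#' @param adapters an [adapter_set()].
#' @return a validated `amp_panel`.
#' @export
load_panel <- function(panel_tsv_path, reference_fasta_path, samples = NULL,
                       adapters = adapter_set()) {
  tab <- read.delim(panel_tsv_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("marker_id", "fwd_primer", "rev_primer", "mode", "specificity", "sites")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_validation("panel TSV missing column: ", paste(miss, collapse = ", "))
  refs <- Biostrings::readDNAStringSet(reference_fasta_path)
  miss_ref <- setdiff(tab$marker_id, names(refs))
  if (length(miss_ref))
    stop_validation("reference FASTA missing marker: ",
                    paste(miss_ref, collapse = ", "))
  if (anyDuplicated(tab$marker_id))
    stop_validation("duplicate marker_id: ",
                    paste(unique(tab$marker_id[duplicated(tab$marker_id)]),
                          collapse = ", "))
  markers <- lapply(seq_len(nrow(tab)), function(i) {
    marker_definition(
      marker_id = tab$marker_id[i],
      forward_primer = tab$fwd_primer[i],
      reverse_primer = tab$rev_primer[i],
      reference_amplicon = as.character(refs[[tab$marker_id[i]]]),
      sites = parse_sites(tab$sites[i]),
      mode = tab$mode[i],
      specificity = tab$specificity[i])
  })
  p <- panel(markers, samples = samples, adapters = adapters)
  f <- validate_panel(p)
  if (length(f)) stop_validation(paste(f, collapse = "; "))
  p
}

parse_sites <- function(x) {
  if (is.na(x) || !nzchar(x) || x == ".")
    return(variant_sites(integer(), character(), character()))
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) stop_validation("malformed site triplet (need pos:fav:wt): ", x)
  pos <- as.integer(vapply(parts, `[`, "", 1L))
  if (any(is.na(pos)) || any(pos < 1L)) stop_validation("position must be >=1")
  variant_sites(
    position = pos,
    favorable_base = vapply(parts, `[`, "", 2L),
    wild_type_base = vapply(parts, `[`, "", 3L),
    site_id = vapply(parts, function(p) if (length(p) >= 4) p[4] else paste0("S", p[1]), ""),
    trait_label = vapply(parts, function(p) if (length(p) >= 5) p[5] else "", ""))
}

format_sites <- function(s) {
  if (!nrow(s)) return(".")
  paste(sprintf("%d:%s:%s:%s:%s", s$position, s$favorable_base,
                s$wild_type_base, s$site_id, s$trait_label), collapse = ",")
}

#' Write a panel back to TSV + FASTA
#'
#' Inverse of [load_panel()]; a load-write-load round trip reproduces the
#' panel field by field.
#' @param p an `amp_panel`.
#' @param panel_tsv_path,reference_fasta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(p, panel_tsv_path, reference_fasta_path) {
  tab <- data.frame(
    marker_id = marker_ids(p),
    fwd_primer = vapply(p$markers, `[[`, "", "forward_primer"),
    rev_primer = vapply(p$markers, `[[`, "", "reverse_primer"),
    mode = vapply(p$markers, `[[`, "", "mode"),
    specificity = vapply(p$markers, `[[`, "", "specificity"),
    sites = vapply(p$markers, function(m) format_sites(m$sites), ""),
    stringsAsFactors = FALSE)
  write.table(tab, panel_tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  refs <- Biostrings::DNAStringSet(
    setNames(vapply(p$markers, `[[`, "", "reference_amplicon"), marker_ids(p)))
  Biostrings::writeXStringSet(refs, reference_fasta_path)
  invisible(c(panel_tsv_path, reference_fasta_path))
}

#' Read a sample sheet (sample-to-barcode mapping)
#'
#' TSV with columns `sample_id`, `barcode`, and optionally `pos_control_for`
#' and `neg_control_for` (comma-separated marker ids, empty or `.` for none).
#' Barcodes must be 10-12 nt and pairwise Hamming-separable at the
#' demultiplexing tolerance; a colliding pair is an error naming both
#' samples.
#'
#' @param tsv_path path to the TSV.
#' @param max_barcode_mismatch demultiplexing tolerance the barcodes must
#'   tolerate (default 1 mismatch).
#' @return data.frame with columns sample_id, barcode, pos_control_for,
#'   neg_control_for.
#' @export
load_sample_sheet <- function(tsv_path, max_barcode_mismatch = 1L) {
  s <- read.delim(tsv_path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("sample_id", "barcode"), names(s))
  if (length(miss))
    stop_validation("sample sheet missing column: ", paste(miss, collapse = ", "))
  if (is.null(s$pos_control_for)) s$pos_control_for <- ""
  if (is.null(s$neg_control_for)) s$neg_control_for <- ""
  s$pos_control_for[s$pos_control_for == "."] <- ""
  s$neg_control_for[s$neg_control_for == "."] <- ""
  s$barcode <- toupper(s$barcode)
  f <- validate_samples(s, max_barcode_mismatch)
  if (length(f)) stop_validation(paste(f, collapse = "; "))
  s
}

#' Write a sample sheet TSV
#' @param s sample sheet data.frame.
#' @param tsv_path output path.
#' @export
write_sample_sheet <- function(s, tsv_path) {
  out <- s[, c("sample_id", "barcode", "pos_control_for", "neg_control_for")]
  out$pos_control_for[!nzchar(out$pos_control_for)] <- "."
  out$neg_control_for[!nzchar(out$neg_control_for)] <- "."
  write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

# sample ids flagged as positive controls for a marker
positive_controls_for <- function(samples, marker_id) {
  hit <- vapply(samples$pos_control_for, function(x)
    marker_id %in% control_markers(x), TRUE)
  samples$sample_id[hit]
}
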