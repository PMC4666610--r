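#' Expected favorable-allele read percentage under homoeolog co-amplification
#'
#' In a polyploid, a primer pair that is not genome-specific co-amplifies the
#' homoeologous copies along with the target locus, so favorable-allele reads
#' are diluted by wild-type reads from the other subgenomes. Assuming equal
#' amplification of all templates, the expected percentage of
#' favorable-allele reads is `100 * a / (2c)`, where `a` is the number of
#' favorable alleles across the `2c` allele slots of the `c` co-amplified
#' diploid genomes. Genotypes use the two-letter convention `A` = favorable
#' allele, `T` = wild type: a genome-specific marker gives 100/50/0 for
#' AA/AT/TT, a semi-genome-specific one (wild-type homoeolog co-amplified)
#' 50/25/0, and a non-genome-specific one 100/3, 100/6, 0 -- printed as
#' 33/16/0 when truncated to integers.
#'
#' @param genotypes_per_genome character vector of length 1-3, one diploid
#'   genotype per co-amplified genome, each in `AA`, `AT`, `TA`, `TT`.
#' @return expected percentage in \[0, 100\], exact (e.g. `100/6` for
#'   `c("AT","TT","TT")`, not a truncated 16).
#' @examples
#' expected_allele_fraction("AA")               # 100
#' expected_allele_fraction(c("AA", "TT"))      # 50
#' expected_allele_fraction(c("AT", "TT", "TT"))# 16.666...
#' @export
expected_allele_fraction <- function(genotypes_per_genome) {
  g <- toupper(genotypes_per_genome)
  if (length(g) < 1L) stop_validation("need at least one co-amplified genome")
  if (length(g) > 3L) stop_validation("at most three co-amplified genomes")
  if (!all(g %in% c("AA", "AT", "TA", "TT")))
    stop_validation("genotypes must be AA, AT, TA or TT (A = favorable allele)")
  n_fav <- sum(vapply(strsplit(g, ""), function(x) sum(x == "A"), 0L))
  100 * n_fav / (2 * length(g))
}

#' Generate a random but valid sample sheet
#'
#' Barcodes are 10-12 nt with pairwise Hamming distance >= 3 (over the
#' shorter length), so single-mismatch demultiplexing is unambiguous. The
#' first `n_pos_controls` samples are named `PC*` and the next
#' `n_neg_controls` are `NC*`; [make_default_panel()] annotates those as
#' positive/negative controls for every marker (control-anchored calling
#' needs in-run controls).
#'
#' @param n_samples total samples including controls.
#' @param seed integer seed.
#' @param n_pos_controls,n_neg_controls how many leading samples are controls.
#' @return sample sheet data.frame.
#' @export
make_default_samples <- function(n_samples = 24L, seed = 1L,
                                 n_pos_controls = 3L, n_neg_controls = 1L) {
  stopifnot(n_samples >= n_pos_controls + n_neg_controls)
  set.seed(seed)
  barcodes <- character(0)
  while (length(barcodes) < n_samples) {
    b <- random_dna(sample(10:12, 1L))
    ok <- all(vapply(barcodes, function(x) hamming(x, b) >= 3L, TRUE))
    if (ok) barcodes <- c(barcodes, b)
  }
  ids <- c(sprintf("PC%d", seq_len(n_pos_controls)),
           sprintf("NC%d", seq_len(n_neg_controls)),
           sprintf("S%02d", seq_len(n_samples - n_pos_controls - n_neg_controls)))
  data.frame(sample_id = ids, barcode = barcodes,
             pos_control_for = "", neg_control_for = "",
             stringsAsFactors = FALSE)
}

#' Generate a random but valid marker panel
#'
#' Markers have 17-21 nt primers and 80-200 nt reference amplicons (the
#' optimum near 150), 1-3 annotated variant sites each, and cycle through the
#' three genome-specificity classes. Every fifth marker is a dominant
#' null-allele marker (presence/absence, genome-specific). The reference
#' amplicon is the favorable accession's sequence, so the favorable base at
#' each site is the reference base. Deterministic under `seed`.
#'
#' @param n_markers number of markers (>= 1).
#' @param seed integer seed.
#' @param n_samples samples for the attached sample sheet (0 for none).
#' @param adapters an [adapter_set()].
#' @return a validated `amp_panel`.
#' @export
make_default_panel <- function(n_markers, seed = 1L, n_samples = 24L,
                               adapters = adapter_set()) {
  stopifnot(n_markers >= 1L)
  set.seed(seed)
  specs <- c("genome_specific", "semi_specific", "non_specific")
  markers <- vector("list", n_markers)
  for (i in seq_len(n_markers)) {
    dominant <- (i %% 5L == 0L)
    fp <- random_dna(sample(17:21, 1L))
    rp <- random_dna(sample(17:21, 1L))
    total_len <- sample(120:200, 1L)
    insert_len <- total_len - nchar(fp) - nchar(rp)
    insert <- random_dna(insert_len)
    ref <- paste0(fp, insert, revcomp(rp))
    n_sites <- if (dominant) 1L else sample(1:3, 1L)
    pos <- sort(sample(seq(nchar(fp) + 5L, total_len - nchar(rp) - 4L), n_sites))
    fav <- substring(ref, pos, pos)
    wt <- vapply(fav, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    markers[[i]] <- marker_definition(
      marker_id = sprintf("M%02d", i),
      forward_primer = fp, reverse_primer = rp, reference_amplicon = ref,
      sites = variant_sites(pos, fav, wt),
      mode = if (dominant) "dominant_null" else "codominant",
      specificity = if (dominant) "genome_specific" else specs[(i - 1L) %% 3L + 1L])
  }
  samples <- if (n_samples > 0L) {
    s <- make_default_samples(n_samples, seed = seed + 1L)
    all_ids <- paste(vapply(markers, `[[`, "", "marker_id"), collapse = ",")
    s$pos_control_for <- ifelse(startsWith(s$sample_id, "PC"), all_ids, "")
    s$neg_control_for <- ifelse(startsWith(s$sample_id, "NC"), all_ids, "")
    s
  } else NULL
  p <- panel(markers, samples = samples, adapters = adapters)
  f <- validate_panel(p)
  if (length(f)) stop("default panel generation failed: ",
                      paste(f, collapse = "; "))
  p
}

#' Generate a ground-truth genotype table for a simulation
#'
#' One row per (sample, marker). Codominant markers get a comma-joined
#' per-genome genotype string (`A` = favorable, `T` = wild type; genome 1 is
#' the target, co-amplified homoeologs are wild type), dominant null-allele
#' markers get `present` or `null`. Positive-control samples are forced
#' homozygous favorable / present; negative controls homozygous wild type /
#' null; other samples are drawn at random. The default draws only
#' homozygous target genotypes, matching inbred line panels; set `het_prob`
#' above zero to include heterozygotes.
#'
#' @param p an `amp_panel` with samples.
#' @param seed integer seed.
#' @param het_prob probability a non-control codominant genotype is
#'   heterozygous (default 0).
#' @return data.frame with columns sample_id, marker_id, genotype.
#' @export
make_truth <- function(p, seed = 1L, het_prob = 0) {
  stopifnot(inherits(p, "amp_panel"), !is.null(p$samples))
  set.seed(seed)
  rows <- list()
  for (m in p$markers) {
    pc <- positive_controls_for(p$samples, m$marker_id)
    nc <- p$samples$sample_id[vapply(p$samples$neg_control_for, function(x)
      m$marker_id %in% control_markers(x), TRUE)]
    for (sid in p$samples$sample_id) {
      g <- if (m$mode == "dominant_null") {
        if (sid %in% pc) "present"
        else if (sid %in% nc) "null"
        else sample(c("present", "null"), 1L)
      } else {
        target <- if (sid %in% pc) "AA"
        else if (sid %in% nc) "TT"
        else if (runif(1) < het_prob) "AT"
        else sample(c("AA", "TT"), 1L)
        paste(c(target, rep("TT", m$copies_coamplified - 1L)), collapse = ",")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, marker_id = m$marker_id, genotype = g,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Define a simulation scenario
#'
#' Bundles the panel, per-pair ground truth and the generative parameters.
#' Defaults emulate a realistic multiplexed amplicon run: mean depth 800
#' reads per sample-marker pair with negative-binomial overdispersion
#' (per-marker depth in real runs spans orders of magnitude), substitution
#' error 0.5%, 2% fixed homoeolog divergence at non-site positions, and a 3%
#' spike of unrelated contaminant reads without valid barcode or primer
#' structure.
#'
#' @param p an `amp_panel` with samples.
#' @param truth truth table from [make_truth()]; generated from `seed` when
#'   NULL.
#' @param reads_per_marker mean depth per (sample, marker); scalar or vector
#'   recycled over markers (to emulate tiered primer pooling).
#' @param depth_dispersion negative-binomial size parameter; larger is less
#'   overdispersed, `Inf` fixes every pair's depth at the mean exactly.
#' @param substitution_error_rate per-base substitution probability in [0,1].
#' @param homoeolog_divergence per-base substitution rate distinguishing
#'   non-target homoeolog templates from the reference (fixed per genome, not
#'   per read).
#' @param contaminant_fraction fraction of total reads that are unrelated
#'   contaminants.
#' @param null_samples optional data.frame (sample_id, marker_id) of pairs
#'   forced to zero reads, emulating PCR failure.
#' @param seed integer seed fixing all randomness.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(p, truth = NULL, reads_per_marker = 800,
                         depth_dispersion = 5, substitution_error_rate = 0.005,
                         homoeolog_divergence = 0.02,
                         contaminant_fraction = 0.03,
                         null_samples = NULL, seed = 1L) {
  stopifnot(inherits(p, "amp_panel"), !is.null(p$samples))
  for (r in c(substitution_error_rate, homoeolog_divergence, contaminant_fraction))
    if (r < 0 || r > 1) stop_validation("rates must be in [0,1]")
  if (any(reads_per_marker < 0)) stop_validation("depth must be >= 0")
  if (is.null(truth)) truth <- make_truth(p, seed = seed)
  structure(list(panel = p, truth = truth,
                 reads_per_marker = rep_len(reads_per_marker, length(p$markers)),
                 depth_dispersion = depth_dispersion,
                 substitution_error_rate = substitution_error_rate,
                 homoeolog_divergence = homoeolog_divergence,
                 contaminant_fraction = contaminant_fraction,
                 null_samples = null_samples,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# allele-resolved template sequences for one marker: 2c haplotypes given the
# per-genome genotype vector and the (fixed) homoeolog background sequences
marker_templates <- function(m, genome_seqs, genotypes) {
  out <- character(0)
  for (k in seq_along(genotypes)) {
    alleles <- strsplit(genotypes[[k]], "")[[1]]
    for (a in alleles) {
      tmpl <- genome_seqs[[k]]
      for (r in seq_len(nrow(m$sites))) {
        base <- if (a == "A") m$sites$favorable_base[r] else m$sites$wild_type_base[r]
        substr(tmpl, m$sites$position[r], m$sites$position[r]) <- base
      }
      out <- c(out, tmpl)
    }
  }
  out
}

# fixed homoeolog backgrounds: genome 1 = reference; genomes 2..c diverge at
# non-site, non-primer positions at the configured rate
homoeolog_backgrounds <- function(m, divergence) {
  c_copies <- m$copies_coamplified
  len <- nchar(m$reference_amplicon)
  fp <- nchar(m$forward_primer); rp <- nchar(m$reverse_primer)
  free <- setdiff(seq(fp + 1L, len - rp), m$sites$position)
  seqs <- rep(m$reference_amplicon, c_copies)
  if (c_copies > 1L && divergence > 0) {
    for (k in 2:c_copies) {
      n_sub <- rbinom(1L, length(free), divergence)
      if (n_sub > 0L) {
        pos <- sample(free, n_sub)
        for (pp in pos) {
          old <- substr(seqs[[k]], pp, pp)
          substr(seqs[[k]], pp, pp) <- sample(setdiff(DNA_BASES, old), 1L)
        }
      }
    }
  }
  seqs
}

# expected categorical call for a truth genotype
truth_call <- function(mode, genotype) {
  if (mode == "dominant_null")
    return(if (genotype == "null") "null_allele_putative" else "homozygous_positive")
  target <- strsplit(genotype, ",", fixed = TRUE)[[1]][1]
  switch(target, AA = "homozygous_positive", TT = "homozygous_negative",
         "heterozygous")
}

#' Simulate a multiplexed amplicon sequencing run
#'
#' Emits a 4-line FASTQ (constant Q30 qualities) whose reads follow the
#' sequenced-library layout ([expected_read_layout()]): barcode, M13 tail,
#' forward primer, allele-resolved insert, reverse-complemented reverse
#' primer, P1/B adapter. Per (sample, marker), the read count is drawn
#' negative-binomially around the configured mean; each read's template is
#' drawn uniformly from the 2c haplotypes of the c co-amplified genomes;
#' substitution errors are applied i.i.d. at the configured rate over the
#' whole read. Dominant-null `null` genotypes and `null_samples` pairs emit
#' zero reads. Contaminant reads are random DNA with no valid structure.
#' Deterministic under the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @param fastq output FASTQ path.
#' @return object of class `sim_result`: list with `fastq` (path), `truth`
#'   (per sample-marker-site: genotype, expected favorable fraction, expected
#'   call), `emitted` (per-pair structured read counts), `n_contaminant`, and
#'   `n_total`.
#' @export
simulate_reads <- function(scenario, fastq = tempfile(fileext = ".fastq")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p <- scenario$panel
  set.seed(scenario$seed)

  null_key <- character(0)
  if (!is.null(scenario$null_samples))
    null_key <- paste(scenario$null_samples$sample_id,
                      scenario$null_samples$marker_id)

  truth <- scenario$truth
  truth_key <- setNames(truth$genotype, paste(truth$sample_id, truth$marker_id))
  barcodes <- setNames(p$samples$barcode, p$samples$sample_id)

  seqs <- character(0)
  emitted <- list()
  truth_rows <- list()
  for (mi in seq_along(p$markers)) {
    m <- p$markers[[mi]]
    backgrounds <- homoeolog_backgrounds(m, scenario$homoeolog_divergence)
    mu <- scenario$reads_per_marker[[mi]]
    for (sid in p$samples$sample_id) {
      g <- unname(truth_key[paste(sid, m$marker_id)])
      if (is.na(g))
        stop_validation("truth table has no genotype for pair ", sid, " / ",
                        m$marker_id)
      is_null <- (m$mode == "dominant_null" && g == "null") ||
        (paste(sid, m$marker_id) %in% null_key)
      d <- if (is_null) 0L
      else if (is.infinite(scenario$depth_dispersion)) as.integer(round(mu))
      else as.integer(rnbinom(1L, size = scenario$depth_dispersion, mu = mu))
      if (d > 0L) {
        genotypes <- if (m$mode == "dominant_null")
          rep("AA", m$copies_coamplified)
        else strsplit(g, ",", fixed = TRUE)[[1]]
        tmpl <- marker_templates(m, backgrounds, genotypes)
        pick <- sample.int(length(tmpl), d, replace = TRUE)
        seqs <- c(seqs, paste0(barcodes[[sid]], p$adapters$m13_tail,
                               tmpl[pick], p$adapters$trp1_adapter))
      }
      emitted[[length(emitted) + 1L]] <- data.frame(
        sample_id = sid, marker_id = m$marker_id, n_reads = d,
        stringsAsFactors = FALSE)
      frac <- if (m$mode == "dominant_null" || g %in% c("null", "present")) NA_real_
      else expected_allele_fraction(strsplit(g, ",", fixed = TRUE)[[1]])
      if (nrow(m$sites)) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sample_id = sid, marker_id = m$marker_id, site_id = m$sites$site_id,
          genotype = g, expected_fraction = frac,
          expected_call = truth_call(m$mode, g), stringsAsFactors = FALSE)
      }
    }
  }
  seqs <- apply_substitution_errors(seqs, scenario$substitution_error_rate)

  n_struct <- length(seqs)
  n_cont <- if (scenario$contaminant_fraction > 0)
    as.integer(round(scenario$contaminant_fraction /
                       (1 - scenario$contaminant_fraction) * n_struct)) else 0L
  if (n_cont > 0L)
    seqs <- c(seqs, vapply(sample(100:250, n_cont, replace = TRUE), random_dna, ""))

  ord <- sample.int(length(seqs))
  seqs <- seqs[ord]
  names(seqs) <- sprintf("sim_%06d", seq_along(seqs))
  dna <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(strrep("?", nchar(seqs)))  # constant Q30
  Biostrings::writeXStringSet(dna, fastq, format = "fastq", qualities = qual)

  structure(list(fastq = fastq,
                 truth = do.call(rbind, truth_rows),
                 emitted = do.call(rbind, emitted),
                 n_contaminant = n_cont,
                 n_total = length(seqs)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d reads (%d structured + %d contaminant) -> %s\n",
              x$n_total, sum(x$emitted$n_reads), x$n_contaminant, x$fastq))
  invisible(x)
}
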