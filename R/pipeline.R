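#' Run the full genotyping pipeline
#'
#' Executes the four analysis steps over a multiplexed amplicon FASTQ:
#' barcode demultiplexing into samples, forward-primer subdivision into
#' markers, alignment of each insert to its marker's reference with per-site
#' base extraction, and allele counting with control-anchored genotype
#' calling. Deterministic: a rerun on identical inputs reproduces the call
#' table byte for byte.
#'
#' When `outdir` is given, the run writes `allele_counts.tsv`,
#' `genotype_calls.tsv`, `cutoffs.tsv`, `call_rates.tsv`, `run_report.json`
#' and `run_report.txt`.
#'
#' @param fastq FASTQ path (gzip transparent), `DNAStringSet`, or named
#'   character vector of reads.
#' @param p an `amp_panel`; needs samples unless `samples` is given.
#' @param samples optional sample sheet to attach to the panel.
#' @param outdir optional output directory (created if missing).
#' @param max_barcode_mismatch,max_primer_mismatch sorting tolerances.
#' @param align an [align_params()].
#' @param calling a [calling_config()].
#' @param min_mean_quality when > 0 and `fastq` is a file, drop reads whose
#'   mean Phred quality is below this (off by default; simulated and
#'   instrument-filtered data are typically pre-filtered).
#' @return object of class `amplicall_run`: counts, cutoffs, calls,
#'   call_rates, stats, config.
#' @export
run_pipeline <- function(fastq, p, samples = NULL, outdir = NULL,
                         max_barcode_mismatch = 1L, max_primer_mismatch = 2L,
                         align = align_params(), calling = calling_config(),
                         min_mean_quality = 0) {
  if (!is.null(samples)) p$samples <- samples
  if (is.null(p$samples)) stop_validation("panel has no sample sheet")
  findings <- validate_panel(p, max_primer_mismatch, max_barcode_mismatch)
  if (length(findings))
    stop_validation("panel validation failed: ", paste(findings, collapse = "; "))

  reads <- load_reads(fastq, min_mean_quality)
  sorted <- sort_reads(reads, p, max_barcode_mismatch, max_primer_mismatch)

  obs <- list()
  n_rejected <- 0L
  for (sid in names(sorted$reads)) {
    for (mid in names(sorted$reads[[sid]])) {
      o <- observe_sites(sorted$reads[[sid]][[mid]], p$markers[[mid]], align)
      n_rejected <- n_rejected + attr(o, "n_rejected")
      if (nrow(o)) {
        o$sample_id <- sid; o$marker_id <- mid
        obs[[length(obs) + 1L]] <- o
      }
    }
  }
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(sample_id = character(), marker_id = character(),
               site_id = character(), observed = character(),
               stringsAsFactors = FALSE)
  counts <- count_alleles(observations, p)
  cutoffs <- derive_cutoffs(counts, p, calling)
  calls <- call_genotypes(counts, cutoffs, p, calling)
  rates <- call_rate(calls)

  stats <- c(sorted$stats, list(alignment_rejected = n_rejected))
  run <- structure(list(counts = counts, cutoffs = cutoffs, calls = calls,
                        call_rates = rates, stats = stats,
                        config = list(max_barcode_mismatch = max_barcode_mismatch,
                                      max_primer_mismatch = max_primer_mismatch,
                                      align = unclass(align),
                                      calling = unclass(calling),
                                      min_mean_quality = min_mean_quality)),
                   class = "amplicall_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

load_reads <- function(fastq, min_mean_quality = 0) {
  if (min_mean_quality > 0 && is.character(fastq) && length(fastq) == 1L &&
      file.exists(fastq)) {
    q <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
    mq <- vapply(as(Biostrings::quality(q), "IntegerList"), mean, 0)
    keep <- mq >= min_mean_quality
    out <- as.character(q)[keep]
    names(out) <- sub(" .*", "", names(q)[keep])
    return(out)
  }
  as_read_vector(fastq)
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(run$counts, "allele_counts.tsv")
  calls <- run$calls
  calls$percent_favorable <- ifelse(is.na(calls$percent_favorable), "",
                                    sprintf("%.1f", calls$percent_favorable))
  wt(calls, "genotype_calls.tsv")
  wt(run$cutoffs, "cutoffs.tsv")
  wt(run$call_rates, "call_rates.tsv")
  report <- list(config = run$config,
                 stats = run$stats[setdiff(names(run$stats), "per_pair")],
                 call_rates = run$call_rates)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(sprintf("reads in:             %d", run$stats$n_in),
           sprintf("unassigned barcode:   %d", run$stats$unassigned_barcode),
           sprintf("ambiguous barcode:    %d", run$stats$ambiguous_barcode),
           sprintf("unassigned marker:    %d", run$stats$unassigned_marker),
           sprintf("ambiguous marker:     %d", run$stats$ambiguous_marker),
           sprintf("alignment rejected:   %d", run$stats$alignment_rejected),
           "",
           sprintf("%-12s call rate %6.1f%%", run$call_rates$marker_id,
                   run$call_rates$call_rate_percent))
  writeLines(txt, file.path(outdir, "run_report.txt"))
  invisible(outdir)
}

#' @export
print.amplicall_run <- function(x, ...) {
  cat(sprintf("<amplicall_run> %d reads in; %d calls over %d markers\n",
              x$stats$n_in, nrow(x$calls), nrow(x$call_rates)))
  cat(sprintf("  unassigned barcode %d | unassigned marker %d | alignment rejected %d\n",
              x$stats$unassigned_barcode, x$stats$unassigned_marker,
              x$stats$alignment_rejected))
  conf <- x$calls[!is_no_call(x$calls$call), "call"]
  tb <- table(conf)
  cat("  calls:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.amplicall_run <- function(object, ...) {
  print(object)
  cat("\nPer-marker call rates:\n")
  print(object$call_rates, row.names = FALSE)
  invisible(object)
}
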