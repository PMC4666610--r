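#' Genotype-calling configuration
#'
#' `min_reads_per_allele` is the minimum accepted read depth at a site for a
#' confident call (default 10; below it calls are `no_call_low_depth`, since
#' sampling bias at lower depth produces false positives).
#' `cutoff_guard_sd` widens the positive-control cutoff downward by that many
#' binomial standard errors of the cutoff percentage at the sample's own
#' depth (never below half the cutoff): the control cutoff estimates the
#' positive class's own read fraction, so a sample drawn from the same
#' binomial would otherwise fall below it about half the time. Set it to 0
#' for the strict literal rule. A percentage exactly equal to the raw cutoff
#' always calls positive ("equal to or greater").
#'
#' Heterozygote calling is off by default: in a polyploid background the
#' het/hom read-fraction separation is compressed, and a het band should be
#' anchored on a synthetic heterozygote control (an equal mix of favorable
#' and wild-type DNA). When enabled, a percentage inside `het_band` calls
#' `heterozygous`.
#'
#' @param min_reads_per_allele minimum accepted reads at a site (>= 1).
#' @param het_calling_enabled logical, default FALSE.
#' @param het_band numeric length-2 percent interval, used only when enabled.
#' @param cutoff_guard_sd binomial-SE guard band multiplier (default 4).
#' @return object of class `calling_config`.
#' @export
calling_config <- function(min_reads_per_allele = 10L,
                           het_calling_enabled = FALSE,
                           het_band = c(NA_real_, NA_real_),
                           cutoff_guard_sd = 4) {
  stopifnot(min_reads_per_allele >= 1L, cutoff_guard_sd >= 0)
  if (het_calling_enabled && any(is.na(het_band)))
    stop_validation("het calling requires an explicit het_band interval")
  structure(list(min_reads_per_allele = as.integer(min_reads_per_allele),
                 het_calling_enabled = het_calling_enabled,
                 het_band = het_band,
                 cutoff_guard_sd = cutoff_guard_sd),
            class = "calling_config")
}

BASE_COLS <- c("n_A", "n_C", "n_G", "n_T", "n_N")

#' Tabulate per-site allele counts
#'
#' Exact tabulation of site observations into A/C/G/T/N counts per
#' (sample, marker, site). When the panel (with samples) is supplied, every
#' expected key appears even with zero observations, so downstream
#' null-allele logic can see absent reads.
#'
#' @param observations data.frame with columns sample_id, marker_id,
#'   site_id, observed (from [observe_sites()], tagged with sample/marker).
#' @param p optional `amp_panel` with samples, for zero-filling.
#' @return data.frame of class `allele_counts` with columns sample_id,
#'   marker_id, site_id, n_A, n_C, n_G, n_T, n_N, total.
#' @export
count_alleles <- function(observations, p = NULL) {
  if (nrow(observations)) {
    key <- paste(observations$sample_id, observations$marker_id,
                 observations$site_id, sep = "\r")
    tab <- table(key, factor(observations$observed, levels = c(DNA_BASES, "N")))
    parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
    counts <- data.frame(sample_id = parts[, 1L], marker_id = parts[, 2L],
                         site_id = parts[, 3L], stringsAsFactors = FALSE)
    counts[BASE_COLS] <- as.data.frame.matrix(unclass(tab))
  } else {
    counts <- data.frame(sample_id = character(), marker_id = character(),
                         site_id = character(), stringsAsFactors = FALSE)
    counts[BASE_COLS] <- rep(list(integer()), 5L)
  }
  if (!is.null(p)) {
    grid <- do.call(rbind, lapply(p$markers, function(m) {
      if (!nrow(m$sites)) return(NULL)
      expand.grid(sample_id = p$samples$sample_id, marker_id = m$marker_id,
                  site_id = m$sites$site_id, stringsAsFactors = FALSE)
    }))
    have <- paste(counts$sample_id, counts$marker_id, counts$site_id, sep = "\r")
    want <- paste(grid$sample_id, grid$marker_id, grid$site_id, sep = "\r")
    missing <- grid[!(want %in% have), , drop = FALSE]
    if (nrow(missing)) {
      missing[BASE_COLS] <- 0L
      counts <- rbind(counts, missing)
    }
    counts <- counts[counts$marker_id %in% marker_ids(p), , drop = FALSE]
  }
  counts$total <- rowSums(counts[BASE_COLS])
  counts <- counts[order(counts$marker_id, counts$site_id, counts$sample_id), ]
  rownames(counts) <- NULL
  class(counts) <- c("allele_counts", "data.frame")
  counts
}

#' Percent favorable-allele reads
#'
#' `100 * n_favorable / total`, full precision. Undefined (NA) when no reads
#' were observed; callers must handle that explicitly rather than read it as
#' zero.
#'
#' @param counts named numeric vector with elements `n_A`, `n_C`, `n_G`,
#'   `n_T`, `n_N` (a row of an `allele_counts` table works).
#' @param favorable_base one of A/C/G/T.
#' @return percentage in \[0, 100\], or NA when total is 0.
#' @export
percent_favorable <- function(counts, favorable_base) {
  counts <- unlist(counts[BASE_COLS])
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  100 * counts[[paste0("n_", favorable_base)]] / total
}

# vectorized percent + favorable-base annotation over a counts table
add_percent <- function(counts, p) {
  fav <- do.call(c, unname(lapply(p$markers, function(m)
    setNames(m$sites$favorable_base,
             paste(m$marker_id, m$sites$site_id, sep = "\r")))))
  counts$favorable_base <- fav[paste(counts$marker_id, counts$site_id, sep = "\r")]
  m <- as.matrix(counts[BASE_COLS])
  counts$n_favorable <- m[cbind(seq_len(nrow(counts)),
                                match(paste0("n_", counts$favorable_base),
                                      BASE_COLS))]
  counts$percent_favorable <- ifelse(counts$total > 0,
                                     100 * counts$n_favorable / counts$total,
                                     NA_real_)
  counts
}

#' Derive per-site cutoffs from in-run positive controls
#'
#' For each (marker, site), the cutoff is the minimum percent favorable
#' reads among the run's qualifying positive-control replicates (controls
#' with depth at or above the minimum read cutoff). Controls must be part of
#' the same run; a marker without a qualifying control gets no cutoff, and
#' downstream codominant calls become `no_call_no_control`.
#'
#' @param counts an `allele_counts` table.
#' @param p an `amp_panel` with control-annotated samples.
#' @param config a [calling_config()].
#' @return data.frame with columns marker_id, site_id, cutoff_percent,
#'   n_controls, control_samples.
#' @export
derive_cutoffs <- function(counts, p, config = calling_config()) {
  counts <- add_percent(counts, p)
  rows <- list()
  for (m in p$markers) {
    pc <- positive_controls_for(p$samples, m$marker_id)
    for (r in seq_len(nrow(m$sites))) {
      sel <- counts$marker_id == m$marker_id &
        counts$site_id == m$sites$site_id[r] &
        counts$sample_id %in% pc &
        counts$total >= config$min_reads_per_allele
      q <- counts[sel, , drop = FALSE]
      if (nrow(q)) {
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = m$marker_id, site_id = m$sites$site_id[r],
          cutoff_percent = min(q$percent_favorable),
          n_controls = nrow(q),
          control_samples = paste(q$sample_id, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(marker_id = character(), site_id = character(),
                      cutoff_percent = numeric(), n_controls = integer(),
                      control_samples = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# effective threshold after the depth-aware guard band; monotone
# nondecreasing in the cutoff and never above it. The proportion is shrunk
# toward 1/2 by one pseudo-observation so the SE stays positive at 0/100%
effective_threshold <- function(cutoff, depth, guard_sd) {
  d <- pmax(depth, 1)
  p <- (cutoff / 100 * d + 1) / (d + 2)
  se <- 100 * sqrt(p * (1 - p) / d)
  pmax(cutoff - guard_sd * se, cutoff / 2)
}

#' Call genotypes from allele counts and control cutoffs
#'
#' Codominant markers: a site with depth below the minimum read cutoff is
#' `no_call_low_depth`; with no in-run control cutoff, `no_call_no_control`;
#' otherwise the percent favorable reads is compared to the control-anchored
#' threshold -- at or above calls `homozygous_positive`, below calls
#' `homozygous_negative` (see [calling_config()] for the guard band; equality
#' with the raw cutoff always calls positive). Dominant null-allele markers
#' are presence/absence: depth at or above the minimum calls
#' `homozygous_positive`, exactly zero reads calls `null_allele_putative`
#' with a caution flag (a true null is indistinguishable from PCR failure),
#' and anything between is `no_call_low_depth`. A dominant marker never
#' yields `homozygous_negative`.
#'
#' @param counts an `allele_counts` table.
#' @param cutoffs from [derive_cutoffs()].
#' @param p an `amp_panel`.
#' @param config a [calling_config()].
#' @return data.frame of class `genotype_calls`: sample_id, marker_id,
#'   site_id, depth, percent_favorable, call, caution_flag, reason.
#' @export
call_genotypes <- function(counts, cutoffs, p, config = calling_config()) {
  counts <- add_percent(counts, p)
  mode <- setNames(vapply(p$markers, `[[`, "", "mode"), marker_ids(p))
  ckey <- setNames(cutoffs$cutoff_percent,
                   paste(cutoffs$marker_id, cutoffs$site_id, sep = "\r"))
  n <- nrow(counts)
  call <- character(n); caution <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    md <- mode[[counts$marker_id[i]]]
    depth <- counts$total[i]
    if (md == "dominant_null") {
      if (depth >= config$min_reads_per_allele) {
        call[i] <- "homozygous_positive"
      } else if (depth == 0L) {
        call[i] <- "null_allele_putative"; caution[i] <- TRUE
        reason[i] <- "zero reads: null allele or PCR failure"
      } else {
        call[i] <- "no_call_low_depth"
        reason[i] <- sprintf("depth %d < %d", depth, config$min_reads_per_allele)
      }
      next
    }
    if (depth < config$min_reads_per_allele) {
      call[i] <- "no_call_low_depth"
      reason[i] <- sprintf("depth %d < %d", depth, config$min_reads_per_allele)
      next
    }
    cutoff <- ckey[paste(counts$marker_id[i], counts$site_id[i], sep = "\r")]
    if (is.na(cutoff)) {
      call[i] <- "no_call_no_control"; reason[i] <- "no qualifying in-run control"
      next
    }
    pct <- counts$percent_favorable[i]
    if (config$het_calling_enabled &&
        pct >= config$het_band[1L] && pct <= config$het_band[2L]) {
      call[i] <- "heterozygous"
      next
    }
    thr <- effective_threshold(cutoff, depth, config$cutoff_guard_sd)
    call[i] <- if (pct >= min(thr, cutoff)) "homozygous_positive"
               else "homozygous_negative"
  }
  out <- data.frame(sample_id = counts$sample_id, marker_id = counts$marker_id,
                    site_id = counts$site_id, depth = counts$total,
                    percent_favorable = counts$percent_favorable,
                    call = call, caution_flag = caution, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("genotype_calls", "data.frame")
  out
}

is_no_call <- function(x) startsWith(x, "no_call")

#' Per-marker call rate
#'
#' Fraction of samples with a confident genotype call (anything but
#' `no_call_*`) for each marker, as a percentage. A sample counts as called
#' for a multi-site marker only when every site is confidently called.
#'
#' @param calls a `genotype_calls` table.
#' @return data.frame with columns marker_id, n_samples, n_called,
#'   call_rate_percent.
#' @export
call_rate <- function(calls) {
  key <- paste(calls$marker_id, calls$sample_id, sep = "\r")
  called <- tapply(!is_no_call(calls$call), key, all)
  mk <- sub("\r.*", "", names(called))
  n <- tapply(called, mk, length)
  k <- tapply(called, mk, sum)
  data.frame(marker_id = names(n), n_samples = as.integer(n),
             n_called = as.integer(k),
             call_rate_percent = 100 * as.integer(k) / as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype concordance between two call sets
#'
#' Proportion of matched calls between two marker systems over the samples
#' compared, per marker and overall. Rows are joined on sample, marker and
#' (when both tables carry it) site. Non-confident calls (`no_call_*`) are
#' excluded from the denominator by default, mirroring how scored genotypes
#' are compared across assay systems; set `include_no_call = TRUE` to count
#' them as mismatches.
#'
#' @param calls_a,calls_b data.frames with columns sample_id, marker_id,
#'   optionally site_id, and call.
#' @param include_no_call logical, default FALSE.
#' @return list of class `amp_concordance`: `overall` proportion, `n_compared`,
#'   `per_marker` data.frame.
#' @export
concordance <- function(calls_a, calls_b, include_no_call = FALSE) {
  keys <- c("sample_id", "marker_id")
  if ("site_id" %in% names(calls_a) && "site_id" %in% names(calls_b))
    keys <- c(keys, "site_id")
  mg <- merge(calls_a[, c(keys, "call")], calls_b[, c(keys, "call")],
              by = keys, suffixes = c("_a", "_b"))
  if (!include_no_call)
    mg <- mg[!is_no_call(mg$call_a) & !is_no_call(mg$call_b), , drop = FALSE]
  if (!nrow(mg)) {
    warning("no comparable calls between the two call sets")
    return(structure(list(overall = NA_real_, n_compared = 0L,
                          per_marker = data.frame(marker_id = character(),
                                                  n_compared = integer(),
                                                  concordance = numeric())),
                     class = "amp_concordance"))
  }
  mg$matched <- mg$call_a == mg$call_b
  per <- aggregate(matched ~ marker_id, mg,
                   function(x) c(n = length(x), conc = mean(x)))
  per_marker <- data.frame(marker_id = per$marker_id,
                           n_compared = as.integer(per$matched[, "n"]),
                           concordance = per$matched[, "conc"],
                           stringsAsFactors = FALSE)
  structure(list(overall = mean(mg$matched), n_compared = nrow(mg),
                 per_marker = per_marker),
            class = "amp_concordance")
}

#' @export
print.amp_concordance <- function(x, ...) {
  cat(sprintf("<amp_concordance> overall %.3f over %d compared calls\n",
              x$overall, x$n_compared))
  invisible(x)
}

#' Collapse per-site calls to marker level
#'
#' For multi-SNP amplicons the per-site calls are primary; this derived
#' summary reports one call per (sample, marker): the shared call when all
#' sites agree, otherwise `discordant_sites`.
#'
#' @param calls a `genotype_calls` table.
#' @return data.frame with columns sample_id, marker_id, call.
#' @export
marker_level_calls <- function(calls) {
  key <- paste(calls$sample_id, calls$marker_id, sep = "\r")
  agg <- tapply(calls$call, key, function(x)
    if (length(unique(x)) == 1L) x[[1L]] else "discordant_sites")
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  data.frame(sample_id = parts[, 1L], marker_id = parts[, 2L],
             call = as.character(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read an external genotype call table
#'
#' Accepts TSVs from uniplex assay systems with columns `sample`/`sample_id`,
#' `marker`/`marker_id` and `call`, for concordance computation.
#' @param tsv_path path to the TSV.
#' @return data.frame with columns sample_id, marker_id, call.
#' @export
read_call_table <- function(tsv_path) {
  x <- read.delim(tsv_path, stringsAsFactors = FALSE)
  nm <- names(x)
  nm[nm == "sample"] <- "sample_id"
  nm[nm == "marker"] <- "marker_id"
  names(x) <- nm
  miss <- setdiff(c("sample_id", "marker_id", "call"), nm)
  if (length(miss))
    stop_validation("call table missing column: ", paste(miss, collapse = ", "))
  x[, c("sample_id", "marker_id", "call")]
}
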