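# deterministic toy fixtures, built in code

toy_fwd <- "ACGTACGTACGTACGTA"            # 17 nt
toy_rev <- "TTTTGGGGCCCCAAAAT"            # 17 nt
toy_insert <- paste0("GGATCCTTAAGGCCAATTGGCCTAGGATCC",
                     "AATTCCGGAATTCCGGAATTCCGGAATTCC")  # 60 nt

toy_marker <- function(marker_id = "TOY1", mode = "codominant",
                       specificity = "genome_specific",
                       sites = variant_sites(position = 30,
                                             favorable_base = "A",
                                             wild_type_base = "G")) {
  ref <- paste0(toy_fwd, toy_insert, revcomp_chr(toy_rev))
  # reference carries the favorable base at each site
  for (r in seq_len(nrow(sites)))
    substr(ref, sites$position[r], sites$position[r]) <- sites$favorable_base[r]
  marker_definition(marker_id, toy_fwd, toy_rev, ref, sites = sites,
                    mode = mode, specificity = specificity)
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

toy_samples <- function() {
  data.frame(sample_id = c("PC1", "S1", "S2"),
             barcode = c("AACCGGTTAA", "TTGGCCAATT", "ACACACACAC"),
             pos_control_for = c("TOY1,TOY2", "", ""),
             neg_control_for = "",
             stringsAsFactors = FALSE)
}

toy_panel <- function() {
  m2 <- {
    fwd <- "GGGGAAAACCCCTTTTG"
    rev <- "CACACTGTGTGAGAGAC"
    ref <- paste0(fwd, substr(toy_insert, 1, 50), revcomp_chr(rev))
    marker_definition("TOY2", fwd, rev, ref,
                      sites = variant_sites(40, substr(ref, 40, 40),
                                            setdiff(c("A","C","G","T"),
                                                    substr(ref, 40, 40))[1]),
                      mode = "codominant", specificity = "semi_specific")
  }
  panel(list(toy_marker(), m2), samples = toy_samples())
}

# write a panel + sample sheet to tempfiles; returns the three paths
write_toy_files <- function(p = toy_panel()) {
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fasta")
  ss <- tempfile(fileext = ".tsv")
  write_panel(p, tsv, fa)
  write_sample_sheet(p$samples, ss)
  c(tsv = tsv, fasta = fa, samples = ss)
}

# random read/reference pair with substitutions and at most `max_indel`
# nt inserted or deleted; returns list(read, ref)
random_pair <- function(len = 50, n_sub = 2, max_indel = 3) {
  ref <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  rd <- strsplit(ref, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(len, n_sub)
    for (p in pos) rd[p] <- sample(c("A", "C", "G", "T"), 1)
  }
  rd <- paste(rd, collapse = "")
  k <- sample(0:max_indel, 1)
  if (k > 0) {
    pos <- sample(nchar(rd) - k, 1)
    if (runif(1) < 0.5) {
      rd <- paste0(substr(rd, 1, pos), substr(rd, pos + k + 1, nchar(rd)))
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
      rd <- paste0(substr(rd, 1, pos), ins, substr(rd, pos + 1, nchar(rd)))
    }
  }
  list(read = rd, ref = ref)
}

# Biostrings full dynamic-programming global alignment score: the
# independent oracle for the banded aligner
oracle_score <- function(read, ref, match = 1, mismatch = 1,
                         gap_open = 2, gap_ext = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = -mismatch)
  Biostrings::pairwiseAlignment(read, ref, substitutionMatrix = mat,
                                gapOpening = gap_open, gapExtension = gap_ext,
                                type = "global", scoreOnly = TRUE)
}

# tiny hand-built allele-count tables for calling-rule tests
mini_counts <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    out <- data.frame(sample_id = r$s, marker_id = r$m, site_id = r$site,
                      n_A = 0L, n_C = 0L, n_G = 0L, n_T = 0L, n_N = 0L,
                      stringsAsFactors = FALSE)
    for (b in names(r$counts)) out[[paste0("n_", b)]] <- r$counts[[b]]
    out
  }))
  df$total <- rowSums(df[paste0("n_", c("A", "C", "G", "T", "N"))])
  class(df) <- c("allele_counts", "data.frame")
  df
}
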