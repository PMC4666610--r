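DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) && nzchar(x) &&
    grepl("^[ACGT]+$", x)
}

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Hamming distance between two equal-rank prefixes
#'
#' Compared over the shorter of the two lengths (length alignment by prefix).
#' @keywords internal
hamming <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, n), "")[[1]] != strsplit(substr(b, 1, n), "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("amplicall_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# apply iid substitution errors to a character vector of sequences; the
# error count and positions are drawn in R (seed-reproducible), the string
# surgery happens in C++
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  tot <- sum(n_err)
  if (tot == 0L) return(seqs)
  read_idx <- rep.int(seq_along(seqs), n_err)
  pos <- ceiling(runif(tot) * lens[read_idx])
  offset <- sample.int(3L, tot, replace = TRUE)
  out <- cpp_apply_subs(seqs, read_idx, pos, offset)
  names(out) <- names(seqs)
  out
}
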