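test_that("expected allele fraction enumerates all nine one-to-three-genome rows", {
  # exact values; the printed table truncates 100/3 and 100/6 to 33 and 16
  expect_equal(expected_allele_fraction("AA"), 100)
  expect_equal(expected_allele_fraction("AT"), 50)
  expect_equal(expected_allele_fraction("TT"), 0)
  expect_equal(expected_allele_fraction(c("AA", "TT")), 50)
  expect_equal(expected_allele_fraction(c("AT", "TT")), 25)
  expect_equal(expected_allele_fraction(c("TT", "TT")), 0)
  expect_equal(expected_allele_fraction(c("AA", "TT", "TT")), 100 / 3)
  expect_equal(expected_allele_fraction(c("AT", "TT", "TT")), 100 / 6)
  expect_equal(expected_allele_fraction(c("TT", "TT", "TT")), 0)
  # floor-rounding recovers the printed integers
  grid <- list("AA", "AT", "TT", c("AA","TT"), c("AT","TT"), c("TT","TT"),
               c("AA","TT","TT"), c("AT","TT","TT"), c("TT","TT","TT"))
  expect_identical(vapply(grid, function(g) floor(expected_allele_fraction(g)), 0),
                   c(100, 50, 0, 50, 25, 0, 33, 16, 0))
  expect_error(expected_allele_fraction(character(0)), "at least one")
  expect_error(expected_allele_fraction(c("AA","TT","TT","TT")), "at most three")
  expect_error(expected_allele_fraction("AG"), "genotypes")
})

test_that("error-free single-template simulation is exact", {
  p <- make_default_panel(1, seed = 2, n_samples = 0)
  p$samples <- data.frame(sample_id = "S1", barcode = "AACCGGTTAA",
                          pos_control_for = "", neg_control_for = "",
                          stringsAsFactors = FALSE)
  m <- p$markers[[1]]
  truth <- data.frame(sample_id = "S1", marker_id = m$marker_id,
                      genotype = paste(rep("AA", m$copies_coamplified),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
  sc <- sim_scenario(p, truth = truth, reads_per_marker = 100,
                     depth_dispersion = Inf,   # fixed depth
                     substitution_error_rate = 0, contaminant_fraction = 0,
                     homoeolog_divergence = 0, seed = 3)
  sim <- simulate_reads(sc)
  reads <- as.character(Biostrings::readDNAStringSet(sim$fastq, format = "fastq"))
  expect_equal(length(reads), 100)
  lay <- expected_read_layout(m, "AACCGGTTAA")
  expect_true(all(reads == paste(lay, collapse = "")))
})

test_that("heterozygous template draws follow the binomial", {
  p <- make_default_panel(1, seed = 2, n_samples = 0)
  p$samples <- data.frame(sample_id = "S1", barcode = "AACCGGTTAA",
                          pos_control_for = "", neg_control_for = "",
                          stringsAsFactors = FALSE)
  m <- p$markers[[1]]
  truth <- data.frame(sample_id = "S1", marker_id = m$marker_id,
                      genotype = paste(c("AT", rep("TT", m$copies_coamplified - 1)),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
  sc <- sim_scenario(p, truth = truth, reads_per_marker = 100,
                     depth_dispersion = Inf, substitution_error_rate = 0,
                     contaminant_fraction = 0, homoeolog_divergence = 0, seed = 5)
  sim <- simulate_reads(sc)
  reads <- as.character(Biostrings::readDNAStringSet(sim$fastq, format = "fastq"))
  site <- m$sites[1, ]
  at_site <- substr(reads, 10 + 21 + site$position, 10 + 21 + site$position)
  frac <- mean(at_site == site$favorable_base)
  ci <- qbinom(c(0.005, 0.995), 100, 0.5) / 100
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
})

test_that("null pairs emit zero reads and read totals are conserved", {
  p <- make_default_panel(5, seed = 4, n_samples = 6)
  sc <- sim_scenario(p, reads_per_marker = 40, seed = 6,
                     null_samples = data.frame(sample_id = "S01",
                                               marker_id = "M01"))
  sim <- simulate_reads(sc)
  em <- sim$emitted
  expect_identical(em$n_reads[em$sample_id == "S01" & em$marker_id == "M01"], 0L)
  # dominant-null truth pairs (M05 here) emit nothing as well
  tr <- sim$truth
  null_pairs <- unique(tr[tr$genotype == "null", c("sample_id", "marker_id")])
  for (i in seq_len(nrow(null_pairs)))
    expect_identical(em$n_reads[em$sample_id == null_pairs$sample_id[i] &
                                em$marker_id == null_pairs$marker_id[i]], 0L)
  # conservation: structured + contaminant = total
  expect_identical(sum(em$n_reads) + sim$n_contaminant, sim$n_total)
  n_fastq <- length(Biostrings::readDNAStringSet(sim$fastq, format = "fastq"))
  expect_identical(n_fastq, sim$n_total)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- make_default_panel(3, seed = 9, n_samples = 5)
  sc <- sim_scenario(p, reads_per_marker = 30, seed = 123)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_reads(sc, fastq = f1)
  simulate_reads(sc, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("default panel generation scales and validates clean", {
  p <- make_default_panel(27, seed = 1, n_samples = 24)
  expect_length(p$markers, 27)
  expect_length(validate_panel(p), 0)
  lens <- vapply(p$markers, function(m) nchar(m$reference_amplicon), 0L)
  expect_true(all(lens >= 80 & lens <= 200))
  # determinism
  p2 <- make_default_panel(27, seed = 1, n_samples = 24)
  expect_identical(vapply(p$markers, `[[`, "", "reference_amplicon"),
                   vapply(p2$markers, `[[`, "", "reference_amplicon"))
  expect_identical(p$samples, p2$samples)
  # minimal panel
  expect_length(make_default_panel(1, seed = 2, n_samples = 4)$markers, 1)
})

test_that("scenario construction rejects invalid rates", {
  p <- make_default_panel(1, seed = 2, n_samples = 4)
  expect_error(sim_scenario(p, substitution_error_rate = 1.5), "rates",
               class = "amplicall_validation_error")
  expect_error(sim_scenario(p, contaminant_fraction = -0.1), "rates",
               class = "amplicall_validation_error")
  expect_error(sim_scenario(p, reads_per_marker = -5), "depth",
               class = "amplicall_validation_error")
})

test_that("empirical favorable fraction converges to the model value", {
  # law of large numbers at depth 4000, error-free: within 3 binomial SD
  p <- make_default_panel(3, seed = 7, n_samples = 0)
  p$samples <- data.frame(sample_id = "S1", barcode = "AACCGGTTAA",
                          pos_control_for = "", neg_control_for = "",
                          stringsAsFactors = FALSE)
  for (mid in names(p$markers)) {
    m <- p$markers[[mid]]
    if (m$mode != "codominant") next
    gts <- c("AT", rep("TT", m$copies_coamplified - 1))
    truth <- data.frame(sample_id = "S1", marker_id = mid,
                        genotype = paste(gts, collapse = ","),
                        stringsAsFactors = FALSE)
    p1 <- p; p1$markers <- p$markers[mid]
    sc <- sim_scenario(p1, truth = truth, reads_per_marker = 4000,
                       depth_dispersion = Inf, substitution_error_rate = 0,
                       contaminant_fraction = 0, homoeolog_divergence = 0,
                       seed = 11)
    sim <- simulate_reads(sc)
    reads <- as.character(Biostrings::readDNAStringSet(sim$fastq, format = "fastq"))
    site <- m$sites[1, ]
    bc_len <- nchar(p$samples$barcode[1])
    at_site <- substr(reads, bc_len + 21 + site$position,
                      bc_len + 21 + site$position)
    pexp <- expected_allele_fraction(gts) / 100
    sd3 <- 3 * sqrt(pexp * (1 - pexp) / length(reads))
    expect_lt(abs(mean(at_site == site$favorable_base) - pexp), sd3 + 1e-12)
  }
})
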