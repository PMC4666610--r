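test_that("allele counting tabulates exactly and zero-fills missing keys", {
  obs <- data.frame(sample_id = rep("S1", 10), marker_id = "TOY1",
                    site_id = "S30",
                    observed = c(rep("A", 6), rep("T", 4)),
                    stringsAsFactors = FALSE)
  ct <- count_alleles(obs)
  expect_equal(ct$n_A, 6L)
  expect_equal(ct$n_T, 4L)
  expect_equal(ct$total, 10)

  p <- toy_panel()
  ct2 <- count_alleles(obs, p)
  # every sample x marker-site key exists, zero rows included
  expect_equal(nrow(ct2), nrow(p$samples) * 2)
  z <- ct2[ct2$sample_id == "S2" & ct2$marker_id == "TOY1", ]
  expect_equal(z$total, 0)
})

test_that("percent favorable is the exact read fraction, undefined at zero depth", {
  expect_equal(percent_favorable(c(n_A = 50, n_C = 0, n_G = 0, n_T = 50, n_N = 0), "A"),
               50.0)
  expect_equal(percent_favorable(c(n_A = 1, n_C = 0, n_G = 0, n_T = 5, n_N = 0), "A"),
               100 / 6)
  expect_true(is.na(percent_favorable(c(n_A = 0, n_C = 0, n_G = 0, n_T = 0, n_N = 0), "A")))
  # a third (error) base stays in the denominator
  expect_equal(percent_favorable(c(n_A = 6, n_C = 1, n_G = 0, n_T = 3, n_N = 0), "A"),
               60)
})

test_that("cutoffs are the minimum over qualifying in-run positive controls", {
  p <- toy_panel()
  p$samples <- data.frame(sample_id = c("PC1", "PC2", "S1"),
                          barcode = c("AACCGGTTAA", "TTGGCCAATT", "ACACACACAC"),
                          pos_control_for = c("TOY1", "TOY1", ""),
                          neg_control_for = "", stringsAsFactors = FALSE)
  ct <- mini_counts(list(
    list(s = "PC1", m = "TOY1", site = "S30", counts = c(A = 521, G = 479)),
    list(s = "PC2", m = "TOY1", site = "S30", counts = c(A = 503, G = 497)),
    list(s = "S1", m = "TOY1", site = "S30", counts = c(A = 999, G = 1))))
  co <- derive_cutoffs(ct, p)
  expect_equal(nrow(co), 1)
  expect_equal(co$cutoff_percent, 50.3)
  expect_equal(co$n_controls, 2)

  # a single control degenerates to its own value
  ct1 <- ct[ct$sample_id != "PC2", ]
  co1 <- derive_cutoffs(ct1, p)
  expect_equal(co1$cutoff_percent, 52.1)

  # control below the minimum depth does not qualify -> no cutoff,
  # downstream codominant calls are no_call
  ct_low <- mini_counts(list(
    list(s = "PC1", m = "TOY1", site = "S30", counts = c(A = 5)),
    list(s = "S1", m = "TOY1", site = "S30", counts = c(A = 60, G = 40))))
  co_low <- derive_cutoffs(ct_low, p)
  expect_equal(nrow(co_low), 0)
  calls <- call_genotypes(ct_low, co_low, p)
  expect_identical(calls$call[calls$sample_id == "S1"], "no_call_no_control")
})

test_that("calling rules respect the depth cutoff and the at-or-above rule", {
  p <- toy_panel()
  cutoffs <- data.frame(marker_id = "TOY1", site_id = "S30",
                        cutoff_percent = 50, n_controls = 1,
                        control_samples = "PC1", stringsAsFactors = FALSE)
  ct <- mini_counts(list(
    list(s = "a", m = "TOY1", site = "S30", counts = c(A = 9)),        # depth 9
    list(s = "b", m = "TOY1", site = "S30", counts = c(A = 10)),       # depth 10
    list(s = "c", m = "TOY1", site = "S30", counts = c(A = 50, G = 50)),  # == cutoff
    list(s = "d", m = "TOY1", site = "S30", counts = c(A = 60, G = 40)),
    list(s = "e", m = "TOY1", site = "S30", counts = c(A = 1, G = 99))))
  calls <- call_genotypes(ct, cutoffs, p)
  get <- function(s) calls$call[calls$sample_id == s]
  expect_identical(get("a"), "no_call_low_depth")
  expect_identical(get("b"), "homozygous_positive")
  # percentage exactly equal to the control cutoff is positive
  expect_identical(get("c"), "homozygous_positive")
  expect_identical(get("d"), "homozygous_positive")
  expect_identical(get("e"), "homozygous_negative")
})

test_that("dominant null-allele markers never call homozygous_negative", {
  p <- panel(list(toy_marker(mode = "dominant_null")), samples = toy_samples())
  ct <- mini_counts(list(
    list(s = "a", m = "TOY1", site = "S30", counts = c(A = 100)),
    list(s = "b", m = "TOY1", site = "S30", counts = c(A = 0)),
    list(s = "c", m = "TOY1", site = "S30", counts = c(A = 7))))
  calls <- call_genotypes(ct, derive_cutoffs(ct, p), p)
  expect_identical(calls$call[calls$sample_id == "a"], "homozygous_positive")
  expect_identical(calls$call[calls$sample_id == "b"], "null_allele_putative")
  expect_true(calls$caution_flag[calls$sample_id == "b"])
  expect_identical(calls$call[calls$sample_id == "c"], "no_call_low_depth")
  expect_false(any(calls$call == "homozygous_negative"))
})

test_that("raising the cutoff never converts a negative call to positive", {
  p <- toy_panel()
  ct <- mini_counts(lapply(seq(0, 100, by = 5), function(pc) {
    list(s = paste0("s", pc), m = "TOY1", site = "S30",
         counts = c(A = pc, G = 100 - pc))
  }))
  prev_pos <- rep(TRUE, nrow(ct))
  for (cut in seq(5, 100, by = 5)) {
    cutoffs <- data.frame(marker_id = "TOY1", site_id = "S30",
                          cutoff_percent = cut, n_controls = 1,
                          control_samples = "PC1", stringsAsFactors = FALSE)
    calls <- call_genotypes(ct, cutoffs, p)
    pos <- calls$call == "homozygous_positive"
    expect_true(all(prev_pos | !pos),
                info = sprintf("cutoff %d resurrected a positive", cut))
    prev_pos <- pos
  }
})

test_that("heterozygote band calling works only when explicitly enabled", {
  p <- toy_panel()
  cutoffs <- data.frame(marker_id = "TOY1", site_id = "S30",
                        cutoff_percent = 90, n_controls = 1,
                        control_samples = "PC1", stringsAsFactors = FALSE)
  ct <- mini_counts(list(
    list(s = "het", m = "TOY1", site = "S30", counts = c(A = 50, G = 50))))
  expect_error(calling_config(het_calling_enabled = TRUE), "het_band",
               class = "amplicall_validation_error")
  cfg <- calling_config(het_calling_enabled = TRUE, het_band = c(35, 65))
  calls <- call_genotypes(ct, cutoffs, p, cfg)
  expect_identical(calls$call, "heterozygous")
  calls_off <- call_genotypes(ct, cutoffs, p)
  expect_false(any(calls_off$call == "heterozygous"))
})

test_that("call rate is the fraction of confidently scored samples", {
  calls <- data.frame(
    sample_id = rep(sprintf("s%02d", 1:24), 2),
    marker_id = rep(c("M1", "M2"), each = 24),
    site_id = "S1",
    call = c(rep("homozygous_positive", 24),
             c(rep("homozygous_negative", 23), "no_call_low_depth")),
    stringsAsFactors = FALSE)
  cr <- call_rate(calls)
  expect_equal(cr$call_rate_percent[cr$marker_id == "M1"], 100)
  expect_equal(cr$call_rate_percent[cr$marker_id == "M2"], 100 * 23 / 24)
  calls$call <- "no_call_low_depth"
  expect_true(all(call_rate(calls)$call_rate_percent == 0))
})

test_that("concordance matches the proportion-of-matched-calls definition", {
  a <- data.frame(sample_id = sprintf("s%02d", 1:24), marker_id = "M1",
                  call = "homozygous_positive", stringsAsFactors = FALSE)
  expect_equal(concordance(a, a)$overall, 1.0)

  b <- a
  b$call[1:5] <- "homozygous_negative"
  cc <- concordance(a, b)
  expect_equal(cc$overall, 19 / 24, tolerance = 1e-12)
  expect_equal(round(cc$overall, 3), 0.792)

  # no_call excluded from the denominator by default, counted as mismatch
  # on request
  b2 <- a
  b2$call[1:4] <- "no_call_low_depth"
  expect_equal(concordance(a, b2)$n_compared, 20)
  expect_equal(concordance(a, b2, include_no_call = TRUE)$overall, 20 / 24)

  # disjoint keys are undefined with a warning
  d <- a; d$sample_id <- paste0("x", d$sample_id)
  expect_warning(cc0 <- concordance(a, d), "no comparable")
  expect_true(is.na(cc0$overall))
})

test_that("per-site calls collapse to marker level with discordance flagged", {
  calls <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                      marker_id = "M1", site_id = c("A", "B", "A", "B"),
                      call = c("homozygous_positive", "homozygous_positive",
                               "homozygous_positive", "homozygous_negative"),
                      stringsAsFactors = FALSE)
  ml <- marker_level_calls(calls)
  expect_identical(ml$call[ml$sample_id == "s1"], "homozygous_positive")
  expect_identical(ml$call[ml$sample_id == "s2"], "discordant_sites")
})
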