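make_meta <- function(days, reps) {
  data.frame(sample = paste0("d", rep(days, each = reps), "_r",
                             rep(seq_len(reps), length(days))),
             day = rep(days, each = reps),
             replicate = rep(seq_len(reps), length(days)))
}

test_that("average_replicates takes per-day means", {
  meta <- make_meta(c(15, 30), 2)
  counts <- matrix(c(1, 2, 1, 2, 10, 5, 14, 5), nrow = 2,
                   dimnames = list(c("g1", "g2"), meta$sample))
  avg <- average_replicates(counts, meta)
  expect_equal(avg["g1", "30"], 12)     # mean(10, 14)
  expect_equal(avg["g1", "15"], 1)
  # single replicate is the identity
  meta1 <- make_meta(15, 1)
  m1 <- matrix(7, 1, 1, dimnames = list("g", meta1$sample))
  expect_equal(unname(average_replicates(m1, meta1)[1, 1]), 7)
})

test_that("average_replicates equals brute-force group means on random input", {
  set.seed(501)
  meta <- make_meta(c(15, 30, 45, 60), 3)
  counts <- matrix(rpois(50 * 12, 30), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), meta$sample))
  avg <- average_replicates(counts, meta)
  for (d in unique(meta$day)) {
    brute <- apply(counts[, meta$day == d, drop = FALSE], 1, mean)
    expect_equal(avg[, as.character(d)], brute)
  }
})

test_that("normalize_to_max scales to [0,1] and flags non-detection", {
  expect_equal(normalize_to_max(c(100, 200, 400))$profile, c(0.25, 0.5, 1))
  z <- normalize_to_max(c(0, 0, 0))
  expect_equal(z$profile, c(0, 0, 0))
  expect_false(z$detected)
  expect_equal(normalize_to_max(7)$profile, 1)
  expect_error(normalize_to_max(c(-1, 2)), "nonnegative")
  # idempotent, and invariant to positive rescaling
  x <- c(3, 9, 27)
  p <- normalize_to_max(x)$profile
  expect_equal(normalize_to_max(p)$profile, p)
  expect_equal(normalize_to_max(100 * x)$profile, p)
})

test_that("log2 fold change follows the pseudocount closed form", {
  meta <- make_meta(c(15, 60), 2)
  counts <- matrix(c(1, 1, 31, 31), nrow = 1,
                   dimnames = list("g", meta$sample))
  d <- differential(counts, meta, 60,
                    config = volcano_config(min_count_threshold = 0))
  expect_equal(d$log2fc, log2(32) - log2(2))
  expect_equal(d$log2fc, 4)
  # identical groups: log2fc 0, zero-variance p reported missing
  counts2 <- matrix(c(8, 8, 8, 8), nrow = 1,
                    dimnames = list("g", meta$sample))
  d2 <- differential(counts2, meta, 60,
                     config = volcano_config(min_count_threshold = 0))
  expect_equal(d2$log2fc, 0)
  expect_true(is.na(d2$p_value))
  expect_false(d2$significant)
})

test_that("comparing a day to itself gives zero fold change everywhere", {
  cfg <- simulation_config(seed = 502, n_proteins = 50)
  cm <- simulate_counts(cfg)
  d <- differential(cm$counts, cm$meta, 30, reference_day = 30)
  expect_true(all(d$log2fc == 0))
})

test_that("single-replicate groups yield missing p-values", {
  meta <- make_meta(c(15, 60), 1)
  counts <- matrix(c(5, 80), nrow = 1, dimnames = list("g", meta$sample))
  d <- differential(counts, meta, 60,
                    config = volcano_config(min_count_threshold = 0))
  expect_true(is.na(d$p_value))
  expect_false(d$significant)
  expect_error(differential(counts, meta, 45), "absent")
})

test_that("the significant flag is exactly the joint threshold rule", {
  cfg <- simulation_config(seed = 503, n_proteins = 300,
                           planted_fraction = 0.3, planted_magnitude = 32)
  cm <- simulate_counts(cfg)
  d <- differential(cm$counts, cm$meta, 60)
  expect_equal(d$significant,
               !is.na(d$p_value) & d$p_value < 0.05 & abs(d$log2fc) > 4)
})

test_that("planted 32-fold changes are detected with high power", {
  cfg <- simulation_config(seed = 504, n_proteins = 500,
                           planted_fraction = 0.2, planted_magnitude = 32)
  cm <- simulate_counts(cfg)
  d <- differential(cm$counts, cm$meta, 60)
  planted <- cm$truth$planted[match(d$gene, cm$truth$gene)]
  expect_gte(mean(d$significant[planted]), 0.8)
  expect_lte(mean(d$significant[!planted]), 0.07)
})

test_that("volcano_table restricts, sorts and labels", {
  diffs <- data.frame(
    gene = c("A", "B", "C"), day = 60, reference_day = 15, base_mean = 100,
    log2fc = c(4.5, 5, 3.9), p_value = c(0.01, 0.2, 0.01), p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  diffs$significant <- !is.na(diffs$p_value) & diffs$p_value < 0.05 &
    abs(diffs$log2fc) > 4
  vt <- volcano_table(diffs)
  expect_equal(vt$label[vt$gene == "A"], "A")       # p and fc both pass
  expect_true(is.na(vt$label[vt$gene == "B"]))      # p fails
  expect_true(is.na(vt$label[vt$gene == "C"]))      # fc fails
  expect_equal(vt$p_value, sort(vt$p_value))

  spc <- c(A = 4L, B = 0L, C = 3L)
  expect_equal(sort(volcano_table(diffs, "spc_high", spc_table = spc)$gene),
               c("A", "C"))
  expect_equal(nrow(volcano_table(diffs, "spc_high",
                                  spc_table = c(Z = 4L))), 0L)
  expect_lte(nrow(volcano_table(diffs, "cazy",
                                cazy_genes = c("B", "Q"))), 10L)
  expect_equal(volcano_table(diffs, "cazy", cazy_genes = "B")$gene, "B")
  expect_error(volcano_table(diffs, "spc_high"), "SPC")
  expect_error(volcano_table(diffs, "cazy"), "gene list")
  expect_error(volcano_table(diffs, "bogus"))
})

test_that("evidence profiles normalize each modality to its maximum", {
  meta <- make_meta(c(15, 30, 45, 60), 2)
  counts <- matrix(rep(c(10, 20, 40, 40), each = 2), nrow = 1, byrow = TRUE,
                   dimnames = list("G1", meta$sample))
  psm <- matrix(c(1, 6, 10, 10), nrow = 1,
                dimnames = list("G1", c("15", "30", "45", "60")))
  ep <- evidence_profiles(counts, meta, psm)
  prof <- ep$profiles
  expect_equal(max(prof$transcript), 1)
  expect_equal(max(prof$psm), 1)
  expect_equal(prof$transcript[1], 0.25)
  expect_true(ep$detection$transcript_detected)
})

test_that("concordance sign and the detected-by-one-modality flag", {
  meta <- make_meta(c(15, 30, 45), 1)
  counts <- rbind(
    G1 = c(20, 50, 100),   # rising transcript
    G2 = c(0, 0, 0)        # silent transcript
  )
  colnames(counts) <- meta$sample
  psm <- rbind(G1 = c(1, 6, 10), G2 = c(0, 4, 10))
  colnames(psm) <- c("15", "30", "45")
  ep <- evidence_profiles(counts, meta, psm)
  cc <- evidence_concordance(ep, floor = 5)
  expect_equal(cc$direction[cc$protein == "G1"], "positive")
  expect_false(cc$discordant[cc$protein == "G1"])
  expect_true(cc$discordant[cc$protein == "G2"])   # PSMs without transcript

  # fewer than 3 shared timepoints: correlation missing
  meta2 <- make_meta(c(15, 30), 1)
  counts2 <- matrix(c(5, 10), 1, dimnames = list("G1", meta2$sample))
  psm2 <- matrix(c(1, 2), 1, dimnames = list("G1", c("15", "30")))
  cc2 <- evidence_concordance(evidence_profiles(counts2, meta2, psm2))
  expect_true(is.na(cc2$rho))
})

test_that("independent random profiles have near-zero mean correlation", {
  set.seed(505)
  n <- 1000
  meta <- make_meta(c(15, 30, 45, 60), 1)
  counts <- matrix(runif(n * 4, 1, 100), nrow = n,
                   dimnames = list(sprintf("G%04d", 1:n), meta$sample))
  psm <- matrix(rpois(n * 4, 10), nrow = n,
                dimnames = list(sprintf("G%04d", 1:n), c("15", "30", "45", "60")))
  cc <- evidence_concordance(evidence_profiles(counts, meta, psm))
  expect_lt(abs(mean(cc$rho, na.rm = TRUE)), 0.06)
})
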