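test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(seed = 601, n_proteins = 30)
  expect_identical(simulate_proteome(cfg), simulate_proteome(cfg))
  pro <- simulate_proteome(cfg)
  expect_identical(simulate_isoforms(pro, cfg), simulate_isoforms(pro, cfg))
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_psm(pro$id, cfg), simulate_psm(pro$id, cfg))
  expect_identical(simulate_spc(pro$gene, cfg), simulate_spc(pro$gene, cfg))
  cfg2 <- simulation_config(seed = 602, n_proteins = 30)
  expect_false(identical(simulate_proteome(cfg)$sequence,
                         simulate_proteome(cfg2)$sequence))
})

test_that("config validation and degenerate sizes", {
  expect_equal(nrow(simulate_proteome(
    simulation_config(seed = 1, n_proteins = 0))), 0L)
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(composition = c(A = 0.5)), "sum to 1")
  expect_error(simulation_config(event_mix = c(internal_deletion = 1,
                                               internal_insertion = 1)),
               "sum to 1")
  cfg <- simulation_config(seed = 1, n_proteins = 5)
  expect_true(all(nchar(simulate_proteome(cfg)$sequence) >= cfg$min_length))
})

test_that("planted sequons are recovered at the configured rate", {
  r <- 0.05
  cfg <- simulation_config(seed = 603, n_proteins = 200, length_mean = 1000,
                           length_sd = 50, sequon_rate = r)
  pro <- simulate_proteome(cfg)
  total <- sum(nchar(pro$sequence))
  observed <- nrow(scan_proteome(pro))
  # renewal model: planting advances 3 positions on success, 1 otherwise,
  # so planted sites occur at rate r/(1+2r); the rest is background
  p_plant <- r / (1 + 2 * r)
  predicted <- total * p_plant +
    total * (1 - 3 * p_plant) * 2 * (1 / 20) * (19 / 20) * (1 / 20)
  expect_lt(abs(observed / predicted - 1), 0.05)
})

test_that("isoform events respect sequence bounds and produce valid records", {
  cfg <- simulation_config(seed = 604, n_proteins = 50)
  pro <- simulate_proteome(cfg)
  iso <- simulate_isoforms(pro, cfg)
  expect_equal(nrow(iso$records), nrow(pro))
  expect_true(all(nchar(iso$records$sequence) >= 1))
  expect_silent(validate_protein_records(rbind(pro, iso$records)))
  expect_true(all(iso$pairs$event_type %in% names(cfg$event_mix)))
  # every truth row refers to a known pair
  expect_true(all(iso$truth$canonical_id %in% pro$id))
  expect_true(all(iso$truth$isoform_id %in% iso$records$id))
})

test_that("coordinate-derived labels follow event arithmetic", {
  # deletion upstream of a sequon shifts it by exactly the event size
  cfg <- simulation_config(seed = 605, n_proteins = 200)
  pro <- simulate_proteome(cfg)
  iso <- simulate_isoforms(pro, cfg, event_type = "internal_deletion")
  sh <- iso$truth[iso$truth$status == "shifted", ]
  expect_gt(nrow(sh), 0)
  expect_true(all(sh$isoform_pos < sh$canonical_pos))
  shift <- unique(sh$canonical_pos - sh$isoform_pos)
  expect_true(all(shift >= 3))  # event sizes are >= 3 residues
  # retained sites keep their coordinate
  re <- iso$truth[iso$truth$status == "retained", ]
  expect_true(all(re$canonical_pos == re$isoform_pos))
  # lost sites have no isoform coordinate; gained no canonical one
  expect_true(all(is.na(iso$truth$isoform_pos[iso$truth$status == "lost"])))
  expect_true(all(is.na(iso$truth$canonical_pos[iso$truth$status == "gained"])))
})

test_that("insertions can create gained sequons that re-scanning confirms", {
  cfg <- simulation_config(seed = 606, n_proteins = 300)
  pro <- simulate_proteome(cfg)
  iso <- simulate_isoforms(pro, cfg, event_type = "internal_insertion")
  ga <- iso$truth[iso$truth$status == "gained", ]
  expect_gt(nrow(ga), 0)
  for (i in seq_len(nrow(ga))) {
    s <- iso$records$sequence[iso$records$id == ga$isoform_id[i]]
    expect_true(ga$isoform_pos[i] %in% find_sequons(s)$position)
  }
})

test_that("alignment classification reproduces generator labels end to end", {
  cfg <- simulation_config(seed = 607, n_proteins = 150)
  pro <- simulate_proteome(cfg)
  iso <- simulate_isoforms(pro, cfg)
  ch <- compare_isoforms(rbind(pro, iso$records))
  ids <- unique(c(iso$truth$canonical_id, ch$canonical_id))
  agree <- pair_agreement(iso$truth, ch, ids)
  unamb <- iso$pairs$unambiguous[match(ids, iso$pairs$canonical_id)]
  expect_equal(mean(agree[unamb]), 1)
  expect_gte(mean(agree), 0.99)
})

test_that("null count simulations match their configured means", {
  cfg <- simulation_config(seed = 608, n_proteins = 400, planted_fraction = 0)
  cm <- simulate_counts(cfg)
  expect_equal(dim(cm$counts), c(400L, 12L))
  expect_equal(cm$meta$day, rep(c(15L, 30L, 45L, 60L), each = 3))
  # per-gene empirical mean within 3 SE of its configured NB mean
  mu <- cm$truth$base_mean
  se <- sqrt((mu + cfg$dispersion * mu^2) / ncol(cm$counts))
  within <- abs(rowMeans(cm$counts) - mu) <= 3 * se
  expect_gte(mean(within), 0.98)
})

test_that("planted fold changes land within 20% of the configured factor", {
  cfg <- simulation_config(seed = 609, n_proteins = 1000,
                           planted_fraction = 0.3, planted_magnitude = 16)
  cm <- simulate_counts(cfg)
  avg <- average_replicates(cm$counts, cm$meta)
  up <- cm$truth$gene[cm$truth$planted & cm$truth$direction == "up"]
  up <- up[!is.na(up)]
  ratio <- mean(avg[up, "60"]) / mean(avg[up, "15"])
  expect_lt(abs(ratio / 16 - 1), 0.2)
  dn <- cm$truth$gene[cm$truth$planted & cm$truth$direction == "down"]
  ratio_dn <- mean(avg[dn, "15"]) / mean(avg[dn, "60"])
  expect_lt(abs(ratio_dn / 16 - 1), 0.2)
  null <- cm$truth$gene[!cm$truth$planted]
  expect_lt(abs(mean(avg[null, "60"]) / mean(avg[null, "15"]) - 1), 0.2)
})

test_that("PSM simulation honors detection probability and onset days", {
  cfg0 <- simulation_config(seed = 610, n_proteins = 50, detection_prob = 0)
  ps0 <- simulate_psm(sprintf("P%02d", 1:50), cfg0)
  expect_true(all(ps0$psm == 0))

  cfg <- simulation_config(seed = 611, n_proteins = 200,
                           late_onset_fraction = 1)
  ps <- simulate_psm(sprintf("P%03d", 1:200), cfg)
  for (i in seq_len(nrow(ps$psm))) {
    before <- as.integer(colnames(ps$psm)) < ps$truth$onset_day[i]
    expect_true(all(ps$psm[i, before] == 0))
  }
  expect_gt(sum(ps$psm), 0)
})

test_that("SPC scores follow the configured distribution support", {
  cfg <- simulation_config(seed = 612, n_proteins = 500)
  spc <- simulate_spc(sprintf("G%03d", 1:500), cfg)
  expect_true(all(spc %in% 0:4))
  expect_gt(length(unique(spc)), 2)
})
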