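defs <- load_pathway_definitions()
catalog <- load_marker_catalog()

test_that("protein generation is byte-identical for identical spec and seed", {
  spec <- mag_spec("M1", n_background_proteins = 20,
                   planted_mhcs = data.frame(motif_count = c(3, 8),
                                             has_c_terminal_tm = c(TRUE, FALSE)),
                   seed = 11)
  f1 <- tempfile(fileext = ".faa")
  f2 <- tempfile(fileext = ".faa")
  write_protein_fasta(simulate_proteins(spec)$proteins, f1)
  write_protein_fasta(simulate_proteins(spec)$proteins, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("planted proteins carry exactly the requested motif count", {
  spec <- mag_spec("M1", n_background_proteins = 0,
                   planted_mhcs = data.frame(motif_count = 15,
                                             has_c_terminal_tm = TRUE),
                   seed = 5)
  out <- simulate_proteins(spec)
  expect_equal(nrow(out$truth), 1L)
  expect_equal(out$truth$motif_count, 15L)
  # verified with the brute-force oracle on the emitted sequence
  expect_length(oracle_motif_positions(out$proteins[[1]]), 15L)
})

test_that("background proteins are motif-free by construction", {
  spec <- mag_spec("M1", n_background_proteins = 50, seed = 23)
  out <- simulate_proteins(spec)
  tab <- scan_mhc(out$proteins)
  expect_equal(sum(tab$is_mhc), 0L)
  expect_true(all(tab$motif_count == 0L))
  # and the oracle agrees
  expect_true(all(vapply(out$proteins,
                         function(s) length(oracle_motif_positions(s)) == 0,
                         logical(1))))
})

test_that("truth-table motif counts match the oracle across seeds", {
  for (seed in 1:5) {
    spec <- mag_spec("M1", n_background_proteins = 5,
                     planted_mhcs = data.frame(
                       motif_count = c(2, 5, 12),
                       has_c_terminal_tm = c(TRUE, FALSE, TRUE)),
                     seed = seed)
    out <- simulate_proteins(spec)
    got <- vapply(out$proteins, function(s) length(oracle_motif_positions(s)),
                  integer(1))
    expect_equal(unname(got), out$truth$motif_count)
  }
})

test_that("planted TM tails fire the default hydropathy detector", {
  spec <- mag_spec("M1", n_background_proteins = 0,
                   planted_mhcs = data.frame(motif_count = c(2, 2),
                                             has_c_terminal_tm = c(TRUE, FALSE)),
                   seed = 31)
  out <- simulate_proteins(spec)
  tab <- scan_mhc(out$proteins)
  expect_equal(tab$has_c_terminal_tm, out$truth$has_c_terminal_tm)
})

test_that("a length range too short to host the motifs rejects the spec", {
  spec <- mag_spec("M1", n_background_proteins = 0,
                   background_length_range = c(30, 60),
                   planted_mhcs = data.frame(motif_count = 15,
                                             has_c_terminal_tm = TRUE),
                   seed = 1)
  expect_error(simulate_proteins(spec), "too short")
})

test_that("annotation tables hit the requested pathway fractions exactly", {
  spec <- mag_spec("M1", pathway_fractions = c(WL = 1.0), seed = 3)
  ann <- simulate_annotations(spec, defs, catalog)
  expect_equal(score_pathway(ann$annotation_id, defs$WL), 100)
  # rounding rule on a 4-gene toy pathway: 0.75 -> 3 genes
  toy <- load_pathway_definitions(
    override = list(CBB = c("g1", "g2", "g3", "g4")))
  spec2 <- mag_spec("M2", pathway_fractions = c(CBB = 0.75), seed = 4)
  ann2 <- simulate_annotations(spec2, toy, catalog)
  expect_equal(sum(ann2$annotation_id %in% toy$CBB$essential_genes), 3L)
  expect_equal(score_pathway(ann2$annotation_id, toy$CBB), 75)
})

test_that("marker symbols expand to their aliases; unknown symbols reject", {
  spec <- mag_spec("M1", marker_genes = c("dsrAB", "napA"), seed = 9)
  ann <- simulate_annotations(spec, defs, catalog)
  expect_true(all(c("dsrA", "dsrB", "napA") %in% ann$annotation_id))
  bad <- mag_spec("M1", marker_genes = "notAMarker", seed = 9)
  expect_error(simulate_annotations(bad, defs, catalog), "unknown marker")
})

test_that("empty spec yields annotations classified as Unidentified", {
  spec <- mag_spec("M1", seed = 8)
  ann <- simulate_annotations(spec, defs, catalog)
  presence <- detect_markers(ann, catalog, mag_ids = "M1")
  call <- assign_metabolism(presence["M1", ], mag_id = "M1")
  expect_equal(call$labels, "Unidentified")
})

test_that("ASV tables conserve depth and are reproducible under a seed", {
  t1 <- simulate_asv_table(120, "lognormal", depth = 4000, seed = 17)
  t2 <- simulate_asv_table(120, "lognormal", depth = 4000, seed = 17)
  expect_identical(t1, t2)
  expect_equal(sum(t1$count), 4000)
  expect_lte(nrow(t1), 120)
  t3 <- simulate_asv_table(80, "logseries", depth = 3000, seed = 2)
  expect_equal(sum(t3$count), 3000)
})

test_that("uniform abundances at high depth recover the true richness", {
  tab <- simulate_asv_table(50, "uniform", depth = 5000, seed = 12)
  expect_equal(nrow(tab), 50L)
})

test_that("skewed log-normal tables undersample richness and Chao1 corrects upward", {
  s_obs <- est <- numeric(50)
  for (seed in 1:50) {
    tab <- simulate_asv_table(300, "lognormal", depth = 2000, seed = seed,
                              sigma = 2.5)
    s_obs[seed] <- nrow(tab)
    est[seed] <- chao1(tab$count)
    expect_gte(est[seed], s_obs[seed])
  }
  expect_true(all(s_obs < 300))        # every replicate undersamples
  expect_gt(mean(est), mean(s_obs))    # and Chao1 corrects upward on average
})

test_that("invalid abundance-model parameters are rejected", {
  expect_error(simulate_asv_table(50, "lognormal", depth = 1000, sigma = 0),
               "sigma")
  expect_error(simulate_asv_table(50, "logseries", depth = 1000, x = 1.2),
               "log-series")
  expect_error(simulate_asv_table(100, depth = 50), "depth")
})

test_that("noiseless qPCR runs sit exactly on the theoretical line", {
  run <- simulate_qpcr_run(c(a = 1e5), efficiency_pct = 100,
                           cq_noise_sd = 0, seed = 1)
  curve <- fit_standard_curve(run$standards)
  expect_equal(round(curve$slope, 4), -3.3219)
  expect_equal(curve$efficiency_pct, 100, tolerance = 1e-6)
  q <- quantify_samples(run$samples, curve)
  expect_equal(q$mean_copies, 1e5, tolerance = 1e-9)
  expect_equal(q$sd_copies, 0, tolerance = 1e-6)
})

test_that("qPCR generator validates efficiency, standards span and copies", {
  expect_error(simulate_qpcr_run(c(a = 10), efficiency_pct = 0), "efficiency")
  expect_error(simulate_qpcr_run(c(a = 10), standards = c(10, 100, 500)),
               "decades")
  expect_error(simulate_qpcr_run(c(a = -5)), "true_copies")
})

test_that("tracer records encode rate * days / pool in the label fraction", {
  tr <- simulate_tracer_samples(0.2, ch4_pool = 100, days = 5,
                                noise_cv = 0, seed = 1, control_rate = 0)
  live <- tr[!tr$is_control, ]
  expect_equal(live$a_product / live$a_total, rep(0.01, 3))
  # zero rate -> blank product activity
  tr0 <- simulate_tracer_samples(0, noise_cv = 0, seed = 1, control_rate = 0)
  expect_equal(tr0$a_product, rep(0, 6))
  # a pool too small for the requested rate is rejected
  expect_error(simulate_tracer_samples(10, ch4_pool = 1, days = 5),
               "pool too small")
})
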