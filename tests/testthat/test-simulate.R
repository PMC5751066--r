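# Generator determinism, boundary behavior and truth consistency.

test_that("generators are pure functions of the configuration", {
  cfg <- simulation_config(seed = 9)
  a <- simulate_anchoring_inputs(cfg)
  b <- simulate_anchoring_inputs(cfg)
  expect_identical(a, b)
  ea <- simulate_expression(cfg)
  eb <- simulate_expression(cfg)
  expect_identical(ea, eb)
  ga <- simulate_go_annotations(cfg, ea$truth)
  gb <- simulate_go_annotations(cfg, eb$truth)
  expect_identical(ga, gb)
  # and generators do not disturb the caller's RNG
  withr::local_seed(1)
  r1 <- stats::runif(1)
  withr::local_seed(1)
  invisible(simulate_expression(cfg))
  expect_identical(stats::runif(1), r1)
})

test_that("no-rearrangement limit gives identical gene orders and identity homology", {
  cfg <- simulation_config(seed = 2, translocation_rate = 0,
                           inversion_rate = 0)
  pair <- simulate_genome_pair(cfg)
  expect_equal(sub("LG", "chr", pair$genes$study_chrom), pair$genes$ref_chrom)
  expect_equal(pair$genes$study_start, pair$genes$ref_start)
  expect_true(all(pair$genes$study_strand == "+"))
  expect_equal(sub("LG", "chr", pair$homology$rh_group),
               pair$homology$ref_chromosome)
})

test_that("full translocation re-draws chromosomes but keeps the table 1-to-1", {
  cfg <- simulation_config(seed = 4, translocation_rate = 1)
  pair <- simulate_genome_pair(cfg)
  expect_equal(nrow(pair$homology), cfg$n_chromosomes)
  expect_silent(synanchor:::validate_homology_table(pair$homology))
  # with 200 genes redrawn uniformly over 4 chromosomes, agreement ~ 1/4
  agree <- mean(sub("LG", "chr", pair$genes$study_chrom) ==
                  pair$genes$ref_chrom)
  expect_lt(agree, 0.40)
  expect_gt(agree, 0.12)
})

test_that("fragmentation conserves chromosome sequences and truth is complete", {
  cfg <- simulation_config(seed = 6)
  pair <- simulate_genome_pair(cfg)
  frag <- fragment_genome(pair, cfg)
  expect_setequal(frag$truth$scaffold_id, frag$scaffolds$id)
  for (ch in pair$study_sequences$id) {
    tr <- frag$truth[frag$truth$true_group == ch, ]
    tr <- tr[order(tr$true_order), ]
    seqs <- frag$scaffolds$sequence[match(tr$scaffold_id, frag$scaffolds$id)]
    flip <- tr$true_orientation == "-"
    seqs[flip] <- reverse_complement(seqs[flip])
    expect_identical(paste0(seqs, collapse = ""),
                     pair$study_sequences$sequence[
                       pair$study_sequences$id == ch])
  }
  # n50 target beyond chromosome length: one scaffold per chromosome
  big <- simulation_config(seed = 6, scaffold_n50_target = 10000000L)
  frag1 <- fragment_genome(simulate_genome_pair(big), big)
  expect_equal(nrow(frag1$scaffolds), big$n_chromosomes)
})

test_that("noise-free alignments are truth-consistent and parse losslessly", {
  cfg <- simulation_config(seed = 8, translocation_rate = 0,
                           inversion_rate = 0, false_hit_rate = 0)
  inp <- simulate_anchoring_inputs(cfg)
  truth_group <- stats::setNames(inp$truth$true_group, inp$truth$scaffold_id)
  # every marker hit lands on a scaffold of the marker's own group
  mk_group <- stats::setNames(inp$rh_map$rh_group, inp$rh_map$marker_id)
  expect_true(all(truth_group[inp$marker_hits$subject_id] ==
                    mk_group[inp$marker_hits$query_id]))
  # every scaffold hit points at the homologous reference chromosome
  expect_true(all(inp$ref_hits$subject_id ==
                    sub("LG", "chr", truth_group[inp$ref_hits$query_id])))
  expect_true(all(inp$marker_hits$e_value < 1e-12))

  path <- withr::local_tempfile()
  write_alignment_tabular(inp$ref_hits, path)
  back <- read_alignment_tabular(path)
  rownames(back) <- rownames(inp$ref_hits) <- NULL
  expect_identical(back, inp$ref_hits)
})

test_that("full hit noise leaves roughly 1/n_chromosomes truth-consistent", {
  cfg <- simulation_config(seed = 12, translocation_rate = 0,
                           inversion_rate = 0, false_hit_rate = 1)
  inp <- simulate_anchoring_inputs(cfg)
  truth_group <- stats::setNames(inp$truth$true_group, inp$truth$scaffold_id)
  consistent <- mean(inp$ref_hits$subject_id ==
                       sub("LG", "chr", truth_group[inp$ref_hits$query_id]))
  n <- nrow(inp$ref_hits)
  # binomial 95% bounds around 1/4
  expect_lt(abs(consistent - 0.25), 1.96 * sqrt(0.25 * 0.75 / n) + 0.02)
})

test_that("RH panel samples the configured number of markers in true order", {
  cfg <- simulation_config(seed = 14)
  pair <- simulate_genome_pair(cfg)
  panel <- simulate_rh_panel(pair, cfg)
  expect_equal(nrow(panel$rh_map),
               cfg$markers_per_group * cfg$n_chromosomes)
  for (lg in unique(panel$rh_map$rh_group)) {
    mk <- panel$rh_map[panel$rh_map$rh_group == lg, ]
    starts <- pair$genes$study_start[match(mk$marker_id, pair$genes$gene_id)]
    expect_true(all(diff(starts[order(mk$position_index)]) > 0))
  }
})

test_that("expression effects hit the configured fold change on average", {
  cfg <- simulation_config(seed = 16, nb_dispersion = 0.001)
  sim <- simulate_expression(cfg)
  de <- sim$truth$true_direction != "none"
  ia <- which(sim$condition == "A")
  ib <- which(sim$condition == "B")
  ratio <- rowMeans(sim$counts[de & sim$truth$true_lfc > 0, ia]) /
    rowMeans(sim$counts[de & sim$truth$true_lfc > 0, ib])
  expect_equal(mean(ratio), 16, tolerance = 0.2)
  none <- sim$truth$true_direction == "none"
  expect_equal(sum(filter_de(sim$de_table)$up_in_a %in%
                     sim$truth$feature_id[none]), 0)
  no_de <- simulate_expression(simulation_config(seed = 16, de_fraction = 0))
  expect_true(all(no_de$truth$true_direction == "none"))
})

test_that("spiked annotation rates scale with the configured fold", {
  cfg <- simulation_config(seed = 18, n_features_expr = 2000L)
  truth <- data.frame(
    feature_id = sprintf("t%05d", 1:2000),
    true_direction = rep(c("up_in_a", "none"), c(500, 1500)),
    stringsAsFactors = FALSE)
  go <- simulate_go_annotations(cfg, truth)
  expect_length(go$spiked_terms, 2L)
  is_de <- truth$true_direction != "none"
  for (tm in go$spiked_terms) {
    annotated <- truth$feature_id %in%
      go$annotations$feature_id[go$annotations$term == tm]
    rate_de <- mean(annotated[is_de])
    expect_equal(rate_de, min(1, cfg$spike_fold * cfg$baseline_term_prob),
                 tolerance = 0.25)
    rate_null <- mean(annotated[!is_de])
    expect_equal(rate_null, cfg$baseline_term_prob, tolerance = 0.35)
  }
  flat <- simulate_go_annotations(
    simulation_config(seed = 18, spike_fold = 1), truth)
  tm <- flat$spiked_terms[1]
  annotated <- truth$feature_id %in%
    flat$annotations$feature_id[flat$annotations$term == tm]
  expect_equal(mean(annotated[is_de]), mean(annotated[!is_de]),
               tolerance = 0.3)
})
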