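# Homology lookup, reconciliation, ordering, concatenation, lift-over and
# transcript-to-group assignment.

test_that("homology lookup works in both directions on the packaged table", {
  h <- seriola_homology_table()
  expect_equal(nrow(h), 24L)
  expect_equal(homology_lookup(h, "SQ12"), "OL8")
  expect_equal(homology_lookup(h, "OL5"), "SQ1")
  expect_equal(homology_lookup(h, "SQ24"), "OL7")
  expect_error(homology_lookup(h, "SQ25"), "unknown label")
})

test_that("reconciliation routes evidence combinations to the right status", {
  h <- seriola_homology_table()
  ev <- data.frame(
    scaffold_id = c("dual", "refonly", "rhonly", "clash", "nothing", "tied"),
    rh_winner = c("SQ12", NA, "SQ12", "SQ12", NA, "SQ1"),
    rh_mass = c(100, NA, 100, 100, NA, 50),
    rh_min_rank = c(3L, NA, 5L, 3L, NA, 1L),
    rh_tie = c(FALSE, NA, FALSE, FALSE, NA, TRUE),
    ref_chromosome = c("OL8", "OL8", NA, "OL5", NA, "OL5"),
    ref_position = c(1000L, 2000L, NA, 3000L, NA, 10L),
    ref_strand = c("+", "-", NA, "+", NA, "+"),
    ref_score_mass = c(500, 400, NA, 300, NA, 100),
    ref_ambiguous = c(FALSE, FALSE, NA, FALSE, NA, FALSE),
    stringsAsFactors = FALSE)
  p <- reconcile_placements(ev, h)
  expect_equal(stats::setNames(p$status, p$scaffold_id),
               c(dual = "placed_dual", refonly = "placed_ref_only",
                 rhonly = "placed_rh_only", clash = "conflict",
                 nothing = "unplaced", tied = "conflict"))
  expect_equal(p$group[p$scaffold_id == "dual"], "SD12")
  expect_equal(p$group[p$scaffold_id == "refonly"], "SD12")
  expect_equal(p$group[p$scaffold_id == "rhonly"], "SD12")
  expect_true(is.na(p$group[p$scaffold_id == "clash"]))
  expect_equal(p$orientation[p$scaffold_id == "rhonly"], "+")
  # partition property: every scaffold gets exactly one status
  expect_equal(sort(table(p$status), decreasing = TRUE),
               sort(table(c("placed_dual", "placed_ref_only",
                            "placed_rh_only", "conflict", "conflict",
                            "unplaced")), decreasing = TRUE))
})

test_that("scaffold ordering sorts by position with stated tie-breaks", {
  pl <- data.frame(scaffold_id = c("a", "b", "c"), status = "placed_dual",
                   group = "SD1", order_key = c(5000, 1200, 300),
                   rh_rank = NA_integer_, orientation = "+",
                   stringsAsFactors = FALSE)
  expect_equal(order_scaffolds(pl)$scaffold_id, c("c", "b", "a"))

  tie <- pl
  tie$order_key <- 100
  expect_equal(order_scaffolds(tie, c(a = 80L, b = 200L, c = 80L))$scaffold_id,
               c("b", "a", "c"))

  mixed <- pl
  mixed$order_key[2] <- NA
  mixed$status[2] <- "placed_rh_only"
  mixed$rh_rank[2] <- 0L
  expect_equal(order_scaffolds(mixed)$scaffold_id, c("c", "a", "b"))

  bad <- pl
  bad$group[2] <- "SD2"
  expect_error(order_scaffolds(bad), "more than one group")
})

test_that("concatenation joins, gaps and reverse-complements correctly", {
  seqs <- data.frame(id = c("s1", "s2"), description = "",
                     sequence = c(strrep("A", 100), "AACG"),
                     stringsAsFactors = FALSE)
  pl <- data.frame(scaffold_id = c("s1", "s2"), status = "placed_dual",
                   group = "SD1", order_key = c(1, 2), rh_rank = NA_integer_,
                   orientation = c("+", "-"), stringsAsFactors = FALSE)
  built <- concatenate_group(order_scaffolds(pl), seqs, gap_length = 100L)
  expect_equal(nchar(built$sequence$sequence), 204L)
  expect_equal(built$index$offset, c(0L, 200L))
  expect_equal(substr(built$sequence$sequence, 201, 204), "CGTT")
  expect_equal(substr(built$sequence$sequence, 101, 200), strrep("N", 100))

  single <- concatenate_group(order_scaffolds(pl[1, ]), seqs, 100L)
  expect_equal(single$sequence$sequence, strrep("A", 100))
  expect_equal(nrow(single$agp), 1L)

  expect_error(concatenate_group(order_scaffolds(pl), seqs[1, ], 100L),
               "no sequence")
})

test_that("group sequence length equals the AGP object_end of its last record", {
  withr::local_seed(3)
  inp <- simulate_anchoring_inputs(simulation_config(
    seed = 3, translocation_rate = 0, inversion_rate = 0))
  res <- anchor_pipeline(inp$scaffolds, inp$marker_hits, inp$ref_hits,
                         inp$rh_map, inp$homology)
  for (i in seq_len(nrow(res$fasta))) {
    g <- res$fasta$id[[i]]
    agp_g <- res$agp[res$agp$object_id == g, ]
    expect_equal(nchar(res$fasta$sequence[[i]]), max(agp_g$object_end))
  }
  # partition invariant over the whole input
  expect_equal(nrow(res$all_placements), nrow(inp$scaffolds))
  expect_true(all(res$all_placements$status %in%
                    c("placed_dual", "placed_ref_only", "placed_rh_only",
                      "conflict", "unplaced")))
})

test_that("lift-over maps forward/reverse scaffolds and rejects gap positions", {
  index <- data.frame(scaffold_id = c("s1", "s2"), offset = c(0L, 200L),
                      length = c(100L, 50L), orientation = c("+", "-"),
                      stringsAsFactors = FALSE)
  expect_equal(lift_to_group(index, "s2", 10L), 200L + (50L - 1L - 10L))
  expect_equal(lift_to_group(index, "s2", 0L), 249L)
  expect_equal(lift_to_group(index, "s1", 10L), 10L)
  expect_error(lift_to_group(index, "sX", 0L), "not in this group")
  expect_error(lift_to_group(index, "s1", 100L), "outside scaffold")

  expect_error(lift_to_scaffold(index, 150L), "gap") # gap spans [100,200)
  expect_error(lift_to_scaffold(index, 400L), "outside the group")
  back <- lift_to_scaffold(index, 249L)
  expect_equal(back$scaffold_id, "s2")
  expect_equal(back$position, 0L)
})

test_that("transcript assignment is unique, counted, and tie-broken by string order", {
  hits <- make_hits(
    make_hit("t1", "SD12", bit = 100, identity = 100, evalue = 0),
    make_hit("t2", "SD12", bit = 100, identity = 100, evalue = 0),
    make_hit("t3", "SD12", bit = 100, identity = 100, evalue = 0),
    make_hit("t4", "SD3", bit = 90, identity = 100, evalue = 0),
    make_hit("t4", "SD12", bit = 100, identity = 100, evalue = 0))
  m <- map_transcripts_to_groups(hits)
  expect_equal(m$counts$n_transcripts[m$counts$group == "SD12"], 4L)
  expect_false("t5" %in% m$assignments$transcript_id)

  # equal-score hits on SD3 and SD12: "SD12" < "SD3" in string order
  tie <- make_hits(make_hit("tx", "SD3", bit = 100, identity = 100, evalue = 0),
                   make_hit("tx", "SD12", bit = 100, identity = 100, evalue = 0))
  # brute-force oracle on the 2-hit instance
  oracle <- sort(c("SD3", "SD12"))[1]
  expect_equal(map_transcripts_to_groups(tie)$assignments$group, oracle)
  expect_equal(oracle, "SD12")
})
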