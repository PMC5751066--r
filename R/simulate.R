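# Synthetic-data generators. Every pipeline input can be produced with
# known ground truth: a pair of diverged karyotypes with 1-to-1 chromosome
# homology, fragmentation of the study genome into scaffolds, noisy tabular
# alignments, an RH marker panel, negative-binomial count matrices with
# spiked effects, and GO annotations with enriched terms. Every generator
# is a pure function of its configuration: the same seed gives bit-identical
# output, and the caller's RNG state is left untouched.

#' Simulation configuration
#'
#' Defaults define a desk-scale study: 4 chromosomes of 50 genes, mild
#' rearrangement between the two karyotypes, noise-free alignments, a
#' 10-marker panel per group, a 2000-feature expression matrix with 5% true
#' effects of |log2FC| = 4 at negative-binomial dispersion 0.1, and 100 GO
#' terms of which 2 are spiked 6-fold in the true-effect features.
#'
#' @param seed Integer seed; mandatory, drives every generator.
#' @param n_chromosomes Chromosomes per karyotype.
#' @param genes_per_chromosome Genes per chromosome.
#' @param gene_length,intergenic_length Gene and spacer sizes in bases.
#' @param translocation_rate Per-gene probability of moving to a random
#'   chromosome in the study karyotype.
#' @param inversion_rate Per-chromosome probability of one segment
#'   inversion.
#' @param scaffold_n50_target Target scaffold length scale in bases.
#' @param min_scaffold_length Smallest scaffold emitted by fragmentation.
#' @param false_hit_rate Probability an alignment hit is redirected to a
#'   uniformly random wrong location.
#' @param markers_per_group RH markers sampled per group.
#' @param n_features_expr Features in the count matrix.
#' @param n_per_condition Samples per condition (two conditions).
#' @param de_fraction Fraction of features with a true effect.
#' @param lfc_magnitude True |log2FC| of affected features.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param n_go_terms Number of GO terms.
#' @param baseline_term_prob Per-feature-term annotation probability.
#' @param spiked_terms Number of terms spiked in true-effect features.
#' @param spike_fold Annotation-probability multiplier for spiked terms.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 4L,
                              genes_per_chromosome = 50L,
                              gene_length = 1000L,
                              intergenic_length = 500L,
                              translocation_rate = 0.02,
                              inversion_rate = 0.1,
                              scaffold_n50_target = 10000L,
                              min_scaffold_length = 200L,
                              false_hit_rate = 0,
                              markers_per_group = 10L,
                              n_features_expr = 2000L,
                              n_per_condition = 4L,
                              de_fraction = 0.05,
                              lfc_magnitude = 4,
                              nb_dispersion = 0.1,
                              n_go_terms = 100L,
                              baseline_term_prob = 0.05,
                              spiked_terms = 2L,
                              spike_fold = 6) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_chromosomes >= 1L, genes_per_chromosome >= 1L,
            translocation_rate >= 0, translocation_rate <= 1,
            inversion_rate >= 0, inversion_rate <= 1,
            false_hit_rate >= 0, false_hit_rate <= 1,
            de_fraction >= 0, de_fraction <= 1,
            baseline_term_prob > 0, baseline_term_prob <= 1,
            spike_fold >= 0, nb_dispersion >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# run code under a deterministic RNG stream derived from (cfg$seed, offset)
# without disturbing the caller's RNG
with_sim_seed <- function(cfg, offset, code) {
  withr::with_seed(as.integer((cfg$seed * 131L + offset) %% .Machine$integer.max),
                   code)
}

random_sequence <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a pair of diverged karyotypes
#'
#' Two genomes with identical gene content and a 1-to-1 chromosome homology
#' (study group `LG<i>` corresponds to reference chromosome `chr<i>`). The
#' study gene order starts as a copy of the reference order; each gene then
#' moves to a uniformly random study chromosome with probability
#' `translocation_rate`, and each study chromosome has one contiguous
#' segment inverted with probability `inversion_rate`. Gene coordinates on
#' both karyotypes are laid out with fixed gene and spacer lengths.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genes` (data frame: `gene_id`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `study_chrom`, `study_start`, `study_end`,
#'   `study_strand` — all 1-based inclusive), `homology` (data frame
#'   `rh_group`, `ref_chromosome`), `study_chrom_lengths` (named vector) and
#'   `study_sequences` (FASTA data frame of the study chromosomes).
#' @export
simulate_genome_pair <- function(cfg) {
  with_sim_seed(cfg, 1L, {
    C <- cfg$n_chromosomes
    G <- cfg$genes_per_chromosome
    step <- cfg$gene_length + cfg$intergenic_length
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(C * G)),
      ref_chrom = paste0("chr", rep(seq_len(C), each = G)),
      stringsAsFactors = FALSE)
    within_ref <- rep(seq_len(G), times = C)
    genes$ref_start <- (within_ref - 1L) * step + 1L
    genes$ref_end <- genes$ref_start + cfg$gene_length - 1L

    # study karyotype: start homologous, then translocate
    study_idx <- rep(seq_len(C), each = G)
    move <- stats::runif(C * G) < cfg$translocation_rate
    study_idx[move] <- sample.int(C, sum(move), replace = TRUE)
    genes$study_chrom <- paste0("LG", study_idx)
    genes$study_strand <- "+"

    # per-chromosome gene order on the study genome follows reference order
    # of the genes assigned there; optional single segment inversion
    genes$study_order <- NA_integer_
    genes$study_start <- NA_integer_
    for (ci in seq_len(C)) {
      on_c <- which(study_idx == ci)
      ord <- on_c[order(genes$ref_chrom[on_c], genes$ref_start[on_c])]
      if (length(ord) > 1L && stats::runif(1) < cfg$inversion_rate) {
        ends <- sort(sample.int(length(ord), 2L))
        seg <- seq.int(ends[[1L]], ends[[2L]])
        ord[seg] <- rev(ord[seg])
        genes$study_strand[ord[seg]] <- "-"
      }
      genes$study_order[ord] <- seq_along(ord)
      genes$study_start[ord] <- (seq_along(ord) - 1L) * step + 1L
    }
    genes$study_end <- genes$study_start + cfg$gene_length - 1L

    chrom_lengths <- vapply(seq_len(C), function(ci) {
      n_on <- sum(study_idx == ci)
      max(n_on, 1L) * step
    }, numeric(1))
    names(chrom_lengths) <- paste0("LG", seq_len(C))
    study_sequences <- data.frame(
      id = names(chrom_lengths), description = "",
      sequence = vapply(chrom_lengths, random_sequence, character(1)),
      stringsAsFactors = FALSE)
    homology <- data.frame(rh_group = paste0("LG", seq_len(C)),
                           ref_chromosome = paste0("chr", seq_len(C)),
                           stringsAsFactors = FALSE)
    list(genes = genes, homology = homology,
         study_chrom_lengths = chrom_lengths,
         study_sequences = study_sequences)
  })
}

#' Fragment the study karyotype into scaffolds
#'
#' Cuts each study chromosome at random positions into scaffolds whose
#' expected length is `scaffold_n50_target`, applies a random strand flip to
#' half of them (recorded), and emits the scaffold sequences plus the ground
#' truth needed by recovery tests. Concatenating the truth-ordered,
#' truth-oriented scaffolds reconstructs each chromosome exactly.
#'
#' @param pair Output of [simulate_genome_pair()].
#' @param cfg The same [simulation_config()].
#' @return List with `scaffolds` (FASTA data frame) and `truth` (data frame
#'   `scaffold_id`, `true_group`, `true_order`, `true_orientation`,
#'   `chrom_start`, `chrom_end` — 1-based span on the study chromosome).
#' @export
fragment_genome <- function(pair, cfg) {
  with_sim_seed(cfg, 2L, {
    truth <- list()
    seqs <- list()
    sn <- 0L
    for (i in seq_len(nrow(pair$study_sequences))) {
      chrom <- pair$study_sequences$id[[i]]
      seq <- pair$study_sequences$sequence[[i]]
      len <- nchar(seq)
      n_cuts <- max(0L, as.integer(round(len / cfg$scaffold_n50_target)) - 1L)
      cuts <- integer(0)
      if (n_cuts > 0L) {
        eligible <- seq.int(cfg$min_scaffold_length,
                            len - cfg$min_scaffold_length)
        cuts <- sort(sample(eligible, min(n_cuts, length(eligible))))
      }
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, len)
      for (k in seq_along(starts)) {
        sn <- sn + 1L
        sid <- sprintf("scf%04d", sn)
        flip <- stats::runif(1) < 0.5
        frag <- substr(seq, starts[[k]], ends[[k]])
        seqs[[sn]] <- data.frame(
          id = sid, description = "",
          sequence = if (flip) reverse_complement(frag) else frag,
          stringsAsFactors = FALSE)
        truth[[sn]] <- data.frame(
          scaffold_id = sid, true_group = chrom, true_order = k,
          true_orientation = if (flip) "-" else "+",
          chrom_start = starts[[k]], chrom_end = ends[[k]],
          stringsAsFactors = FALSE)
      }
    }
    list(scaffolds = do.call(rbind, seqs), truth = do.call(rbind, truth))
  })
}

# map a study-chromosome interval to (scaffold, scaffold-local 1-based
# coords, strand relative to the scaffold as stored)
.locate_on_scaffold <- function(truth, chrom, start, end) {
  rows <- truth[truth$true_group == chrom &
                  truth$chrom_start <= end & truth$chrom_end >= start, ,
                drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(j) {
    r <- rows[j, ]
    s <- max(start, r$chrom_start) - r$chrom_start + 1L
    e <- min(end, r$chrom_end) - r$chrom_start + 1L
    slen <- r$chrom_end - r$chrom_start + 1L
    if (r$true_orientation == "-") {
      tmp <- slen - e + 1L
      e <- slen - s + 1L
      s <- tmp
      strand <- "-"
    } else {
      strand <- "+"
    }
    data.frame(scaffold_id = r$scaffold_id, q_start = s, q_end = e,
               strand = strand,
               chrom_start = max(start, r$chrom_start),
               chrom_end = min(end, r$chrom_end), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate tabular alignments for markers and scaffolds
#'
#' Emits the two alignment channels the anchoring pipeline consumes:
#' markers vs scaffolds, and scaffolds vs reference chromosomes (one hit per
#' gene portion a scaffold carries, with subject coordinates at the gene's
#' reference location and strand composed from the scaffold flip and any
#' segment inversion). E-values are drawn log-uniform below 1e-12 and bit
#' scores are proportional to match length (2 bits/base). With probability
#' `false_hit_rate` a hit is redirected to a uniformly random chromosome and
#' position.
#'
#' @param pair Output of [simulate_genome_pair()].
#' @param frag Output of [fragment_genome()].
#' @param rh_panel Output of [simulate_rh_panel()].
#' @param cfg The same [simulation_config()].
#' @return List with `marker_hits` and `ref_hits` (alignment data frames in
#'   the layout of [read_alignment_tabular()]).
#' @export
simulate_alignments <- function(pair, frag, rh_panel, cfg) {
  with_sim_seed(cfg, 3L, {
    genes <- pair$genes
    truth <- frag$truth
    rand_eval <- function(n) 10^stats::runif(n, -50, -12.5)

    # --- marker hits: marker sequence vs the scaffold carrying the gene ---
    mk <- merge(rh_panel$rh_map, genes, by.x = "marker_id", by.y = "gene_id")
    marker_rows <- list()
    for (j in seq_len(nrow(mk))) {
      loc <- .locate_on_scaffold(truth, mk$study_chrom[[j]],
                                 mk$study_start[[j]], mk$study_end[[j]])
      if (is.null(loc) || nrow(loc) == 0L) next
      loc <- loc[which.max(loc$chrom_end - loc$chrom_start), , drop = FALSE]
      qlen <- loc$chrom_end - loc$chrom_start + 1L
      subj <- loc$scaffold_id
      ss <- loc$q_start
      se <- loc$q_end
      if (loc$strand == "-") { tmp <- ss; ss <- se; se <- tmp }
      if (stats::runif(1) < cfg$false_hit_rate) {
        subj <- sample(truth$scaffold_id, 1L)
        slen <- nchar(frag$scaffolds$sequence[
          match(subj, frag$scaffolds$id)])
        ss <- sample.int(max(1L, slen - qlen + 1L), 1L)
        se <- min(slen, ss + qlen - 1L)
      }
      marker_rows[[length(marker_rows) + 1L]] <- data.frame(
        query_id = mk$marker_id[[j]], subject_id = subj,
        percent_identity = 100, alignment_length = qlen, mismatches = 0L,
        gap_opens = 0L, q_start = 1L, q_end = qlen,
        s_start = as.integer(ss), s_end = as.integer(se),
        e_value = rand_eval(1), bit_score = round(2 * qlen, 1),
        stringsAsFactors = FALSE)
    }
    marker_hits <- if (length(marker_rows)) do.call(rbind, marker_rows) else
      empty_alignment_table()

    # --- scaffold hits: each gene portion on a scaffold hits the gene's ---
    # --- reference location ---
    ref_rows <- list()
    for (j in seq_len(nrow(genes))) {
      loc <- .locate_on_scaffold(truth, genes$study_chrom[[j]],
                                 genes$study_start[[j]], genes$study_end[[j]])
      if (is.null(loc) || nrow(loc) == 0L) next
      for (m in seq_len(nrow(loc))) {
        piece <- loc[m, ]
        plen <- piece$q_end - piece$q_start + 1L
        # reference span of the covered gene portion
        off0 <- piece$chrom_start - genes$study_start[[j]]
        off1 <- piece$chrom_end - genes$study_start[[j]]
        if (genes$study_strand[[j]] == "-") {
          rs <- genes$ref_end[[j]] - off1
          re <- genes$ref_end[[j]] - off0
        } else {
          rs <- genes$ref_start[[j]] + off0
          re <- genes$ref_start[[j]] + off1
        }
        subj <- genes$ref_chrom[[j]]
        # hit strand = scaffold flip XOR study-segment inversion
        minus <- xor(piece$strand == "-", genes$study_strand[[j]] == "-")
        ss <- if (minus) re else rs
        se <- if (minus) rs else re
        if (stats::runif(1) < cfg$false_hit_rate) {
          subj <- paste0("chr", sample.int(cfg$n_chromosomes, 1L))
          clen <- cfg$genes_per_chromosome *
            (cfg$gene_length + cfg$intergenic_length)
          ss <- sample.int(max(1L, clen - plen + 1L), 1L)
          se <- ss + plen - 1L
        }
        ref_rows[[length(ref_rows) + 1L]] <- data.frame(
          query_id = piece$scaffold_id, subject_id = subj,
          percent_identity = 100, alignment_length = plen, mismatches = 0L,
          gap_opens = 0L, q_start = piece$q_start, q_end = piece$q_end,
          s_start = as.integer(ss), s_end = as.integer(se),
          e_value = rand_eval(1), bit_score = round(2 * plen, 1),
          stringsAsFactors = FALSE)
      }
    }
    ref_hits <- if (length(ref_rows)) do.call(rbind, ref_rows) else
      empty_alignment_table()
    list(marker_hits = marker_hits, ref_hits = ref_hits)
  })
}

#' Simulate an RH marker panel
#'
#' Samples `markers_per_group` genes per study chromosome as markers; ranks
#' within a group follow the true gene order along the chromosome.
#'
#' @param pair Output of [simulate_genome_pair()].
#' @param cfg The same [simulation_config()].
#' @return List with `rh_map` (data frame `marker_id`, `rh_group`,
#'   `position_index`).
#' @export
simulate_rh_panel <- function(pair, cfg) {
  with_sim_seed(cfg, 4L, {
    rows <- list()
    for (ci in seq_len(cfg$n_chromosomes)) {
      lg <- paste0("LG", ci)
      on_c <- pair$genes[pair$genes$study_chrom == lg, , drop = FALSE]
      on_c <- on_c[order(on_c$study_start), , drop = FALSE]
      take <- sort(sample.int(nrow(on_c),
                              min(cfg$markers_per_group, nrow(on_c))))
      rows[[ci]] <- data.frame(marker_id = on_c$gene_id[take],
                               rh_group = lg,
                               position_index = seq_along(take) - 1L,
                               stringsAsFactors = FALSE)
    }
    list(rh_map = do.call(rbind, rows))
  })
}

#' Simulate a count matrix with known effects and a stand-in DE table
#'
#' Baseline means are log-normal; counts are negative-binomial with
#' dispersion `nb_dispersion`. A fraction `de_fraction` of features receive
#' a true effect of `± lfc_magnitude` log2 units in condition A (half up,
#' half down). The companion DE table is computed by a simple two-group
#' Welch t-test on log2(count + 1) with BH adjustment — an explicitly
#' labeled stand-in for a count-model fit, adequate for exercising the
#' filtering stage but not a negative-binomial GLM.
#'
#' @param cfg A [simulation_config()].
#' @return List with `counts` (matrix, features x samples), `condition`
#'   (factor `A`/`B` per sample), `de_table` (data frame in the layout of
#'   [read_de_table()]) and `truth` (data frame `feature_id`,
#'   `true_direction` in `up_in_a` / `up_in_b` / `none`, `true_lfc`).
#' @export
simulate_expression <- function(cfg) {
  with_sim_seed(cfg, 5L, {
    n <- cfg$n_features_expr
    reps <- cfg$n_per_condition
    feature_id <- sprintf("t%05d", seq_len(n))
    base_mu <- stats::rlnorm(n, meanlog = log(500), sdlog = 1)
    n_de <- as.integer(round(cfg$de_fraction * n))
    true_lfc <- rep(0, n)
    if (n_de > 0L) {
      half <- n_de %/% 2L
      true_lfc[seq_len(n_de)] <- rep(c(1, -1), length.out = n_de) *
        cfg$lfc_magnitude
    }
    mu_a <- base_mu * 2^true_lfc
    mu_b <- base_mu
    size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
    draw <- function(mu) {
      if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
      else stats::rpois(n, lambda = mu)
    }
    counts <- cbind(
      matrix(unlist(lapply(seq_len(reps), function(i) draw(mu_a))), ncol = reps),
      matrix(unlist(lapply(seq_len(reps), function(i) draw(mu_b))), ncol = reps))
    dimnames(counts) <- list(feature_id,
                             c(paste0("A", seq_len(reps)),
                               paste0("B", seq_len(reps))))
    condition <- factor(rep(c("A", "B"), each = reps))

    lg <- log2(counts + 1)
    ia <- which(condition == "A")
    ib <- which(condition == "B")
    lfc_hat <- rowMeans(lg[, ia, drop = FALSE]) -
      rowMeans(lg[, ib, drop = FALSE])
    pvals <- welch_p(lg[, ia, drop = FALSE], lg[, ib, drop = FALSE])
    de_table <- data.frame(feature_id = feature_id,
                           log2_fold_change = lfc_hat,
                           p_value = pvals,
                           p_adjusted = stats::p.adjust(pvals, "BH"),
                           stringsAsFactors = FALSE)
    truth <- data.frame(
      feature_id = feature_id,
      true_direction = ifelse(true_lfc > 0, "up_in_a",
                              ifelse(true_lfc < 0, "up_in_b", "none")),
      true_lfc = true_lfc, stringsAsFactors = FALSE)
    rownames(de_table) <- NULL
    list(counts = counts, condition = condition, de_table = de_table,
         truth = truth)
  })
}

# row-wise Welch t-test p-values; degenerate rows (zero variance in both
# groups) get p = 1 when the means agree and p = 0 otherwise
welch_p <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)
  p[is.na(p)] <- 1
  p
}

#' Simulate GO annotations with spiked terms
#'
#' Baseline annotation is Bernoulli per feature-term pair; `spiked_terms`
#' terms are assigned to true-effect features at `spike_fold` times the
#' baseline probability (capped at 1).
#'
#' @param cfg A [simulation_config()].
#' @param de_truth Truth table from [simulate_expression()] (its
#'   `true_direction` column marks the spiking targets); `NULL` disables
#'   spiking regardless of `cfg$spiked_terms`.
#' @return List with `annotations` (long data frame `feature_id`, `term`)
#'   and `spiked_terms` (character vector of spiked term ids).
#' @export
simulate_go_annotations <- function(cfg, de_truth = NULL) {
  with_sim_seed(cfg, 6L, {
    feats <- if (is.null(de_truth)) sprintf("t%05d", seq_len(cfg$n_features_expr))
      else de_truth$feature_id
    terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
    is_de <- if (is.null(de_truth)) rep(FALSE, length(feats)) else
      de_truth$true_direction != "none"
    n_spike <- if (is.null(de_truth)) 0L else
      min(cfg$spiked_terms, cfg$n_go_terms)
    spiked <- terms[seq_len(n_spike)]
    prob <- matrix(cfg$baseline_term_prob, nrow = length(feats),
                   ncol = length(terms))
    if (n_spike > 0L) {
      prob[is_de, seq_len(n_spike)] <-
        min(1, cfg$spike_fold * cfg$baseline_term_prob)
    }
    hit <- matrix(stats::runif(length(prob)) < prob, nrow = nrow(prob))
    idx <- which(hit, arr.ind = TRUE)
    ann <- data.frame(feature_id = feats[idx[, 1L]], term = terms[idx[, 2L]],
                      stringsAsFactors = FALSE)
    ann <- ann[order(ann$feature_id, ann$term), , drop = FALSE]
    rownames(ann) <- NULL
    list(annotations = ann, spiked_terms = spiked)
  })
}

#' Generate every anchoring input with ground truth
#'
#' Convenience wrapper running [simulate_genome_pair()],
#' [fragment_genome()], [simulate_rh_panel()] and [simulate_alignments()].
#'
#' @param cfg A [simulation_config()].
#' @return List with `scaffolds`, `marker_hits`, `ref_hits`, `rh_map`,
#'   `homology`, `truth`, `pair`.
#' @export
simulate_anchoring_inputs <- function(cfg) {
  pair <- simulate_genome_pair(cfg)
  frag <- fragment_genome(pair, cfg)
  panel <- simulate_rh_panel(pair, cfg)
  aln <- simulate_alignments(pair, frag, panel, cfg)
  list(scaffolds = frag$scaffolds, marker_hits = aln$marker_hits,
       ref_hits = aln$ref_hits, rh_map = panel$rh_map,
       homology = pair$homology, truth = frag$truth, pair = pair)
}

#' Score anchoring recovery against simulator truth
#'
#' @param result An [anchor_pipeline()] result.
#' @param truth Truth table from [fragment_genome()].
#' @param homology The simulator homology table (maps true study groups to
#'   output group names through the group number).
#' @param prefix Output prefix used by the pipeline (default `"SD"`).
#' @return List with `group_accuracy` (fraction of placed scaffolds whose
#'   group matches truth), `mean_kendall_tau` (within-group rank correlation
#'   of recovered vs true order, averaged over groups with at least 2
#'   correctly placed scaffolds) and `n_placed`.
#' @export
score_anchoring <- function(result, truth, homology, prefix = "SD") {
  placed <- result$placements
  if (is.null(placed) || nrow(placed) == 0L) {
    return(list(group_accuracy = NA_real_, mean_kendall_tau = NA_real_,
                n_placed = 0L))
  }
  truth_group_out <- paste0(prefix, sub("^[A-Za-z]+", "", truth$true_group))
  names(truth_group_out) <- truth$scaffold_id
  correct <- placed$group == truth_group_out[placed$scaffold_id]
  taus <- c()
  for (g in names(result$indexes)) {
    ix <- result$indexes[[g]]
    ok <- ix$scaffold_id[truth_group_out[ix$scaffold_id] == g]
    if (length(ok) < 2L) next
    rec_rank <- match(ok, ix$scaffold_id)
    true_rank <- truth$true_order[match(ok, truth$scaffold_id)]
    taus <- c(taus, stats::cor(rec_rank, true_rank, method = "kendall"))
  }
  list(group_accuracy = mean(correct),
       mean_kendall_tau = if (length(taus)) mean(taus) else NA_real_,
       n_placed = nrow(placed))
}
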