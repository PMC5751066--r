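# Per-scaffold homology evidence: marker-derived linkage-group votes and
# reference-chromosome assignments. Evidence strength is bit score
# throughout: it is additive and length-aware, unlike e-value or identity.

#' Evidence filtering thresholds
#'
#' Defaults follow the anchoring protocol this package implements: markers
#' are kept below a stringent e-value of 1e-10 (strict `<`), and transcript
#' placements require perfect identity (>= 100%) at e-value 0 (<=, an
#' equality bound). The exact-zero transcript bound is deliberate — it keeps
#' only placements the aligner could not distinguish from identity — but can
#' be relaxed here.
#'
#' @param max_marker_evalue Strict upper bound on marker-hit e-value.
#' @param transcript_min_identity Minimum percent identity for transcript
#'   placements.
#' @param transcript_max_evalue Inclusive upper bound on transcript-hit
#'   e-value.
#' @param ambiguity_ratio A scaffold's chromosome call is flagged ambiguous
#'   when the runner-up chromosome's score mass is at least this fraction of
#'   the winner's.
#' @return A list of class `evidence_config`.
#' @export
evidence_config <- function(max_marker_evalue = 1e-10,
                            transcript_min_identity = 100,
                            transcript_max_evalue = 0,
                            ambiguity_ratio = 0.8) {
  stopifnot(max_marker_evalue >= 0, transcript_min_identity >= 0,
            transcript_max_evalue >= 0,
            ambiguity_ratio >= 0, ambiguity_ratio <= 1)
  structure(list(max_marker_evalue = max_marker_evalue,
                 transcript_min_identity = transcript_min_identity,
                 transcript_max_evalue = transcript_max_evalue,
                 ambiguity_ratio = ambiguity_ratio),
            class = "evidence_config")
}

#' Filter hits by e-value
#'
#' Retains hits with e-value strictly below the threshold, preserving order.
#'
#' @param hits Alignment table.
#' @param max_evalue Strict upper bound (default 1e-10).
#' @return The retained rows.
#' @export
filter_hits_by_evalue <- function(hits, max_evalue = 1e-10) {
  stopifnot(max_evalue >= 0)
  hits[hits$e_value < max_evalue, , drop = FALSE]
}

#' Best hit per query
#'
#' For each query, keeps the hit with maximal bit score; ties broken by
#' higher percent identity, then by lexicographically smallest subject id.
#' The result is identical for any permutation of the input.
#'
#' @param hits Alignment table.
#' @return One row per query, ordered by query id.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  # total order: query, then -bit, -identity, subject; first row per query
  o <- order(hits$query_id, -hits$bit_score, -hits$percent_identity,
             hits$subject_id, method = "radix")
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Accumulate marker votes for linkage groups on scaffolds
#'
#' Each mapped marker contributes its best hit's bit score to its RH group's
#' vote mass on the scaffold it hits. Total vote mass over all scaffolds
#' therefore equals the summed bit score of all best marker hits.
#'
#' @param marker_best_hits One best hit per marker ([best_hit_per_query()]);
#'   query ids are marker ids and subject ids are scaffold ids.
#' @param rh_map RH marker map ([read_rh_map()]); every marker in
#'   `marker_best_hits` must appear in it.
#' @return Data frame with columns `scaffold_id`, `rh_group`, `mass`
#'   (summed bit score), `n_markers`, `min_rank` (smallest position index of
#'   the supporting markers, the ordering fallback for scaffolds without a
#'   reference position).
#' @export
marker_group_votes <- function(marker_best_hits, rh_map) {
  idx <- match(marker_best_hits$query_id, rh_map$marker_id)
  if (anyNA(idx)) {
    stop("marker vote validation error: marker '",
         marker_best_hits$query_id[is.na(idx)][[1L]],
         "' is not in the RH map", call. = FALSE)
  }
  if (nrow(marker_best_hits) == 0L) {
    return(data.frame(scaffold_id = character(0), rh_group = character(0),
                      mass = numeric(0), n_markers = integer(0),
                      min_rank = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(marker_best_hits$subject_id, rh_map$rh_group[idx], sep = "\r")
  mass <- tapply(marker_best_hits$bit_score, key, sum)
  nmk <- tapply(marker_best_hits$bit_score, key, length)
  rnk <- tapply(rh_map$position_index[idx], key, min)
  parts <- strsplit(names(mass), "\r", fixed = TRUE)
  out <- data.frame(
    scaffold_id = vapply(parts, `[[`, character(1), 1L),
    rh_group = vapply(parts, `[[`, character(1), 2L),
    mass = as.numeric(mass),
    n_markers = as.integer(nmk),
    min_rank = as.integer(rnk),
    stringsAsFactors = FALSE)
  out[order(out$scaffold_id, out$rh_group), , drop = FALSE]
}

#' Assign scaffolds to reference chromosomes by summed bit score
#'
#' The winning chromosome of a scaffold is the one with maximal summed bit
#' score over the scaffold's hits (ties to the lexicographically smaller
#' label). The representative position is the subject-coordinate midpoint,
#' `floor((s_start + s_end) / 2)`, of the scaffold's single highest-scoring
#' hit on the winning chromosome, and the strand is that hit's strand. Calls
#' whose runner-up chromosome carries at least `ambiguity_ratio` of the
#' winner's mass are flagged ambiguous but not discarded.
#'
#' @param scaffold_hits Alignment table of scaffold queries against reference
#'   chromosomes, already e-value filtered.
#' @param ambiguity_ratio See [evidence_config()].
#' @return Data frame with columns `scaffold_id`, `ref_chromosome`,
#'   `ref_position`, `ref_strand`, `ref_score_mass`, `runner_up_mass`,
#'   `ambiguous`. Scaffolds without hits are absent.
#' @export
vote_reference_chromosome <- function(scaffold_hits, ambiguity_ratio = 0.8) {
  if (nrow(scaffold_hits) == 0L) {
    return(data.frame(scaffold_id = character(0), ref_chromosome = character(0),
                      ref_position = integer(0), ref_strand = character(0),
                      ref_score_mass = numeric(0), runner_up_mass = numeric(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  key <- paste(scaffold_hits$query_id, scaffold_hits$subject_id, sep = "\r")
  mass <- tapply(scaffold_hits$bit_score, key, sum)
  parts <- strsplit(names(mass), "\r", fixed = TRUE)
  per_chrom <- data.frame(
    scaffold_id = vapply(parts, `[[`, character(1), 1L),
    chrom = vapply(parts, `[[`, character(1), 2L),
    mass = as.numeric(mass), stringsAsFactors = FALSE)
  # winner per scaffold: max mass, ties to smaller chromosome label
  o <- order(per_chrom$scaffold_id, -per_chrom$mass, per_chrom$chrom,
             method = "radix")
  pc <- per_chrom[o, , drop = FALSE]
  first <- !duplicated(pc$scaffold_id)
  winners <- pc[first, , drop = FALSE]
  runner <- tapply(seq_len(nrow(pc)), pc$scaffold_id, function(i) {
    if (length(i) >= 2L) pc$mass[[i[[2L]]]] else 0
  })
  runner <- as.numeric(runner[winners$scaffold_id])

  out <- data.frame(scaffold_id = winners$scaffold_id,
                    ref_chromosome = winners$chrom,
                    ref_position = NA_integer_,
                    ref_strand = NA_character_,
                    ref_score_mass = winners$mass,
                    runner_up_mass = runner,
                    stringsAsFactors = FALSE)
  out$ambiguous <- out$runner_up_mass >= ambiguity_ratio * out$ref_score_mass &
    out$runner_up_mass > 0

  # representative position/strand from the single best hit on the winner
  hk <- match(paste(scaffold_hits$query_id, scaffold_hits$subject_id,
                    sep = "\r"),
              paste(out$scaffold_id, out$ref_chromosome, sep = "\r"))
  on_winner <- scaffold_hits[!is.na(hk), , drop = FALSE]
  ob <- order(on_winner$query_id, -on_winner$bit_score,
              -on_winner$percent_identity, on_winner$subject_id,
              pmin(on_winner$s_start, on_winner$s_end), method = "radix")
  bh <- on_winner[ob, , drop = FALSE]
  bh <- bh[!duplicated(bh$query_id), , drop = FALSE]
  bi <- match(out$scaffold_id, bh$query_id)
  out$ref_position <- as.integer((bh$s_start[bi] + bh$s_end[bi]) %/% 2)
  out$ref_strand <- hit_strand(bh[bi, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Merge marker votes and reference assignments into scaffold evidence
#'
#' @param votes Output of [marker_group_votes()].
#' @param ref_calls Output of [vote_reference_chromosome()].
#' @return One row per scaffold seen in either channel, with the winning RH
#'   group (maximal vote mass; `rh_tie` records an exact tie, which blocks
#'   placement downstream), its mass and fallback rank, plus the reference
#'   chromosome call columns (`NA` where a channel is silent).
#' @export
scaffold_evidence <- function(votes, ref_calls) {
  if (nrow(votes) > 0L) {
    o <- order(votes$scaffold_id, -votes$mass, votes$rh_group,
               method = "radix")
    v <- votes[o, , drop = FALSE]
    top <- v[!duplicated(v$scaffold_id), , drop = FALSE]
    tie <- tapply(seq_len(nrow(v)), v$scaffold_id, function(i) {
      length(i) >= 2L && v$mass[[i[[2L]]]] == v$mass[[i[[1L]]]]
    })
    top$rh_tie <- as.logical(tie[top$scaffold_id])
    names(top)[names(top) == "rh_group"] <- "rh_winner"
    names(top)[names(top) == "mass"] <- "rh_mass"
  } else {
    top <- data.frame(scaffold_id = character(0), rh_winner = character(0),
                      rh_mass = numeric(0), n_markers = integer(0),
                      min_rank = integer(0), rh_tie = logical(0),
                      stringsAsFactors = FALSE)
  }
  ids <- sort(unique(c(top$scaffold_id, ref_calls$scaffold_id)))
  ti <- match(ids, top$scaffold_id)
  ri <- match(ids, ref_calls$scaffold_id)
  out <- data.frame(
    scaffold_id = ids,
    rh_winner = top$rh_winner[ti],
    rh_mass = top$rh_mass[ti],
    rh_min_rank = top$min_rank[ti],
    rh_tie = top$rh_tie[ti],
    ref_chromosome = ref_calls$ref_chromosome[ri],
    ref_position = ref_calls$ref_position[ri],
    ref_strand = ref_calls$ref_strand[ri],
    ref_score_mass = ref_calls$ref_score_mass[ri],
    ref_ambiguous = ref_calls$ambiguous[ri],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter transcript placements
#'
#' Retains hits meeting the perfect-placement criteria: percent identity at
#' least `transcript_min_identity` and e-value at most
#' `transcript_max_evalue` (both inclusive bounds).
#'
#' @param hits Alignment table of transcripts against pseudo-chromosomes.
#' @param cfg An [evidence_config()].
#' @return The retained rows.
#' @export
transcript_placement_filter <- function(hits, cfg = evidence_config()) {
  hits[hits$percent_identity >= cfg$transcript_min_identity &
         hits$e_value <= cfg$transcript_max_evalue, , drop = FALSE]
}
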