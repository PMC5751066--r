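# Reconciles the two evidence channels against the fixed homology table,
# orders and orients scaffolds, and concatenates them into named in silico
# groups (pseudo-chromosomes) with AGP output and coordinate lift-over.

#' Reconcile scaffold evidence into placements
#'
#' Applies the dual-evidence rule: a scaffold whose winning RH group and
#' reference chromosome agree with the homology table is placed with full
#' support (`placed_dual`); a scaffold with only one channel is placed from
#' that channel alone (`placed_ref_only` / `placed_rh_only`, the latter via
#' the marker-rank ordering fallback); a scaffold whose two channels
#' contradict the table, or whose RH vote is tied, is a `conflict`; a
#' scaffold with no evidence is `unplaced`. Output group names replace the
#' RH-group prefix with `prefix` (e.g. `SQ12` -> `SD12`).
#'
#' @param evidence Per-scaffold evidence from [scaffold_evidence()].
#' @param homology Homology table ([read_homology_table()]).
#' @param prefix Output group-name prefix (default `"SD"`).
#' @return Data frame with columns `scaffold_id`, `status`, `group`,
#'   `order_key`, `rh_rank`, `orientation` plus the evidence columns.
#'   `order_key` is the reference position where available, `NA` for
#'   rh_only placements (ordered after positioned scaffolds by `rh_rank`).
#' @export
reconcile_placements <- function(evidence, homology, prefix = "SD") {
  validate_homology_table(homology)
  n <- nrow(evidence)
  status <- character(n)
  group <- rep(NA_character_, n)
  order_key <- rep(NA_real_, n)
  rh_rank <- rep(NA_integer_, n)
  orientation <- rep(NA_character_, n)

  group_number <- function(rh_group) sub("^[A-Za-z]+", "", rh_group)

  for (i in seq_len(n)) {
    has_rh <- !is.na(evidence$rh_winner[[i]]) && !isTRUE(evidence$rh_tie[[i]])
    rh_tied <- isTRUE(evidence$rh_tie[[i]])
    has_ref <- !is.na(evidence$ref_chromosome[[i]])
    if (rh_tied) {
      status[[i]] <- "conflict"
    } else if (has_rh && has_ref) {
      expected <- homology_lookup(homology, evidence$rh_winner[[i]])
      if (identical(expected, evidence$ref_chromosome[[i]])) {
        status[[i]] <- "placed_dual"
        group[[i]] <- paste0(prefix, group_number(evidence$rh_winner[[i]]))
        order_key[[i]] <- evidence$ref_position[[i]]
        orientation[[i]] <- evidence$ref_strand[[i]]
      } else {
        status[[i]] <- "conflict"
      }
    } else if (has_ref) {
      rh_of_chrom <- homology_lookup(homology, evidence$ref_chromosome[[i]])
      status[[i]] <- "placed_ref_only"
      group[[i]] <- paste0(prefix, group_number(rh_of_chrom))
      order_key[[i]] <- evidence$ref_position[[i]]
      orientation[[i]] <- evidence$ref_strand[[i]]
    } else if (has_rh) {
      status[[i]] <- "placed_rh_only"
      group[[i]] <- paste0(prefix, group_number(evidence$rh_winner[[i]]))
      rh_rank[[i]] <- evidence$rh_min_rank[[i]]
      orientation[[i]] <- "+" # no orientation evidence from markers
    } else {
      status[[i]] <- "unplaced"
    }
    if (status[[i]] %in% c("placed_dual", "placed_ref_only") &&
        !is.na(evidence$rh_min_rank[[i]])) {
      rh_rank[[i]] <- evidence$rh_min_rank[[i]]
    }
  }
  out <- cbind(data.frame(scaffold_id = evidence$scaffold_id, status = status,
                          group = group, order_key = order_key,
                          rh_rank = rh_rank, orientation = orientation,
                          stringsAsFactors = FALSE),
               evidence[setdiff(names(evidence), "scaffold_id")])
  rownames(out) <- NULL
  out
}

#' Order the scaffolds of one group
#'
#' Reference-positioned scaffolds come first in ascending reference
#' position; marker-only scaffolds follow in ascending marker rank. Ties are
#' broken by longer scaffold first, then lexicographic id, so the order is
#' deterministic.
#'
#' @param placements Placement rows sharing one `group`.
#' @param scaffold_lengths Named integer vector of scaffold lengths (used
#'   for tie-breaks; optional).
#' @return The placements, reordered.
#' @export
order_scaffolds <- function(placements, scaffold_lengths = NULL) {
  if (length(unique(placements$group)) > 1L) {
    stop("ordering validation error: placements span more than one group",
         call. = FALSE)
  }
  len <- if (is.null(scaffold_lengths)) {
    rep(0L, nrow(placements))
  } else {
    as.integer(scaffold_lengths[placements$scaffold_id])
  }
  len[is.na(len)] <- 0L
  positioned <- !is.na(placements$order_key)
  o <- order(!positioned,
             ifelse(positioned, placements$order_key, placements$rh_rank),
             -len, placements$scaffold_id, method = "radix")
  out <- placements[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concatenate ordered scaffolds into a pseudo-chromosome
#'
#' Joins the scaffold sequences, reverse-complementing minus-orientation
#' scaffolds, with runs of `N` of length `gap_length` between consecutive
#' scaffolds. Internal offsets are 0-based; the AGP is 1-based per the
#' standard.
#'
#' @param ordered Ordered placements of one group ([order_scaffolds()]).
#' @param sequences FASTA data frame ([read_fasta()]) covering every placed
#'   scaffold.
#' @param gap_length Spacer length in bases (default 100).
#' @return List with elements `sequence` (one-row FASTA data frame for the
#'   group), `agp` (AGP data frame) and `index` (data frame `scaffold_id`,
#'   `offset`, `length`, `orientation` with 0-based offsets).
#' @export
concatenate_group <- function(ordered, sequences, gap_length = 100L) {
  stopifnot(gap_length >= 0L)
  gid <- unique(ordered$group)
  stopifnot(length(gid) == 1L)
  si <- match(ordered$scaffold_id, sequences$id)
  if (anyNA(si)) {
    stop("concatenation validation error: no sequence for scaffold '",
         ordered$scaffold_id[is.na(si)][[1L]], "'", call. = FALSE)
  }
  seqs <- sequences$sequence[si]
  lens <- nchar(seqs)
  flip <- ordered$orientation == "-"
  seqs[flip] <- reverse_complement(seqs[flip])
  n <- length(seqs)
  offsets <- cumsum(c(0L, (lens + gap_length)[-n][seq_len(max(0L, n - 1L))]))
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- seqs
  if (n > 1L) {
    pieces[seq(2L, 2L * n - 2L, by = 2L)] <- strrep("N", gap_length)
  }
  group_seq <- paste0(pieces, collapse = "")

  agp <- vector("list", 2L * n - 1L)
  part <- 0L
  pos <- 1L
  for (k in seq_len(n)) {
    if (k > 1L && gap_length > 0L) {
      part <- part + 1L
      agp[[part]] <- data.frame(
        object_id = gid, object_beg = pos, object_end = pos + gap_length - 1L,
        part_number = part, component_type = "N", component_id = NA_character_,
        gap_length = as.integer(gap_length), component_beg = NA_integer_,
        component_end = NA_integer_, orientation = NA_character_,
        gap_type = "scaffold", linkage = "yes",
        linkage_evidence = "align_genus", stringsAsFactors = FALSE)
      pos <- pos + gap_length
    }
    part <- part + 1L
    agp[[part]] <- data.frame(
      object_id = gid, object_beg = pos, object_end = pos + lens[[k]] - 1L,
      part_number = part, component_type = "W",
      component_id = ordered$scaffold_id[[k]], gap_length = NA_integer_,
      component_beg = 1L, component_end = lens[[k]],
      orientation = ordered$orientation[[k]], gap_type = NA_character_,
      linkage = NA_character_, linkage_evidence = NA_character_,
      stringsAsFactors = FALSE)
    pos <- pos + lens[[k]]
  }
  agp <- do.call(rbind, agp[seq_len(part)])
  validate_agp(agp)

  index <- data.frame(scaffold_id = ordered$scaffold_id,
                      offset = as.integer(offsets), length = lens,
                      orientation = ordered$orientation,
                      stringsAsFactors = FALSE)
  list(sequence = data.frame(id = gid, description = "", sequence = group_seq,
                             stringsAsFactors = FALSE),
       agp = agp, index = index)
}

#' Build all in silico groups
#'
#' @param placements Placement table from [reconcile_placements()].
#' @param sequences FASTA data frame with every placed scaffold.
#' @param gap_length Spacer length between scaffolds (default 100).
#' @param include_rh_only Keep marker-only scaffolds in the groups
#'   (default `TRUE`).
#' @return List with `fasta` (data frame of group sequences), `agp`
#'   (combined AGP), `indexes` (named list of per-group lift-over indexes),
#'   `placements` (the ordered placed rows), `conflicts` (conflict rows,
#'   preserved in a side table) and `unplaced`.
#' @export
build_groups <- function(placements, sequences, gap_length = 100L,
                         include_rh_only = TRUE) {
  keep <- placements$status %in% c("placed_dual", "placed_ref_only",
                                   if (include_rh_only) "placed_rh_only")
  placed <- placements[keep, , drop = FALSE]
  lens <- stats::setNames(nchar(sequences$sequence), sequences$id)
  groups <- sort(unique(placed$group))
  fasta <- vector("list", length(groups))
  agps <- vector("list", length(groups))
  indexes <- vector("list", length(groups))
  ordered_all <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- order_scaffolds(placed[placed$group == groups[[g]], , drop = FALSE],
                            lens)
    built <- concatenate_group(rows, sequences, gap_length)
    fasta[[g]] <- built$sequence
    agps[[g]] <- built$agp
    indexes[[g]] <- built$index
    ordered_all[[g]] <- rows
  }
  names(indexes) <- groups
  list(fasta = do.call(rbind, fasta),
       agp = do.call(rbind, agps),
       indexes = indexes,
       placements = do.call(rbind, ordered_all),
       conflicts = placements[placements$status == "conflict", , drop = FALSE],
       unplaced = placements[placements$status == "unplaced", , drop = FALSE])
}

#' Lift a scaffold coordinate onto its group
#'
#' @param index Per-group index (`scaffold_id`, `offset`, `length`,
#'   `orientation`) from [concatenate_group()].
#' @param scaffold_id Scaffold identifier.
#' @param position 0-based position on the scaffold.
#' @return 0-based position on the group.
#' @export
lift_to_group <- function(index, scaffold_id, position) {
  i <- match(scaffold_id, index$scaffold_id)
  if (is.na(i)) {
    stop("lift error: scaffold '", scaffold_id, "' is not in this group",
         call. = FALSE)
  }
  if (position < 0L || position >= index$length[[i]]) {
    stop("lift error: position ", position, " outside scaffold '",
         scaffold_id, "'", call. = FALSE)
  }
  if (index$orientation[[i]] == "-") {
    index$offset[[i]] + (index$length[[i]] - 1L - position)
  } else {
    index$offset[[i]] + position
  }
}

#' Lift a group coordinate back onto its scaffold
#'
#' @param index Per-group index from [concatenate_group()].
#' @param position 0-based position on the group.
#' @return List with `scaffold_id` and 0-based `position`; positions falling
#'   in an inter-scaffold gap raise an in-gap error.
#' @export
lift_to_scaffold <- function(index, position) {
  hit <- which(position >= index$offset &
                 position < index$offset + index$length)
  if (length(hit) == 0L) {
    total <- index$offset[[nrow(index)]] + index$length[[nrow(index)]]
    if (position < 0L || position >= total) {
      stop("lift error: position ", position, " outside the group",
           call. = FALSE)
    }
    stop("lift error: position ", position, " falls in an inter-scaffold gap",
         call. = FALSE)
  }
  i <- hit[[1L]]
  p <- position - index$offset[[i]]
  if (index$orientation[[i]] == "-") p <- index$length[[i]] - 1L - p
  list(scaffold_id = index$scaffold_id[[i]], position = p)
}

#' Assign transcripts to groups from filtered placements
#'
#' Each transcript is assigned to the group of its best surviving hit
#' (maximal bit score; ties by higher identity, then lexicographically
#' smallest group id — note string order, so `"SD12" < "SD3"`).
#'
#' @param transcript_hits Alignment table of transcripts vs groups, already
#'   passed through [transcript_placement_filter()].
#' @return List with `assignments` (data frame `transcript_id`, `group`,
#'   `start`, `end` — 1-based subject span of the best hit) and `counts`
#'   (data frame `group`, `n_transcripts`).
#' @export
map_transcripts_to_groups <- function(transcript_hits) {
  best <- best_hit_per_query(transcript_hits)
  assignments <- data.frame(
    transcript_id = best$query_id, group = best$subject_id,
    start = pmin(best$s_start, best$s_end),
    end = pmax(best$s_start, best$s_end), stringsAsFactors = FALSE)
  counts <- as.data.frame(table(assignments$group), stringsAsFactors = FALSE)
  names(counts) <- c("group", "n_transcripts")
  list(assignments = assignments, counts = counts)
}

#' Circos-style links between scaffolds and their group placements
#'
#' One link per placed scaffold, connecting the scaffold (full span) to its
#' location on the group; coordinates 1-based inclusive.
#'
#' @param groups Result of [build_groups()].
#' @return Data frame consumable by [write_links()].
#' @export
group_links <- function(groups) {
  links <- lapply(names(groups$indexes), function(g) {
    ix <- groups$indexes[[g]]
    data.frame(obj_a = ix$scaffold_id, start_a = 1L, end_a = ix$length,
               obj_b = g, start_b = ix$offset + 1L,
               end_b = ix$offset + ix$length, stringsAsFactors = FALSE)
  })
  do.call(rbind, links)
}

#' Run the full anchoring pipeline
#'
#' Marker hits are e-value filtered and reduced to best hits per marker,
#' scaffold hits are e-value filtered and voted per chromosome, the two
#' channels are reconciled against the homology table, and the resulting
#' placements are concatenated into pseudo-chromosomes.
#'
#' @param scaffolds FASTA data frame of draft scaffolds.
#' @param marker_hits Alignment table, markers vs scaffolds.
#' @param ref_hits Alignment table, scaffolds vs reference chromosomes.
#' @param rh_map RH marker map.
#' @param homology Homology table.
#' @param cfg An [evidence_config()].
#' @param gap_length Spacer length (default 100).
#' @param prefix Output group-name prefix (default `"SD"`).
#' @param include_rh_only Keep marker-only scaffolds (default `TRUE`).
#' @return The [build_groups()] result, plus `evidence` and `links`.
#' @export
anchor_pipeline <- function(scaffolds, marker_hits, ref_hits, rh_map,
                            homology, cfg = evidence_config(),
                            gap_length = 100L, prefix = "SD",
                            include_rh_only = TRUE) {
  mk <- filter_hits_by_evalue(marker_hits, cfg$max_marker_evalue)
  mk_best <- best_hit_per_query(mk)
  votes <- marker_group_votes(mk_best, rh_map)
  rf <- filter_hits_by_evalue(ref_hits, cfg$max_marker_evalue)
  ref_calls <- vote_reference_chromosome(rf, cfg$ambiguity_ratio)
  ev <- scaffold_evidence(votes, ref_calls)
  placements <- reconcile_placements(ev, homology, prefix = prefix)
  # scaffolds with no evidence at all still count as unplaced
  missing <- setdiff(scaffolds$id, placements$scaffold_id)
  if (length(missing) > 0L) {
    pad <- placements[rep(NA_integer_, length(missing)), , drop = FALSE]
    pad$scaffold_id <- missing
    pad$status <- "unplaced"
    placements <- rbind(placements, pad)
    rownames(placements) <- NULL
  }
  groups <- build_groups(placements, scaffolds, gap_length = gap_length,
                         include_rh_only = include_rh_only)
  groups$evidence <- ev
  groups$links <- group_links(groups)
  groups$all_placements <- placements
  groups
}
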