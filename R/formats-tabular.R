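# Tabular formats: 12-column pairwise-alignment tables ("outfmt 6" dialect),
# RH marker maps, DE result tables, GO annotation tables, the chromosome
# homology table, and circos-style link files.

.blast_cols <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Read a 12-column tabular alignment file
#'
#' Parses the tab-separated 12-column pairwise alignment format written by
#' BLAST-family tools (`-outfmt 6`). Lines starting with `#` are skipped.
#' The format carries no strand column: a hit is on the minus strand of the
#' subject exactly when `s_start > s_end` (see [hit_strand()]).
#'
#' @param path Path to a tab-separated alignment file.
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
read_alignment_tabular <- function(path) {
  lines <- read_text_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  rows <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(rows) == 0L) {
    return(empty_alignment_table())
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[[1L]]
    stop("alignment format error: expected 12 tab-separated fields, found ",
         nf[[bad]], " (line ", lineno[[bad]], ")", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num_cols <- 3:12
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  for (j in num_cols) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[[1L]]
      stop("alignment format error: non-numeric value '", m[bad, j],
           "' in field ", j, " (line ", lineno[[bad]], ")", call. = FALSE)
    }
    out[[.blast_cols[[j]]]] <- v
  }
  int_cols <- c("alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  out[int_cols] <- lapply(out[int_cols], as.integer)
  validate_alignment_hits(out, lineno)
  out
}

empty_alignment_table <- function() {
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    stringsAsFactors = FALSE)
  for (nm in .blast_cols[3:12]) out[[nm]] <- numeric(0)
  int_cols <- c("alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  out[int_cols] <- lapply(out[int_cols], as.integer)
  out
}

validate_alignment_hits <- function(hits, lineno = seq_len(nrow(hits))) {
  bad <- which(hits$q_start > hits$q_end)
  if (length(bad) > 0L) {
    stop("alignment format error: q_start > q_end (line ", lineno[[bad[[1L]]]],
         ")", call. = FALSE)
  }
  bad <- which(hits$e_value < 0)
  if (length(bad) > 0L) {
    stop("alignment format error: negative e-value (line ",
         lineno[[bad[[1L]]]], ")", call. = FALSE)
  }
  invisible(hits)
}

#' Subject strand of alignment hits
#'
#' @param hits Alignment table from [read_alignment_tabular()].
#' @return Character vector of `"+"`/`"-"`, minus iff `s_start > s_end`.
#' @export
hit_strand <- function(hits) {
  ifelse(hits$s_start > hits$s_end, "-", "+")
}

#' Write a 12-column tabular alignment file
#'
#' @param hits Alignment table with the columns of [read_alignment_tabular()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tabular <- function(hits, path) {
  stopifnot(all(.blast_cols %in% names(hits)))
  fmt_num <- function(x) {
    # digits = 17 guarantees that as.numeric() recovers the exact double
    vapply(x, function(v) format(v, scientific = NA, trim = TRUE,
                                 digits = 17), character(1))
  }
  lines <- paste(hits$query_id, hits$subject_id,
                 fmt_num(hits$percent_identity), hits$alignment_length,
                 hits$mismatches, hits$gap_opens, hits$q_start, hits$q_end,
                 hits$s_start, hits$s_end, fmt_num(hits$e_value),
                 fmt_num(hits$bit_score), sep = "\t")
  write_lines_lf(lines, path)
  invisible(path)
}

#' Read an RH marker map
#'
#' A radiation-hybrid (RH) map table assigns each marker to a linkage group
#' and an ordinal rank within the group. Expected columns (with header):
#' `marker_id`, `rh_group`, `position_index`.
#'
#' @param path Path to a 3-column TSV with header.
#' @param valid_groups Optional character vector of admissible group labels;
#'   any other label is a validation error.
#' @return Data frame with columns `marker_id`, `rh_group`, `position_index`,
#'   in file order.
#' @export
read_rh_map <- function(path, valid_groups = NULL) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("marker_id", "rh_group", "position_index")
  if (!all(need %in% names(x))) {
    stop("RH map format error: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x <- x[need]
  x$position_index <- as.integer(x$position_index)
  if (anyNA(x$position_index) || any(x$position_index < 0L)) {
    stop("RH map validation error: position_index must be a non-negative ",
         "integer", call. = FALSE)
  }
  dup <- duplicated(x$marker_id)
  if (any(dup)) {
    stop("RH map validation error: duplicate marker id '",
         x$marker_id[dup][[1L]], "'", call. = FALSE)
  }
  if (!is.null(valid_groups)) {
    alien <- setdiff(x$rh_group, valid_groups)
    if (length(alien) > 0L) {
      stop("RH map validation error: unknown group label '", alien[[1L]],
           "'", call. = FALSE)
    }
  }
  x
}

#' Write an RH marker map
#' @param x Data frame from [read_rh_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rh_map <- function(x, path) {
  write_tsv_lf(x[c("marker_id", "rh_group", "position_index")], path)
}

#' Read a differential-expression result table
#'
#' Expected columns (with header): `feature` (or `feature_id`), `log2FC`,
#' `pvalue`, `padj`. A missing or `NA` adjusted p-value is preserved as `NA`
#' and treated as non-significant downstream, never imputed.
#'
#' @param path Path to a TSV with header.
#' @return Data frame with columns `feature_id`, `log2_fold_change`,
#'   `p_value`, `p_adjusted`.
#' @export
read_de_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  nm <- names(x)
  pick <- function(...) {
    cand <- c(...)
    hit <- cand[cand %in% nm]
    if (length(hit) == 0L) {
      stop("DE table format error: none of the columns ",
           paste(cand, collapse = "/"), " present", call. = FALSE)
    }
    hit[[1L]]
  }
  out <- data.frame(
    feature_id = as.character(x[[pick("feature", "feature_id")]]),
    log2_fold_change = as.numeric(x[[pick("log2FC", "log2_fold_change")]]),
    p_value = as.numeric(x[[pick("pvalue", "p_value")]]),
    p_adjusted = as.numeric(x[[pick("padj", "p_adjusted")]]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$feature_id)) {
    stop("DE table validation error: duplicate feature id", call. = FALSE)
  }
  chk <- function(v, nm) {
    ok <- is.na(v) | (v >= 0 & v <= 1)
    if (!all(ok)) {
      stop("DE table validation error: ", nm, " outside [0,1] for feature '",
           out$feature_id[!ok][[1L]], "'", call. = FALSE)
    }
  }
  chk(out$p_value, "pvalue")
  chk(out$p_adjusted, "padj")
  out
}

#' Write a differential-expression result table
#' @param x Data frame from [read_de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  out <- data.frame(feature = x$feature_id, log2FC = x$log2_fold_change,
                    pvalue = x$p_value, padj = x$p_adjusted,
                    stringsAsFactors = FALSE)
  write_tsv_lf(out, path)
}

#' Read GO annotations
#'
#' Two-column TSV (no header): feature id, then a semicolon-separated list of
#' GO identifiers (`GO:` followed by 7 digits). Duplicate terms within a
#' feature are dropped.
#'
#' @param path Path to the annotation TSV.
#' @return Long-format data frame with columns `feature_id`, `term`; one row
#'   per (feature, term) pair.
#' @export
read_go_annotations <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(feature_id = character(0), term = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- which(lengths(parts) != 2L)[[1L]]
    stop("GO annotation format error: expected 2 tab-separated fields ",
         "(line ", bad, ")", call. = FALSE)
  }
  feats <- vapply(parts, `[[`, character(1), 1L)
  termsets <- lapply(parts, function(p) unique(strsplit(p[[2L]], ";",
                                                        fixed = TRUE)[[1L]]))
  all_terms <- unlist(termsets)
  bad <- all_terms[!grepl("^GO:[0-9]{7}$", all_terms)]
  if (length(bad) > 0L) {
    stop("GO annotation validation error: malformed GO id '", bad[[1L]], "'",
         call. = FALSE)
  }
  if (any(lengths(termsets) == 0L)) {
    stop("GO annotation validation error: feature with empty term set",
         call. = FALSE)
  }
  data.frame(feature_id = rep(feats, lengths(termsets)), term = all_terms,
             stringsAsFactors = FALSE)
}

#' Write GO annotations
#' @param x Long-format annotation data frame (`feature_id`, `term`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_annotations <- function(x, path) {
  sets <- split(x$term, factor(x$feature_id, levels = unique(x$feature_id)))
  lines <- paste0(names(sets), "\t",
                  vapply(sets, function(t) paste0(unique(t), collapse = ";"),
                         character(1)))
  write_lines_lf(lines, path)
  invisible(path)
}

#' Write a circos-style link file
#'
#' Six whitespace-separated columns: object A, start, end, object B, start,
#' end (1-based inclusive, the convention of circos link tracks).
#'
#' @param links Data frame with columns `obj_a`, `start_a`, `end_a`,
#'   `obj_b`, `start_b`, `end_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  lines <- paste(links$obj_a, links$start_a, links$end_a,
                 links$obj_b, links$start_b, links$end_b)
  write_lines_lf(lines, path)
  invisible(path)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

write_tsv_lf <- function(x, path) {
  # doubles serialized at 17 significant digits so readers recover the
  # exact value
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      x[[j]] <- vapply(x[[j]], function(v)
        if (is.na(v)) "NA" else format(v, scientific = NA, trim = TRUE,
                                       digits = 17), character(1))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}
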