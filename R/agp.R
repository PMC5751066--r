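# AGP v2.1 serialization for pseudo-chromosomes. W lines carry scaffold
# components; N lines carry fixed-length "scaffold" gaps. Coordinates in the
# file are 1-based inclusive per the AGP standard.

#' Read an AGP file
#'
#' @param path Path to a 9-column AGP v2.1 file; `#` comment lines skipped.
#' @return Data frame with columns `object_id`, `object_beg`, `object_end`,
#'   `part_number`, `component_type` (`"W"` or `"N"`), `component_id`
#'   (`NA` on gap lines), `gap_length` (`NA` on component lines),
#'   `component_beg`, `component_end`, `orientation`, `gap_type`, `linkage`,
#'   `linkage_evidence`.
#' @export
read_agp <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_agp())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) {
    bad <- which(lengths(parts) != 9L)[[1L]]
    stop("AGP format error: expected 9 tab-separated fields (line ", bad,
         ")", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  is_gap <- m[, 5L] %in% c("N", "U")
  out <- data.frame(
    object_id = m[, 1L],
    object_beg = as.integer(m[, 2L]),
    object_end = as.integer(m[, 3L]),
    part_number = as.integer(m[, 4L]),
    component_type = m[, 5L],
    component_id = ifelse(is_gap, NA_character_, m[, 6L]),
    gap_length = ifelse(is_gap, suppressWarnings(as.integer(m[, 6L])),
                        NA_integer_),
    component_beg = ifelse(is_gap, NA_integer_,
                           suppressWarnings(as.integer(m[, 7L]))),
    component_end = ifelse(is_gap, NA_integer_,
                           suppressWarnings(as.integer(m[, 8L]))),
    orientation = ifelse(is_gap, NA_character_, m[, 9L]),
    gap_type = ifelse(is_gap, m[, 7L], NA_character_),
    linkage = ifelse(is_gap, m[, 8L], NA_character_),
    linkage_evidence = ifelse(is_gap, m[, 9L], NA_character_),
    stringsAsFactors = FALSE)
  validate_agp(out)
  out
}

empty_agp <- function() {
  data.frame(object_id = character(0), object_beg = integer(0),
             object_end = integer(0), part_number = integer(0),
             component_type = character(0), component_id = character(0),
             gap_length = integer(0), component_beg = integer(0),
             component_end = integer(0), orientation = character(0),
             gap_type = character(0), linkage = character(0),
             linkage_evidence = character(0), stringsAsFactors = FALSE)
}

#' Validate AGP records
#'
#' Checks the tiling invariants: spans match component lengths or gap
#' lengths, part numbers run consecutively from 1 per object, and consecutive
#' records tile each object without overlap or holes.
#'
#' @param agp AGP data frame as returned by [read_agp()].
#' @return The input, invisibly; stops on violation.
#' @export
validate_agp <- function(agp) {
  span <- agp$object_end - agp$object_beg + 1L
  is_gap <- agp$component_type %in% c("N", "U")
  comp_len <- ifelse(is_gap, agp$gap_length,
                     agp$component_end - agp$component_beg + 1L)
  bad <- which(span != comp_len)
  if (length(bad) > 0L) {
    stop("AGP validation error: object span does not match component span ",
         "for object '", agp$object_id[[bad[[1L]]]], "' part ",
         agp$part_number[[bad[[1L]]]], call. = FALSE)
  }
  for (obj in unique(agp$object_id)) {
    rec <- agp[agp$object_id == obj, , drop = FALSE]
    rec <- rec[order(rec$part_number), , drop = FALSE]
    if (!identical(rec$part_number, seq_len(nrow(rec)))) {
      stop("AGP validation error: part numbers of object '", obj,
           "' are not consecutive from 1", call. = FALSE)
    }
    if (rec$object_beg[[1L]] != 1L) {
      stop("AGP validation error: object '", obj, "' does not start at 1",
           call. = FALSE)
    }
    if (nrow(rec) > 1L) {
      gaps <- rec$object_beg[-1L] - rec$object_end[-nrow(rec)]
      if (any(gaps != 1L)) {
        stop("AGP validation error: records of object '", obj,
             "' overlap or leave holes", call. = FALSE)
      }
    }
  }
  invisible(agp)
}

#' Write an AGP v2.1 file
#'
#' @param agp AGP data frame; validated before writing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  is_gap <- agp$component_type %in% c("N", "U")
  f6 <- ifelse(is_gap, as.character(agp$gap_length), agp$component_id)
  f7 <- ifelse(is_gap, agp$gap_type, as.character(agp$component_beg))
  f8 <- ifelse(is_gap, agp$linkage, as.character(agp$component_end))
  f9 <- ifelse(is_gap, agp$linkage_evidence, agp$orientation)
  lines <- paste(agp$object_id, agp$object_beg, agp$object_end,
                 agp$part_number, agp$component_type, f6, f7, f8, f9,
                 sep = "\t")
  write_lines_lf(c("##agp-version\t2.1", lines), path)
  invisible(path)
}
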