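# FASTA reading/writing. Sequences are plain character strings over
# {A,C,G,T,N} in either case; coordinates elsewhere in the package are
# 0-based half-open internally and converted at format boundaries only.

.fasta_alphabet <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) nucleotide FASTA file into a data frame
#' with one row per record. The first whitespace-delimited token of each
#' header is the record id; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description` and `sequence`.
#'   Residues are restricted to `A/C/G/T/N` in either case; anything else is
#'   a format error reported with its line number.
#' @seealso [write_fasta()] for the inverse; `read_fasta(write_fasta(x))`
#'   reproduces `x` exactly.
#' @export
#' @examples
#' path <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a scaffold", "ACGT", "ACGT"), path)
#' read_fasta(path)
read_fasta <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) {
    stop("FASTA format error: file '", path, "' is empty", call. = FALSE)
  }
  if (!startsWith(lines[[1L]], ">")) {
    stop("FASTA format error: file does not begin with '>' (line 1)",
         call. = FALSE)
  }
  header_idx <- which(startsWith(lines, ">"))
  ids <- character(length(header_idx))
  desc <- character(length(header_idx))
  seqs <- character(length(header_idx))
  bounds <- c(header_idx, length(lines) + 1L)
  for (i in seq_along(header_idx)) {
    h <- sub("^>", "", lines[[header_idx[[i]]]])
    ids[[i]] <- sub("\\s.*$", "", h)
    desc[[i]] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    if (ids[[i]] == "") {
      stop("FASTA format error: empty record id (line ", header_idx[[i]], ")",
           call. = FALSE)
    }
    body_lines <- if (bounds[[i + 1L]] - 1L >= header_idx[[i]] + 1L) {
      seq.int(header_idx[[i]] + 1L, bounds[[i + 1L]] - 1L)
    } else {
      integer(0)
    }
    for (j in body_lines) {
      chars <- strsplit(lines[[j]], "", fixed = TRUE)[[1L]]
      alien <- setdiff(chars, .fasta_alphabet)
      if (length(alien) > 0L) {
        stop("FASTA format error: residue '", alien[[1L]],
             "' outside alphabet ACGTN (line ", j, ")", call. = FALSE)
      }
    }
    seqs[[i]] <- paste0(lines[body_lines], collapse = "")
    if (nchar(seqs[[i]]) == 0L) {
      stop("FASTA format error: record '", ids[[i]],
           "' has an empty sequence (line ", header_idx[[i]], ")",
           call. = FALSE)
    }
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequences as wrapped FASTA
#'
#' @param x Data frame with columns `id`, `description` (optional) and
#'   `sequence`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Residues per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)),
            width >= 1L)
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- if (nzchar(desc[[i]])) paste(x$id[[i]], desc[[i]]) else x$id[[i]]
    n <- nchar(x$sequence[[i]])
    starts <- seq.int(1L, n, by = width)
    chunks <- substring(x$sequence[[i]], starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", header), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Case-preserving; `N` maps to `N`.
#'
#' @param x Character vector of sequences over `A/C/G/T/N` (either case).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AACG") # "CGTT"
reverse_complement <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste0(rev(ch), collapse = ""), character(1))
}

# readLines with CRLF tolerance; drops a trailing empty element produced by
# a final newline but keeps interior empties (they are format errors upstream).
read_text_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file '", path, "' does not exist", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)
}
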