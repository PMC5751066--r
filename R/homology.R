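# The fixed 1-to-1 correspondence between RH linkage groups of the marker
# species and chromosomes of the reference genome. The packaged table is the
# published 24-pair correspondence between Japanese yellowtail RH groups
# (SQ1..SQ24) and medaka chromosomes (OL1..OL24), together with the printed
# per-group marker and transcript mapping counts.

#' Read a chromosome homology table
#'
#' @param path Path to a TSV with header containing at least `rh_group` and
#'   `ref_chromosome` columns; extra columns (per-group counts) are kept.
#' @param n_groups Required number of pairs (default 24, the karyotype of
#'   the species involved); use `NULL` to skip the check.
#' @return Data frame with one row per (rh_group, ref_chromosome) pair.
#' @export
read_homology_table <- function(path, n_groups = 24L) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("rh_group", "ref_chromosome") %in% names(x))) {
    stop("homology table format error: columns rh_group and ref_chromosome ",
         "are required", call. = FALSE)
  }
  validate_homology_table(x, n_groups = n_groups)
  x
}

validate_homology_table <- function(table, n_groups = NULL) {
  if (anyDuplicated(table$rh_group) || anyDuplicated(table$ref_chromosome)) {
    stop("homology table validation error: pairing is not a bijection",
         call. = FALSE)
  }
  if (!is.null(n_groups) && nrow(table) != n_groups) {
    stop("homology table validation error: expected ", n_groups,
         " pairs, found ", nrow(table), call. = FALSE)
  }
  invisible(table)
}

#' The packaged yellowtail-medaka homology table
#'
#' The published 24-row correspondence between Japanese yellowtail RH groups
#' and medaka chromosomes, with the per-group counts of mapped markers and
#' of amberjack transcripts mapped to the medaka genome.
#'
#' @return Data frame with columns `rh_group`, `n_markers`,
#'   `ref_chromosome`, `n_transcripts`.
#' @export
#' @examples
#' h <- seriola_homology_table()
#' homology_lookup(h, "SQ12") # "OL8"
seriola_homology_table <- function() {
  read_homology_table(system.file("extdata", "seriola_homology_table.tsv",
                                  package = "synanchor", mustWork = TRUE))
}

#' Published headline counts
#'
#' Totals printed in the source study (transcript totals, DE set sizes,
#' marker counts), packaged for consistency checks against quantities the
#' pipeline recomputes.
#'
#' @return Named numeric vector.
#' @export
reported_counts <- function() {
  x <- utils::read.delim(system.file("extdata", "reported_counts.tsv",
                                     package = "synanchor", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  stats::setNames(x$value, x$quantity)
}

#' Look up the homologous partner of a group or chromosome
#'
#' @param table Homology table (see [read_homology_table()]).
#' @param label An `rh_group` label or a `ref_chromosome` label.
#' @return The paired label. Lookup works in both directions.
#' @export
homology_lookup <- function(table, label) {
  stopifnot(length(label) == 1L)
  i <- match(label, table$rh_group)
  if (!is.na(i)) return(table$ref_chromosome[[i]])
  j <- match(label, table$ref_chromosome)
  if (!is.na(j)) return(table$rh_group[[j]])
  stop("homology lookup error: unknown label '", label, "'", call. = FALSE)
}
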