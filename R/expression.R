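# Sample QC (distances, outlier flagging, PCA), DE filtering at the study
# thresholds, and assignment of DE features to in silico groups. DE model
# fitting itself is out of scope: this stage consumes precomputed tables.

#' DE filtering thresholds
#'
#' Defaults are the gonad-contrast thresholds: adjusted p strictly below
#' 0.005 and absolute log2 fold change strictly above 2.
#'
#' @param alpha Adjusted-p threshold (strict `<`).
#' @param min_abs_lfc Absolute log2FC threshold (strict `>`), log2 units.
#' @param positive_direction_label Condition whose higher expression is
#'   encoded as positive log2FC (default `"A"`; in the gonad fixtures,
#'   female).
#' @return List of class `de_config`.
#' @export
de_config <- function(alpha = 0.005, min_abs_lfc = 2,
                      positive_direction_label = "A") {
  stopifnot(alpha > 0, alpha <= 1, min_abs_lfc >= 0)
  structure(list(alpha = alpha, min_abs_lfc = min_abs_lfc,
                 positive_direction_label = positive_direction_label),
            class = "de_config")
}

#' Filter a DE table into a direction-biased partition
#'
#' A feature is significant iff its adjusted p-value is present, strictly
#' below `alpha`, and its absolute log2FC strictly exceeds `min_abs_lfc`.
#' Missing adjusted p-values are never significant. Positive log2FC routes
#' to `up_in_a`, negative to `up_in_b`.
#'
#' @param de DE table ([read_de_table()]).
#' @param cfg A [de_config()].
#' @return List of class `de_partition` with `up_in_a`, `up_in_b` (feature
#'   id vectors, disjoint) and `n_significant` (their summed size).
#' @export
filter_de <- function(de, cfg = de_config()) {
  sig <- !is.na(de$p_adjusted) & de$p_adjusted < cfg$alpha &
    abs(de$log2_fold_change) > cfg$min_abs_lfc
  de_partition(de$feature_id[sig & de$log2_fold_change > 0],
               de$feature_id[sig & de$log2_fold_change < 0])
}

#' Construct a DE partition
#'
#' @param up_in_a,up_in_b Disjoint feature id vectors.
#' @return List of class `de_partition`; `n_significant` is the invariant
#'   total `length(up_in_a) + length(up_in_b)`.
#' @export
de_partition <- function(up_in_a, up_in_b) {
  if (length(intersect(up_in_a, up_in_b)) > 0L) {
    stop("DE partition validation error: direction sets are not disjoint",
         call. = FALSE)
  }
  structure(list(up_in_a = up_in_a, up_in_b = up_in_b,
                 n_significant = length(up_in_a) + length(up_in_b)),
            class = "de_partition")
}

#' Count DE features per in silico group
#'
#' @param partition A [de_partition()].
#' @param placements Named character vector or data frame
#'   (`transcript_id`, `group`) mapping features to groups.
#' @return List with `per_group` (data frame `group`, `up_in_a`, `up_in_b`,
#'   `total`) and `n_unplaced` (significant features without a placement).
#'   Group totals plus `n_unplaced` equal `n_significant`.
#' @export
assign_de_to_groups <- function(partition, placements) {
  if (is.data.frame(placements)) {
    placements <- stats::setNames(placements$group, placements$transcript_id)
  }
  ga <- placements[partition$up_in_a]
  gb <- placements[partition$up_in_b]
  groups <- sort(unique(stats::na.omit(c(ga, gb))))
  per_group <- data.frame(
    group = groups,
    up_in_a = as.integer(table(factor(ga, levels = groups))[groups]),
    up_in_b = as.integer(table(factor(gb, levels = groups))[groups]),
    stringsAsFactors = FALSE)
  per_group$up_in_a[is.na(per_group$up_in_a)] <- 0L
  per_group$up_in_b[is.na(per_group$up_in_b)] <- 0L
  per_group$total <- per_group$up_in_a + per_group$up_in_b
  list(per_group = per_group,
       n_unplaced = sum(is.na(ga)) + sum(is.na(gb)))
}

#' Sample-to-sample distance matrix
#'
#' Euclidean distances between samples on log2(count + 1)-transformed
#' columns, the transform used for all QC in this package.
#'
#' @param counts Non-negative count matrix, features in rows, samples in
#'   columns.
#' @return Symmetric matrix with zero diagonal, one row/column per sample.
#' @export
sample_distance_matrix <- function(counts) {
  if (ncol(counts) < 2L) {
    stop("QC error: at least 2 samples are required", call. = FALSE)
  }
  as.matrix(stats::dist(t(log2(counts + 1)), method = "euclidean"))
}

#' Flag outlier samples from a distance matrix
#'
#' A sample is flagged when its mean distance to the other samples exceeds
#' the grand mean of those per-sample means by more than `k` standard
#' deviations — a deterministic z-score rule on mean Euclidean distance.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Threshold multiplier (default 2).
#' @return Character vector of flagged sample names (possibly empty).
#' @export
detect_outlier_samples <- function(d, k = 2) {
  n <- nrow(d)
  if (n < 3L) {
    stop("QC error: outlier detection needs at least 3 samples", call. = FALSE)
  }
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  mean_dist <- rowSums(d) / (n - 1)
  flagged <- mean_dist > mean(mean_dist) + k * stats::sd(mean_dist)
  names(mean_dist)[flagged]
}

#' PCA on log-transformed counts
#'
#' Principal components of the centered log2(count + 1) sample matrix
#' (samples as observations).
#'
#' @param counts Count matrix, features in rows, samples in columns.
#' @return List with `scores` (samples x components), `variance_fraction`
#'   (non-increasing, summing to 1 unless the matrix is constant, in which
#'   case scores and fractions are all zero).
#' @export
pca_qc <- function(counts) {
  if (ncol(counts) < 2L) {
    stop("QC error: at least 2 samples are required", call. = FALSE)
  }
  x <- t(log2(counts + 1))
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) {
    k <- ncol(x) # constant input: defined all-zero result
    return(list(scores = matrix(0, nrow(x), min(nrow(x), k),
                                dimnames = list(rownames(x), NULL)),
                variance_fraction = rep(0, min(nrow(x), k))))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, variance_fraction = vf)
}
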