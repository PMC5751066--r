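# Two-tailed Fisher exact GO-term enrichment with Benjamini-Hochberg FDR
# control. The two-tailed p-value uses the probability-mass method: sum the
# hypergeometric probabilities of every table with the observed margins that
# is no more probable than the observed one.

#' Two-tailed Fisher exact p-value for a 2x2 table
#'
#' Cells are `a` (test features with the term), `b` (test without), `c`
#' (reference-only with), `d` (reference-only without). With fixed margins
#' the table count is hypergeometric; the two-tailed p is the total mass of
#' tables whose probability does not exceed the observed table's
#' (probability-mass method, the convention of standard exact-test
#' implementations). A relative tolerance of 1e-7 guards the comparison
#' against floating-point ties. `method = "doubling"` instead doubles the
#' smaller one-sided tail (capped at 1).
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @param method `"probability"` (default) or `"doubling"`.
#' @return p-values in `[0, 1]`; degenerate margins give 1.
#' @export
#' @examples
#' fisher_exact_two_tailed(2, 2, 2, 2) # 1
#' fisher_exact_two_tailed(30, 20, 50, 900) # strongly enriched
fisher_exact_two_tailed <- function(a, b, c, d,
                                    method = c("probability", "doubling")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    stop("contingency validation error: cells must be non-negative integers",
         call. = FALSE)
  }
  vapply(seq_along(a), function(i) {
    r1 <- a[[i]] + b[[i]] # test-set size
    r2 <- c[[i]] + d[[i]] # reference-only size
    k <- a[[i]] + c[[i]]  # features carrying the term
    if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
    support <- max(0, k - r2):min(k, r1)
    mass <- stats::dhyper(support, r1, r2, k)
    obs <- stats::dhyper(a[[i]], r1, r2, k)
    if (method == "probability") {
      min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
    } else {
      lower <- sum(mass[support <= a[[i]]])
      upper <- sum(mass[support >= a[[i]]])
      min(1, 2 * min(lower, upper))
    }
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR control: with `m` p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (q-values), same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("FDR validation error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' GO-term enrichment of a test set against a reference set
#'
#' For every term annotated to at least one test feature, builds the 2x2
#' table of term membership in the test set versus the rest of the reference
#' set, computes the two-tailed Fisher exact p, and controls FDR over all
#' tested terms with [bh_fdr()]. By default the reference side of the table
#' excludes the test features so the two columns are disjoint; set
#' `reference_includes_test = TRUE` for the inclusive variant.
#'
#' @param test_ids Feature ids of the test set (must be a subset of
#'   `reference_ids`).
#' @param reference_ids Feature ids of the reference set.
#' @param annotations Long-format annotation table
#'   ([read_go_annotations()]).
#' @param fdr_threshold Keep terms with `q` strictly below this (default
#'   0.05). Use `all = TRUE` to get every tested term regardless.
#' @param reference_includes_test Count test features on the reference side
#'   too (default `FALSE`).
#' @param method Passed to [fisher_exact_two_tailed()].
#' @param all Return all tested terms, not only those passing the FDR
#'   threshold.
#' @return Data frame with columns `term`, `a`, `b`, `c`, `d`, `p`, `q`,
#'   `direction` (`"over"` iff the term rate in the test set exceeds its
#'   rate in the comparison set), sorted by `q` then `p`.
#' @export
go_enrichment <- function(test_ids, reference_ids, annotations,
                          fdr_threshold = 0.05,
                          reference_includes_test = FALSE,
                          method = "probability", all = FALSE) {
  test_ids <- unique(test_ids)
  reference_ids <- unique(reference_ids)
  if (length(setdiff(test_ids, reference_ids)) > 0L) {
    stop("enrichment validation error: test set is not a subset of the ",
         "reference set", call. = FALSE)
  }
  ann <- unique(annotations[annotations$feature_id %in% reference_ids,
                            c("feature_id", "term"), drop = FALSE])
  in_test <- ann$feature_id %in% test_ids
  terms <- sort(unique(ann$term[in_test]))
  if (length(terms) == 0L) {
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p = numeric(0),
                      q = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  n_test <- length(test_ids)
  n_comp <- if (reference_includes_test) length(reference_ids) else
    length(reference_ids) - n_test
  a <- as.integer(table(factor(ann$term[in_test], levels = terms)))
  with_term_comp <- if (reference_includes_test) {
    as.integer(table(factor(ann$term, levels = terms)))
  } else {
    as.integer(table(factor(ann$term[!in_test], levels = terms)))
  }
  b <- n_test - a
  cc <- with_term_comp
  d <- n_comp - cc
  p <- fisher_exact_two_tailed(a, b, cc, d, method = method)
  q <- bh_fdr(p)
  rate_test <- ifelse(a + b > 0, a / (a + b), 0)
  rate_comp <- ifelse(cc + d > 0, cc / (cc + d), 0)
  out <- data.frame(term = terms, a = a, b = b, c = cc, d = d, p = p, q = q,
                    direction = ifelse(rate_test > rate_comp, "over", "under"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (all) out else out[out$q < fdr_threshold, , drop = FALSE]
}

.default_stop_words <- c("of", "the", "a", "an", "and", "or", "in", "to",
                         "by", "via", "for", "on", "with", "from", "into")

#' Word frequencies of enriched term names
#'
#' Lowercase whitespace tokenization of term names with a stop-word filter;
#' the usual input to a word-cloud summary of an enrichment result.
#'
#' @param terms Character vector of term ids (e.g. the `term` column of a
#'   [go_enrichment()] result).
#' @param term_names Named character vector mapping term ids to names;
#'   ids without a name are skipped.
#' @param stop_words Words to drop after lowercasing.
#' @return Data frame `word`, `count`, sorted by decreasing count then word.
#' @export
#' @examples
#' term_word_frequencies(c("GO:0000001", "GO:0000002"),
#'   c("GO:0000001" = "oxygen transport", "GO:0000002" = "gas transport"))
term_word_frequencies <- function(terms, term_names,
                                  stop_words = .default_stop_words) {
  nm <- term_names[terms]
  nm <- nm[!is.na(nm)]
  if (length(nm) == 0L) {
    return(data.frame(word = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  words <- unlist(strsplit(tolower(nm), "\\s+"))
  words <- words[nzchar(words) & !(words %in% stop_words)]
  tab <- table(words)
  out <- data.frame(word = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}
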