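# Shared builders for in-code fixtures.

make_hit <- function(query, subject, bit = 100, identity = 99,
                     evalue = 1e-30, qs = 1L, qe = 100L,
                     ss = 1L, se = 100L, len = 100L) {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = identity, alignment_length = as.integer(len),
             mismatches = 0L, gap_opens = 0L,
             q_start = as.integer(qs), q_end = as.integer(qe),
             s_start = as.integer(ss), s_end = as.integer(se),
             e_value = evalue, bit_score = bit, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

random_fasta <- function(n, min_len = 1L, max_len = 120L) {
  data.frame(
    id = sprintf("seq%04d", seq_len(n)),
    description = ifelse(seq_len(n) %% 3 == 0,
                         paste("desc", seq_len(n)), ""),
    sequence = vapply(sample(min_len:max_len, n, replace = TRUE),
                      function(l) paste0(sample(c("A", "C", "G", "T", "N",
                                                  "a", "c", "g", "t", "n"),
                                                l, replace = TRUE),
                                         collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

# a small placement set + sequences for group-construction tests
toy_group_inputs <- function() {
  seqs <- data.frame(
    id = c("s1", "s2", "s3"),
    description = "",
    sequence = c(strrep("ACGT", 25), strrep("GGCC", 20), "AACGTT"),
    stringsAsFactors = FALSE)
  placements <- data.frame(
    scaffold_id = c("s1", "s2", "s3"),
    status = "placed_dual", group = "SD1",
    order_key = c(100, 500, 900), rh_rank = NA_integer_,
    orientation = c("+", "-", "+"), stringsAsFactors = FALSE)
  list(sequences = seqs, placements = placements)
}

# independent enumeration oracle for the two-tailed exact test: iterate every
# table with the observed margins via binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
  xs <- max(0, k - r2):min(k, r1)
  mass <- choose(r1, xs) * choose(r2, k - xs) / choose(r1 + r2, k)
  obs <- choose(r1, a) * choose(r2, k - a) / choose(r1 + r2, k)
  min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
}
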