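# Shared fixtures and independent oracles, built in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# Independent sequon oracle: PCRE lookahead over every start position,
# a different mechanism from the package's vectorized character scan.
oracle_sequon_positions <- function(seq, classes = c("NxS", "NxT")) {
  third <- c(NxS = "S", NxT = "T", NxC = "C", NxV = "V")[classes]
  pat <- paste0("N(?=[^PX][", paste(third, collapse = ""), "])")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Canonical change-row key for comparing classifications with ground truth.
change_key <- function(d) {
  paste(d$canonical_id, d$isoform_id, d$status, d$canonical_pos, d$isoform_pos)
}

# Pair-exact agreement between a truth table and a predicted change table.
pair_agreement <- function(truth, predicted, pair_ids) {
  vapply(pair_ids, function(cid) {
    setequal(change_key(truth[truth$canonical_id == cid, , drop = FALSE]),
             change_key(predicted[predicted$canonical_id == cid, , drop = FALSE]))
  }, logical(1))
}

uniform_composition <- function() setNames(rep(1 / 20, 20), AA20)

# All arrangements of a small character multiset (exhaustive permutation
# oracle; only sensible for <= ~7 characters).
all_arrangements <- function(chars) {
  if (length(chars) == 1) return(list(chars))
  out <- list()
  for (i in seq_along(chars)) {
    rest <- all_arrangements(chars[-i])
    out <- c(out, lapply(rest, function(r) c(chars[i], r)))
  }
  out
}
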