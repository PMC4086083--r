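# Independent oracles used by the tests; deliberately simple and
# separate from the implementation paths they check.

# Brute-force linear-scan retrieval over a full fingerprint matrix.
linear_scan <- function(records, fps, query) {
  qfp <- fingerprint(query$record$smiles, query$space)
  d <- as.integer(colSums(abs(t(fps$values) - qfp$values)))
  ok <- passes_filters(records, query)
  cand <- which(ok)
  cand <- cand[order(d[cand], records$id[cand])]
  if (query$mode == "distance") {
    cand <- cand[d[cand] <= query$limit]
    if (length(cand) > 1000L) cand <- cand[seq_len(1000L)]
  } else {
    cand <- cand[seq_len(min(query$limit, length(cand)))]
  }
  data.frame(smiles = records$smiles[cand], id = records$id[cand],
             cbd = d[cand], stringsAsFactors = FALSE, row.names = NULL)
}

# Exhaustive active-decoy pair counting: P(active outranks decoy), ties 1/2.
pair_count_auc <- function(goodness, is_active) {
  a <- goodness[is_active]
  d <- goodness[!is_active]
  tot <- 0
  for (x in a) for (y in d) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(a) * length(d))
}

# Literal character counter for the SMILES fingerprint (keeps Cl/Br whole).
count_symbol <- function(s, sym) {
  if (sym %in% c("Cl", "Br")) {
    return(lengths(regmatches(s, gregexpr(sym, s, fixed = TRUE))))
  }
  s <- gsub("Cl|Br", "", s)  # two-char symbols never count as C/B/l/r
  sum(strsplit(s, "", fixed = TRUE)[[1]] == sym)
}

expect_same_structure <- function(got_smiles, want_smiles) {
  expect_identical(canonical_smiles(got_smiles), canonical_smiles(want_smiles))
}
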