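## Seeded synthetic-library generation. A fragment grammar (scaffolds
## with substitution slots x substituent set) guarantees every generated
## SMILES is chemically valid and drug-like, unlike random strings.
## Generated molecules then pass through the same standardization as any
## external library, so fixtures exercise the full pipeline.

## Scaffolds: %s marks a substitution slot (filled with "(R)" or removed).
FRAGMENT_SCAFFOLDS <- c(
  "c1ccc%scc1",                      # benzene
  "c1ccc%sc%sc1",                    # 1,2-disubstituted benzene
  "c1cc%sccc1%s",                    # 1,4-disubstituted benzene
  "c1cc%scc%sc1",                    # 1,3-disubstituted benzene
  "c1cc%scc%sc1%s",                  # 1,3,5-trisubstituted benzene
  "c1ccnc%sc1",                      # pyridine
  "c1cc%snc%sc1",                    # 2,4-disubstituted pyridine (ring N)
  "c1cnc%scn1",                      # pyrimidine
  "c1ccc2ccc%scc2c1",                # naphthalene
  "c1ccc2cc%sc%scc2c1",              # 2,3-disubstituted naphthalene
  "c1ccc2[nH]c%scc2c1",              # indole
  "c1ccc2nc%sccc2c1",                # quinoline
  "c1csc%sc1",                       # thiophene
  "c1coc%sc1",                       # furan
  "Cn1cc%snc1",                      # 1-methylimidazole
  "C1CCC%sCC1",                      # cyclohexane
  "C1CC%sCC%sC1",                    # 1,4-disubstituted cyclohexane
  "C1CCN%sCC1",                      # piperidine (N-substituted)
  "C1CN%sCCN1%s",                    # piperazine
  "C1CC%sCO1",                       # substituted oxolane
  "c1ccc(C%sC2CC2)cc1",              # phenyl-cyclopropyl linker
  "c1ccc(CC%s)cc1%s",                # phenethyl + para slot
  "c1ccc(O%s)cc1",                   # phenoxy
  "C%sC1CCCCC1",                     # cyclohexyl-methyl
  "c1cc2c(cc1%s)OCO2")               # benzodioxole

## Substituents, written to attach from the scaffold atom.
FRAGMENT_SUBSTITUENTS <- c(
  "", "C", "CC", "C(C)C", "CCC", "O", "OC", "OCC", "N", "NC", "N(C)C",
  "F", "Cl", "Br", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N", "C(=O)C",
  "CO", "CN", "CCN", "C(F)(F)F", "S(=O)(=O)N", "SC", "C=C", "CC(=O)O",
  "CCO", "[N+](=O)[O-]", "NCC")

.fill_scaffold <- function(scaffold, subs) {
  nslot <- lengths(regmatches(scaffold, gregexpr("%s", scaffold, fixed = TRUE)))
  pieces <- strsplit(scaffold, "%s", fixed = TRUE)[[1]]
  if (length(pieces) < nslot + 1L) pieces <- c(pieces, "")
  out <- pieces[1L]
  for (i in seq_len(nslot)) {
    s <- subs[i]
    out <- paste0(out, if (nzchar(s)) paste0("(", s, ")") else "", pieces[i + 1L])
  }
  out
}

## All scaffold x substituent combinations (slots filled independently).
.fragment_space <- function() {
  combos <- character(0)
  for (sc in FRAGMENT_SCAFFOLDS) {
    nslot <- lengths(regmatches(sc, gregexpr("%s", sc, fixed = TRUE)))
    grid <- expand.grid(rep(list(FRAGMENT_SUBSTITUENTS), nslot),
                        stringsAsFactors = FALSE)
    combos <- c(combos, vapply(seq_len(nrow(grid)), function(i)
      .fill_scaffold(sc, unlist(grid[i, ], use.names = FALSE)), character(1)))
  }
  unique(combos)
}

#' Generate a seeded synthetic compound library
#'
#' Samples the fragment grammar with a seeded generator, standardizes
#' every molecule (counter-ion removal is a no-op here; pH 7.4 rules do
#' apply) and keeps the first `n` unique canonical structures. Vendor
#' masks are drawn uniformly from `[1, 511]`. Deterministic per seed.
#'
#' @param n library size (`n >= 1`).
#' @param seed integer seed.
#' @param out optional path; when given the library is also written as a
#'   .smi file.
#' @return a `mol_records` data frame of `n` molecules with ids
#'   `SYN000001`...
#' @export
generate_library <- function(n, seed = 1L, out = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  withr::with_seed(as.integer(seed), {
    pool <- sample(.fragment_space())
    masks <- sample.int(511L, n, replace = TRUE)
  })
  seen <- character(0)
  std_all <- character(0)
  taken <- 0L
  chunk <- max(200L, n)
  while (length(std_all) < n) {
    if (taken >= length(pool)) {
      stop("fragment grammar exhausted before ", n,
           " unique molecules; enlarge the fragment set")
    }
    idx <- seq.int(taken + 1L, min(taken + chunk, length(pool)))
    taken <- max(idx)
    cand <- pool[idx]
    ## a rare slot combination can be chemically inconsistent; drop it
    cand <- cand[!is.na(canonical_smiles(cand))]
    std <- standardize_smiles(cand)
    new <- std[!(std %in% seen)]
    new <- new[!duplicated(new)]
    seen <- c(seen, new)
    std_all <- c(std_all, new)
  }
  std_all <- std_all[seq_len(n)]
  rec <- annotate_molecules(std_all, sprintf("SYN%06d", seq_len(n)), masks)
  if (!is.null(out)) write_smi(rec, out)
  rec
}

#' Bundled reference query molecules
#'
#' Named common drugs for documentation and testing, headed by
#' adrenaline. Queries are annotated as drawn (no pH adjustment), the
#' way a user-sketched query enters a search.
#'
#' @return a `mol_records` data frame with one row per query.
#' @export
reference_queries <- function() {
  smi <- c(adrenaline = "CNC[C@H](O)c1ccc(O)c(O)c1",
           paracetamol = "CC(=O)Nc1ccc(O)cc1",
           aspirin = "CC(=O)Oc1ccccc1C(=O)O",
           caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
           ibuprofen = "CC(C)Cc1ccc(C(C)C(=O)O)cc1")
  annotate_molecules(strip_counter_ions(smi), names(smi))
}

#' Construct well-separated integer-vector blobs
#'
#' Test fixture for the clustering module: `k` groups of `per_blob`
#' count-space fingerprint vectors whose intra-blob city-block spread is
#' at least 10x smaller than the inter-blob separation, so k-means must
#' recover the partition exactly.
#'
#' @param space `"mqn"` or `"smifp"` (count spaces).
#' @param k number of blobs.
#' @param per_blob points per blob.
#' @param seed integer seed.
#' @return list with integer matrix `values` (rows are points), integer
#'   vector `blob` (true membership) and `space`.
#' @export
make_blobs <- function(space = c("mqn", "smifp"), k, per_blob, seed = 1L) {
  space <- match.arg(space)
  d <- FP_LENGTHS[[space]]
  k <- as.integer(k)
  per_blob <- as.integer(per_blob)
  stopifnot(k >= 1L, per_blob >= 1L)
  withr::with_seed(as.integer(seed), {
    ## centers 100 apart in CBD on 5 dims; jitter moves a point by at
    ## most 3 (CBD), so spread <= 6 and separation/spread >= 10
    centers <- matrix(5L, nrow = k, ncol = d)
    for (j in seq_len(k)) centers[j, seq_len(5L)] <- 5L + 20L * (j - 1L)
    values <- centers[rep(seq_len(k), each = per_blob), , drop = FALSE]
    jitter_dims <- matrix(sample.int(d, 3L * nrow(values), replace = TRUE),
                          ncol = 3L)
    jitter_sign <- matrix(sample(c(-1L, 1L), 3L * nrow(values),
                                 replace = TRUE), ncol = 3L)
    for (i in seq_len(nrow(values))) {
      for (t in 1:3) {
        jd <- jitter_dims[i, t]
        values[i, jd] <- max(0L, values[i, jd] + jitter_sign[i, t])
      }
    }
  })
  list(values = values, blob = rep(seq_len(k), each = per_blob),
       space = space)
}
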