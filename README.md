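# fpbrowse

Multi-fingerprint similarity search for small-molecule SMILES libraries:
find the closest commercially-available-style analogs of a hit compound,
cluster them, and benchmark the retrieval machinery.

Medicinal chemists confirming a screening hit need its close structural
analogs. Given a library of molecules (SMILES + identifier + supplier
mask), `fpbrowse` standardizes every entry once, encodes it in four
complementary fingerprint spaces, and organizes each space as a hash
table keyed by the fingerprint **total sum** so that exact city-block
distance (CBD) nearest-neighbour queries touch only a small slice of the
library.

## The method

Two molecules represented by fingerprint vectors *A*, *B* with *K*
components are compared by the city-block distance

    CBD(A, B) = Σ_j |A_j − B_j|

or by the generalized Tanimoto coefficient

    T(A, B) = Σ A_j B_j / (Σ A_j² + Σ B_j² − Σ A_j B_j).

Because `|ΣA − ΣB| ≤ CBD(A, B)`, a query with total sum *s* and distance
bound *L* can only have neighbours in hash buckets keyed in
`[s − L, s + L]` — a query with total sum 100 and CBD ≤ 10 scans keys
90…110 only. Max Count searches expand buckets ring by ring in
increasing `|key − s|` and stop only when the running k-th smallest CBD
provably beats every unexplored ring, so results are exact, not greedy.

Four fingerprint spaces are provided:

| space | length | content |
|-------|--------|---------|
| `sfp` | 1024 bits | hashed linear atom–bond paths of 0–7 bonds |
| `ecfp4` | 1024 bits | circular environments of bond diameter 4 |
| `mqn` | 42 counts | atom / bond / polarity / topology counts |
| `smifp` | 34 counts | character counts of the canonical SMILES |

Standardization removes counter ions (largest fragment), applies a fixed
pH 7.4 ionization rule table (deprotonate carboxylic/sulfonic/phosphonic
acids, protonate aliphatic amines and amidines/guanidines), and annotates
each record with Hill formula, hydrogen-bond acceptor/donor counts and
oxygen/nitrogen counts, which double as query filters. Hit lists can be
grouped with seeded k-means (clusters reported largest-first, each with
a centroid representative), and actives/decoys decks are scored by
rank-sum ROC AUC and enrichment factors.

## Worked example

```r
library(fpbrowse)

lib <- generate_library(2000, seed = 1)      # seeded synthetic library
idx <- build_index(lib, "mqn")
adr <- reference_queries()[1, ]              # adrenaline
res <- search_index(idx, search_query(adr, "mqn", mode = "count", limit = 500))
res
#> <search result: 500 hits (mqn, count mode)>
head(res$hits, 3)
#>                           smiles        id cbd
#> 1        OCc1ccc(cc1N)CC(=O)[O-] SYN000200   3
#> 2         OCCc1ccc(c(c1)O)C(=O)N SYN001255   3
#> 3 [NH3+]Cc1ccc(c(c1)O)CC(=O)[O-] SYN001463   3
head(cbd_histogram(res))                     # count of hits per CBD
#> 3 4 5 6 7 8
#> 4 1 3 7 7 7

cl <- kmeans_cluster(res, "mqn", k = 50, seed = 1)
cl$representatives[1:3]                      # centroid compound per cluster
#>           1           2           3
#> "SYN000519" "SYN001097" "SYN000866"
```

The hit list is sorted by increasing CBD to the query (the molecule
itself would appear at distance 0); the histogram summarizes how
similarity decays with distance; cluster representatives give a focused,
diverse selection for purchase or retesting. The same steps are available
from the shell via `inst/cli/fpbrowse`
(`generate`, `build-index`, `search`, `cluster`, `benchmark`).

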