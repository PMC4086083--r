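---
title: "Methods: standardization, fingerprints and exact CBD retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardization, fingerprints and exact CBD retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fpbrowse` retrieves exact city-block-distance (CBD) nearest neighbours
of a query molecule in four fingerprint spaces, clusters the hit list,
and evaluates retrieval with standard virtual-screening statistics. This
vignette documents the model choices, the tunable parameters, the
numerical conventions, and what the synthetic test fixtures do and do
not demonstrate.

## Library standardization

Every molecule entering an index is standardized exactly once, at
library-build time:

1. **Canonicalization.** All SMILES handling is delegated to OpenBabel
   (through ChemmineOB/ChemmineR); the canonical SMILES string is the
   molecule's identity throughout the package, so any spelling of the
   same structure produces the same fingerprints.
2. **Counter-ion removal.** The fragment with the most heavy atoms is
   kept; ties go to the fragment with more carbons, then to the
   lexicographically smallest canonical string. This is a deterministic
   proxy for "remove the counter ion" that needs no salt dictionary.
3. **pH 7.4 ionization.** A fixed rule table rather than pKa
   prediction: carboxylic, sulfonic and phosphonic/phosphoric acid O–H
   groups are deprotonated; aliphatic primary/secondary/tertiary amines
   and the imine nitrogen of amidines and guanidines are protonated;
   anilines, amides, alcohols and phenols stay neutral. All matching
   sites are transformed (amino acids become zwitterions, diamines
   dications). The table covers the dominant drug-like cases and is
   deterministic and auditable; microspecies enumeration, tautomer
   canonicalization and site-specific pKa are deliberately out of scope.
4. **Annotation.** Hill-order molecular formula (net charge appended,
   e.g. `C2H3O2-`, so a salt form never collides with its neutral parent
   under the formula lock), hydrogen-bond acceptors (count of N + O
   atoms), donors (count of hydrogens on N or O), oxygen and nitrogen
   counts, and a 9-bit vendor mask.

Hydrogen counts come from a standard valence model on the kekulized
graph (charge-adjusted default valences), which reproduces hand counts
for the organic subset (e.g. adrenaline: C9H13NO3, 4 donors).

Queries are **not** re-ionized: a user-drawn query is searched as drawn,
mirroring how a sketched structure enters an interactive search. The
reference query set (`reference_queries()`) therefore reports the drawn,
neutral adrenaline.

One known limitation: stereochemistry is dropped during standardization
(the ionization round-trip passes through a 0-D MOL block without wedge
information). None of the fingerprints is stereo-aware, so retrieval
behaviour is unaffected.

## Fingerprint spaces

* **`sfp` (1024 bits).** All simple linear atom–bond paths of 0–7 bonds
  are enumerated; each path's token string (element symbols, lowercase
  for aromatic atoms, charge suffixes; `-`, `=`, `#` bond symbols; the
  lexicographically smaller of the two read directions) is hashed with
  FNV-1a (32-bit) and folded modulo 1024. The default maximum path
  length is 7 bonds.
* **`ecfp4` (1024 bits).** Circular environments of bond diameter 4
  (radius 0–2). Initial atom identifiers hash (atomic number, heavy
  degree, hydrogen count, formal charge, aromaticity, ring membership);
  each iteration hashes (radius, own identifier, sorted (bond order,
  neighbour identifier) pairs). An atom whose environment set does not
  grow at a radius emits no new identifier, so methane sets exactly one
  bit. Identifiers fold modulo 1024.
* **`mqn` (42 counts).** Atom counts (C, F, Cl, Br, I, S, P,
  acyclic/cyclic N, acyclic/cyclic O, heavy atoms), bond counts
  (acyclic/cyclic single, double, triple; rotatable), polarity counts
  (acceptor sites = lone pairs on N/O, acceptor atoms, donor sites =
  N/O-bound hydrogens, donor atoms, negative and positive formal
  charges) and topology counts (acyclic mono/di/tri/tetravalent and
  cyclic di/tri/tetravalent atoms; SSSR rings of size 3–9 and ≥10;
  atoms and bonds shared by two or more SSSR rings). Aromatic systems
  are kekulized first, since the bond classes have no aromatic
  category. Rotatable bond = acyclic single bond between two
  non-terminal heavy atoms, excluding amide C–N.
* **`smifp` (34 counts).** Literal character counts over the canonical
  SMILES: atoms `C c N n O o S s P F Cl Br I B`, `H`, the structural
  symbols `( ) [ ] = # - + / \ @`, and ring-closure digits `1`–`8`.
  `Cl`/`Br` count as single symbols; anything else is ignored. The
  published 34-symbol table is not reproduced in accessible form, so
  this table is the package's own documented choice in the same spirit
  (it covers every symbol the generator and common drug SMILES emit).

Hash-bit placement is a documented stable function of the token, not an
emulation of any proprietary fingerprint: vector lengths, invariance
under SMILES re-ordering and retrieval behaviour are the contract,
bit-for-bit parity with other toolkits is a non-goal.

SSSR uses the shortest cycle through each non-bridge edge as candidates
and keeps a GF(2)-independent subset of size *E* − *V* + *C*, smallest
rings first. For fused drug-like ring systems this matches the expected
ring counts (naphthalene: two 6-rings, one shared bond, two shared
atoms); the well-known ambiguity of SSSR in highly symmetric cages is
tolerated because both MQN components involved are counts over the
chosen set.

## The sum-keyed index and exact retrieval

For vectors with non-negative components,
`|sum(A) − sum(B)| ≤ CBD(A, B)`. Each space is therefore stored as a
hash table keyed by the fingerprint total sum: a query with sum *s* and
bound *L* scans only keys in `[max(0, s − L), s + L]` (sum 100, bound
10 → keys 90…110).

* **Max Distance** returns every filter-passing record with CBD ≤ L.
* **Max Count** expands key rings in increasing `|key − s|`, tracking
  the running k-th smallest CBD among collected candidates, and stops
  only when that value is *strictly* below the next ring's lower bound.
  The strict comparison matters: a candidate in an unexplored ring can
  still tie the k-th distance and win the deterministic id tie-break.
  With it, the result equals a brute-force linear scan exactly, which
  the test suite verifies over 20 random queries × 4 spaces × both
  modes × with/without filters on a 5000-molecule seeded library.

At most 1000 hits are ever returned (the count limit is clamped with a
warning; an over-long distance result is truncated to the 1000 nearest,
also with a warning). Hits are ordered by increasing CBD, ties by id, so
output files are byte-reproducible.

Vendor filtering uses a nonzero bitwise intersection
(`AND(record, wanted) ≠ 0`). Describing this as an OR test would accept
every record (the OR of nonzero masks is never zero), so the
intersection reading is the only one consistent with "any combination
of nine vendors". Property filters (formula/HBA/HBD locks, exact O and
N counts) compare against the query molecule's annotation.

## K-means clustering of hit lists

Clustering may use a different space than the search did. The engine is
Lloyd's algorithm on the raw fingerprint vectors under Euclidean
distance — a mean is well-defined there, which city-block k-medians
would not give without changing the cluster model. Choices:

* k-means++ initialization with an explicit integer seed; identical
  input and seed give identical assignments.
* Convergence when assignments stop changing; iteration cap 100.
* A cluster emptied during iteration is re-seeded with the point
  farthest from its current center.
* Clusters are reported in decreasing-size order; each cluster's
  representative is the member closest to the cluster mean (ties:
  smallest CBD to the original query, then id) and is written first in
  its block of the saved file.

The per-iteration within-cluster sum of squares is exposed
(`$objective`) and is non-increasing, and on well-separated data the
final partition agrees with `stats::kmeans`, which serves as an
independent cross-check in the tests.

## Screening benchmarks

`rank_deck()` orders a deck (disjoint actives and decoys) by ascending
CBD or descending Tanimoto to the query, ties by id. `roc_auc()` is the
rank-sum (Mann–Whitney) AUC with midrank tie correction — the
probability that a random active outranks a random decoy, ties counted
half — verified against exhaustive pair enumeration on small decks.
`roc_points()` steps through tie groups and integrates back to the same
AUC. `enrichment_factor(f)` selects the top `ceiling(f · N)` molecules
of the deterministic ranking and divides the active fraction recovered
by `f`; boundary ties follow the rank order rather than fractional
counting. With 10 actives in a 1000-molecule deck and a perfect
ranking, EF at 1% is exactly 100; EF at fraction 1 is exactly 1.

## Synthetic fixtures

`generate_library(n, seed)` samples a fragment grammar — ~25 drug-like
scaffolds (substituted benzenes, pyridine, pyrimidine, naphthalene,
indole, quinoline, five-membered heteroaromatics, saturated rings,
linkers) × 30 substituents over one to three substitution slots —
shuffles it with the seed, standardizes every candidate and keeps the
first *n* unique canonical structures; vendor masks are drawn uniformly
from [1, 511]. This guarantees valid, pharmaceutically plausible
chemistry, full determinism per seed, and non-degenerate fingerprints
in all four spaces.

What the fixtures do **not** emulate: the property and similarity
distributions of a real purchasable-compound collection (molecular-
weight spread, scaffold frequencies, salt forms, stereochemistry).
Passing the exactness and conformance suites therefore demonstrates
algorithmic correctness of standardization, encoding, pruning and
retrieval — not retrieval quality on any particular vendor catalog.

`make_blobs()` builds integer count-vectors in k groups whose
inter-center city-block separation (100) exceeds ten times the maximal
intra-blob spread (≤ 6), so exact k-means recovery is a guaranteed
property of the construction, not a tuned outcome.

Problem sizes used by the test suite — a 5000-molecule library for the
dimensionality and exactness suites, 2000 molecules for the retrieval
cap, 10 000 random vector pairs for the metric properties, 200 seeded
shuffles for the chance-AUC band — are the package's chosen validation
scales and run in a few minutes on one CPU.

## Degenerate inputs and edge conventions

* Tanimoto of two all-zero vectors is defined as 0 with a warning
  (0/0 otherwise); all-zero fingerprints indicate degenerate molecules.
* Bond-less molecules (a single atom) are built directly from the
  SMILES token, bypassing the MDL block reader, which mangles zero-bond
  records.
* Malformed library lines are skipped with a line-numbered warning; an
  empty library is an error; duplicate structures under distinct ids
  are retained.
* `#` starts a comment line in every text format; it is never treated
  as a comment character mid-line (triple-bond SMILES contain `#`).
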