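# Shared, lazily built fixtures. Helpers are sourced once per test run,
# so the cache environment persists across test files.

.fx <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- generate_library(5000, seed = 1)
  .fx$lib
}

fixture_graphs <- function() {
  if (is.null(.fx$graphs)) .fx$graphs <- mol_graphs(fixture_library()$smiles)
  .fx$graphs
}

fixture_index <- function(space) {
  key <- paste0("idx_", space)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- build_index(fixture_library(), space,
                              graphs = fixture_graphs())
  }
  .fx[[key]]
}

fixture_fps <- function(space) {
  idx <- fixture_index(space)
  list(space = space, values = idx$fp, total_sum = idx$sums)
}

small_library <- function() {
  if (is.null(.fx$small)) .fx$small <- generate_library(200, seed = 7)
  .fx$small
}
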