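test_that("bucket range follows the total-sum pruning bound", {
  expect_equal(unname(bucket_range(100, 10)), c(90L, 110L))
  expect_equal(unname(bucket_range(5, 10)), c(0L, 15L))
  expect_equal(unname(bucket_range(37, 0)), c(37L, 37L))
  expect_error(bucket_range(-1, 5), ">= 0")
  expect_error(bucket_range(5, -1), ">= 0")
})

test_that("index buckets are keyed by total sum and conserve the library", {
  lib <- small_library()
  idx <- build_index(lib, "mqn")
  expect_equal(idx$size, nrow(lib))
  expect_equal(sum(lengths(idx$buckets)), nrow(lib))
  for (key in names(idx$buckets)) {
    expect_true(all(idx$sums[idx$buckets[[key]]] == as.integer(key)))
  }
  # molecules with equal sums share a bucket, distinct sums do not
  dup <- table(idx$sums)
  expect_equal(length(idx$buckets), length(dup))
  expect_error(build_index(lib[0, ], "mqn"), "non-empty")
})

test_that("vendor and property filters implement the lock semantics", {
  lib <- small_library()
  q <- search_query("CCO", "mqn", vendors = 511L)
  expect_true(all(passes_filters(lib, q)))

  rec <- annotate_molecules(c("CCO", "CCN"), c("a", "b"),
                            c(bitwShiftL(1L, 2L) + 1L, 2L))  # 0b101, 0b010
  q4 <- search_query("CCO", "mqn", vendors = 4L)              # 0b100
  expect_equal(passes_filters(rec, q4), c(TRUE, FALSE))

  # formula lock rejects a non-isomer
  qf <- search_query("CNC[C@H](O)c1ccc(O)c(O)c1", "mqn", lock_formula = TRUE)
  cand <- annotate_molecules(c("CNC[C@H](O)c1ccc(O)c(O)c1", "NCCNc1ccc(O)cc1"),
                             c("adr", "other"))
  expect_equal(passes_filters(cand, qf), c(TRUE, FALSE))

  qo <- search_query("CCO", "mqn", oxygen = 2L, nitrogen = 0L)
  cand2 <- annotate_molecules(c("OCCO", "OCCN", "CCO"), c("x", "y", "z"))
  expect_equal(passes_filters(cand2, qo), c(TRUE, FALSE, FALSE))
})

test_that("searching the query's own library finds it at distance zero", {
  rec <- annotate_molecules("CC(=O)Oc1ccccc1C(=O)O", "aspirin")
  idx <- build_index(rec, "sfp")
  res <- search_index(idx, search_query(rec, "sfp", mode = "distance",
                                        limit = 0L))
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hits$cbd, 0L)
  expect_equal(res$hits$id, "aspirin")
})

test_that("space mismatch and over-limit requests are handled", {
  lib <- small_library()
  idx <- build_index(lib, "smifp")
  expect_error(search_index(idx, search_query("CCO", "mqn")), "space")
  expect_warning(q <- search_query("CCO", "smifp", mode = "count",
                                   limit = 5000L), "1000")
  expect_equal(q$limit, 1000L)
})

test_that("search equals the linear-scan oracle on a small library", {
  lib <- small_library()
  withr::local_seed(5)
  queries <- sample(nrow(lib), 5L)
  for (sp in c("mqn", "ecfp4")) {
    idx <- build_index(lib, sp)
    fps <- list(values = idx$fp)
    for (qi in queries) {
      for (mode in c("count", "distance")) {
        q <- search_query(lib[qi, ], sp, mode = mode,
                          limit = if (mode == "count") 25L else 30L)
        got <- search_index(idx, q)$hits
        want <- linear_scan(lib, fps, q)
        expect_identical(got, want)
      }
    }
  }
})

test_that("raising a Max Count limit never drops an earlier hit", {
  lib <- small_library()
  idx <- build_index(lib, "mqn")
  prev <- character(0)
  for (lim in c(5L, 15L, 40L, 100L)) {
    got <- search_index(idx, search_query(lib[3L, ], "mqn", mode = "count",
                                          limit = lim))$hits$id
    expect_identical(got[seq_along(prev)], prev)
    prev <- got
  }
})

test_that("hits are sorted by CBD with id tie-break and histogram tallies", {
  lib <- small_library()
  idx <- build_index(lib, "smifp")
  res <- search_index(idx, search_query(lib[10L, ], "smifp", mode = "count",
                                        limit = 50L))
  expect_true(!is.unsorted(res$hits$cbd))
  ties <- split(res$hits$id, res$hits$cbd)
  for (grp in ties) expect_identical(grp, sort(grp))

  h <- cbd_histogram(res)
  expect_equal(sum(h), nrow(res$hits))
  expect_equal(unname(h[as.character(res$hits$cbd[1])]),
               sum(res$hits$cbd == res$hits$cbd[1]))

  # hand tally on a constructed hit list
  hh <- fpbrowse:::cbd_histogram_hits(
    data.frame(smiles = "C", id = letters[1:4], cbd = c(0L, 2L, 2L, 3L)))
  expect_equal(hh, c(`0` = 1L, `2` = 2L, `3` = 1L))
  expect_length(fpbrowse:::cbd_histogram_hits(
    data.frame(smiles = character(0), id = character(0),
               cbd = integer(0))), 0L)
})

test_that("an index round-trips through its on-disk format", {
  lib <- small_library()[1:80, ]
  dir <- withr::local_tempdir()
  idx <- build_index(lib, "mqn")
  write_index(idx, dir)
  expect_true(file.exists(file.path(dir, "mqn.tsv")))
  back <- read_index(dir, "mqn")
  q <- search_query(lib[7L, ], "mqn", mode = "count", limit = 20L)
  expect_identical(search_index(back, q)$hits, search_index(idx, q)$hits)
  # dump rows are stored in ascending key order
  dump <- read_fingerprints(file.path(dir, "mqn.tsv"))
  expect_true(!is.unsorted(dump$fps$total_sum))
})

test_that("filters are honoured inside the exact search", {
  lib <- small_library()
  idx <- build_index(lib, "mqn")
  fps <- list(values = idx$fp)
  q <- search_query(lib[1L, ], "mqn", mode = "distance", limit = 40L,
                    vendors = 170L, lock_hba = TRUE)
  got <- search_index(idx, q)$hits
  want <- linear_scan(lib, fps, q)
  expect_identical(got, want)
  if (nrow(got) > 0L) {
    sub <- lib[match(got$id, lib$id), ]
    expect_true(all(bitwAnd(sub$vendor_mask, 170L) != 0L))
    expect_true(all(sub$hba == q$record$hba))
  }
})
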