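test_that("k-means recovers well-separated blobs exactly", {
  blobs <- make_blobs("mqn", k = 2, per_blob = 20, seed = 3)
  res <- kmeans_vectors(blobs$values, k = 2, seed = 11)
  split_got <- split(seq_along(res$assignments), res$assignments)
  split_want <- split(seq_along(blobs$blob), blobs$blob)
  expect_setequal(unname(lapply(split_got, sort)), unname(lapply(split_want, sort)))

  # three blobs, too
  b3 <- make_blobs("smifp", k = 3, per_blob = 10, seed = 5)
  r3 <- kmeans_vectors(b3$values, k = 3, seed = 2)
  expect_setequal(unname(lapply(split(seq_len(30), r3$assignments), sort)),
                  unname(lapply(split(seq_len(30), b3$blob), sort)))
})

test_that("identical inputs and seed give identical assignments", {
  blobs <- make_blobs("mqn", k = 4, per_blob = 15, seed = 8)
  r1 <- kmeans_vectors(blobs$values, k = 4, seed = 21)
  r2 <- kmeans_vectors(blobs$values, k = 4, seed = 21)
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$representatives, r2$representatives)
})

test_that("degenerate k values behave as specified", {
  blobs <- make_blobs("mqn", k = 3, per_blob = 4, seed = 1)
  x <- blobs$values
  n <- nrow(x)

  r1 <- kmeans_vectors(x, k = 1, seed = 5)
  expect_length(unique(r1$assignments), 1L)
  ctr <- colMeans(x)
  d <- colSums((t(x) - ctr)^2)
  expect_equal(unname(r1$representatives[1]),
               as.character(which.min(d)))

  rn <- kmeans_vectors(x, k = n, seed = 5)
  expect_equal(length(unique(rn$assignments)), n)  # all singletons
  expect_equal(max(rn$objective[length(rn$objective)]), 0)

  expect_error(kmeans_vectors(x, k = 0, seed = 1), "positive")
  expect_error(kmeans_vectors(x, k = n + 1, seed = 1), "exceeds")
})

test_that("the within-cluster objective never increases across iterations", {
  withr::local_seed(17)
  x <- matrix(rpois(60L * 42L, 4), nrow = 60L)
  for (seed in 1:5) {
    r <- kmeans_vectors(x, k = 5, seed = seed)
    expect_true(all(diff(r$objective) <= 1e-9))
  }
})

test_that("final partition agrees with stats::kmeans on separated data", {
  blobs <- make_blobs("mqn", k = 2, per_blob = 25, seed = 13)
  mine <- kmeans_vectors(blobs$values, k = 2, seed = 3)
  ref <- stats::kmeans(blobs$values, centers = 2, nstart = 10,
                       iter.max = 100)
  same <- split(seq_len(50), mine$assignments)
  theirs <- split(seq_len(50), ref$cluster)
  expect_setequal(unname(lapply(same, sort)), unname(lapply(theirs, sort)))
  expect_equal(mine$objective[length(mine$objective)], ref$tot.withinss,
               tolerance = 1e-8)
})

test_that("clusters are ordered by decreasing size with valid representatives", {
  lib <- small_library()
  idx <- build_index(lib, "mqn")
  res <- search_index(idx, search_query(lib[2L, ], "mqn", mode = "count",
                                        limit = 60L))
  cl <- kmeans_cluster(res, "smifp", k = 5, seed = 9)  # cross-space step
  sizes <- cl$sizes[as.character(cl$cluster_order)]
  expect_true(all(diff(sizes) <= 0))
  for (lab in cl$cluster_order) {
    rep_id <- cl$representatives[[as.character(lab)]]
    expect_true(rep_id %in% names(cl$assignments)[cl$assignments == lab])
  }
  expect_setequal(names(cl$assignments), res$hits$id)
})

test_that("saved cluster files round-trip with the representative first", {
  lib <- small_library()
  idx <- build_index(lib, "mqn")
  res <- search_index(idx, search_query(lib[4L, ], "mqn", mode = "count",
                                        limit = 40L))
  cl <- kmeans_cluster(res, "mqn", k = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  save_clusters(cl, res, path)
  back <- read_clusters(path)
  expect_equal(nrow(back), nrow(res$hits))
  expect_setequal(back$id, res$hits$id)
  expect_identical(stats::setNames(cl$assignments[back$id], back$id),
                   stats::setNames(back$cluster, back$id))
  first_rows <- back[!duplicated(back$cluster), ]
  for (i in seq_len(nrow(first_rows))) {
    lab <- as.character(first_rows$cluster[i])
    expect_equal(first_rows$id[i], unname(cl$representatives[[lab]]))
  }
})
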