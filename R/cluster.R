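## K-means grouping of a hit list in a chosen fingerprint space.
##
## Lloyd's algorithm on the raw fingerprint vectors (Euclidean distance,
## so cluster means are well defined), k-means++ initialization with an
## explicit seed, iteration cap 100, convergence when assignments stop
## changing. Clusters are reported in decreasing-size order and each
## cluster carries a representative: the member closest to the cluster
## mean (ties: smallest CBD to the original query, then id).

.sq_dist_to <- function(x, center) {
  colSums((t(x) - center)^2)
}

## k-means++ seeding; never duplicates a chosen point while distinct
## points remain.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  chosen <- integer(0)
  first <- sample.int(n, 1L)
  chosen <- first
  centers <- x[first, , drop = FALSE]
  d2 <- .sq_dist_to(x, centers[1L, ])
  while (length(chosen) < k) {
    pick <- if (sum(d2) > 0) {
      sample.int(n, 1L, prob = d2 / sum(d2))
    } else {
      setdiff(seq_len(n), chosen)[1L]
    }
    chosen <- c(chosen, pick)
    centers <- rbind(centers, x[pick, ])
    d2 <- pmin(d2, .sq_dist_to(x, x[pick, ]))
  }
  centers
}

.assign_nearest <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  cl <- max.col(-d2, ties.method = "first")
  list(cluster = cl, d2 = pmax(0, d2[cbind(seq_len(nrow(x)), cl)]))
}

#' K-means on raw fingerprint vectors
#'
#' The clustering engine behind [kmeans_cluster()], usable directly on a
#' matrix of fingerprint vectors (e.g. synthetic blobs). Seeded k-means++
#' initialization, Lloyd iterations capped at 100, convergence when
#' assignments are unchanged; an emptied cluster is re-seeded with the
#' point farthest from its current center.
#'
#' @param values numeric or integer matrix, one vector per row.
#' @param k number of clusters, `1 <= k <= nrow(values)`.
#' @param seed integer seed.
#' @param ids optional row identifiers (default row numbers as strings).
#' @param cbd optional per-row CBD to the original query, used only to
#'   break representative ties.
#' @return a `cluster_result` (see [kmeans_cluster()]); `objective` holds
#'   the within-cluster sum of squares after each assignment step.
#' @export
kmeans_vectors <- function(values, k, seed = 1L, ids = NULL, cbd = NULL) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- as.integer(k)
  if (is.na(k) || k <= 0L) stop("k must be a positive integer")
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(cbd)) cbd <- rep(0L, n)

  cl <- integer(n)
  objective <- numeric(0)
  iter <- 0L
  withr::with_seed(as.integer(seed), {
    centers <- .kmeanspp_init(x, k)
    assign_prev <- rep(0L, n)
    repeat {
      iter <- iter + 1L
      a <- .assign_nearest(x, centers)
      cl <- a$cluster
      empty <- setdiff(seq_len(k), unique(cl))
      for (e in empty) {
        far <- which.max(a$d2)
        centers[e, ] <- x[far, ]
        cl[far] <- e
        a$d2[far] <- 0
      }
      objective <- c(objective, sum(a$d2))
      if (identical(cl, assign_prev) || iter >= 100L) break
      assign_prev <- cl
      for (j in unique(cl)) {
        centers[j, ] <- colMeans(x[cl == j, , drop = FALSE])
      }
    }
  })

  sizes <- tabulate(cl, nbins = k)
  nonempty <- which(sizes > 0L)
  cluster_order <- nonempty[order(-sizes[nonempty], nonempty)]
  reps <- vapply(nonempty, function(j) {
    members <- which(cl == j)
    ctr <- colMeans(x[members, , drop = FALSE])
    d <- .sq_dist_to(x[members, , drop = FALSE], ctr)
    members[order(d, cbd[members], ids[members])][1L]
  }, integer(1))

  structure(list(k = k,
                 assignments = stats::setNames(cl, ids),
                 cluster_order = cluster_order,
                 sizes = stats::setNames(sizes[nonempty], nonempty),
                 representatives = stats::setNames(ids[reps], nonempty),
                 objective = objective,
                 iterations = iter),
            class = "cluster_result")
}

#' K-means clustering of a hit list
#'
#' Fingerprints the hit molecules in the requested space (which may
#' differ from the space they were searched in) and clusters the vectors
#' with [kmeans_vectors()].
#'
#' @param hits an `fp_search_result`, or a data frame with columns
#'   `smiles`, `id`, `cbd`.
#' @param space fingerprint space used for clustering.
#' @param k number of clusters, `1 <= k <=` number of hits.
#' @param seed integer seed for the k-means++ initialization.
#' @return a `cluster_result`: `k`, `assignments` (named by id),
#'   `cluster_order` (labels by decreasing size, ties by label),
#'   `sizes`, `representatives` (label -> member id), per-iteration
#'   `objective` and the iteration count.
#' @export
kmeans_cluster <- function(hits, space = c("sfp", "ecfp4", "mqn", "smifp"),
                           k, seed = 1L) {
  space <- match.arg(space)
  df <- if (inherits(hits, "fp_search_result")) hits$hits else hits
  x <- fingerprint_matrix(df$smiles, space, assume_canonical = TRUE)$values
  kmeans_vectors(x, k, seed = seed, ids = df$id, cbd = df$cbd)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster result: k = %d, %d non-empty clusters, sizes %s>\n",
              x$k, length(x$cluster_order),
              paste(x$sizes[as.character(x$cluster_order)], collapse = " ")))
  invisible(x)
}

#' Save a clustered hit list
#'
#' TSV with columns `smiles`, `id`, `cbd`, `cluster`; rows grouped by
#' cluster in decreasing-size order, the cluster representative first
#' within each block, remaining members by increasing CBD then id.
#'
#' @param result a `cluster_result`.
#' @param hits the hit list that was clustered (`fp_search_result` or
#'   data frame).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_clusters <- function(result, hits, path) {
  df <- if (inherits(hits, "fp_search_result")) hits$hits else hits
  stopifnot(nrow(df) == length(result$assignments),
            all(df$id == names(result$assignments)))
  rows <- list()
  for (lab in result$cluster_order) {
    members <- which(result$assignments == lab)
    rep_id <- result$representatives[[as.character(lab)]]
    rep_row <- members[df$id[members] == rep_id][1L]
    rest <- setdiff(members, rep_row)
    rest <- rest[order(df$cbd[rest], df$id[rest])]
    blk <- df[c(rep_row, rest), , drop = FALSE]
    blk$cluster <- lab
    rows[[length(rows) + 1L]] <- blk
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clustered hit list
#'
#' @param path path written by [save_clusters()].
#' @return data frame with `smiles`, `id`, `cbd`, `cluster`.
#' @export
read_clusters <- function(path) {
  .read_tsv(path, colClasses = c(smiles = "character", id = "character",
                                 cbd = "integer", cluster = "integer"))
}
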