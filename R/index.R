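## Sum-keyed index and exact city-block-distance retrieval.
##
## The library is organized as a hash table per fingerprint space whose
## key is the fingerprint total sum. Because |sum(A) - sum(B)| <= CBD(A, B),
## a query with total sum s and distance bound L only needs buckets with
## keys in [s - L, s + L]; scanning buckets in order of increasing |key - s|
## and stopping once the running k-th smallest CBD is <= the next ring's
## |key - s| makes Max Count retrieval exact, not greedy.

MAX_HITS <- 1000L

#' Total-sum bucket range for a distance bound
#'
#' A query fingerprint with total sum `query_sum` can only have neighbours
#' within `CBD <= max_cbd` in buckets keyed
#' `[max(0, query_sum - max_cbd), query_sum + max_cbd]` (e.g. sum 100,
#' bound 10 gives 90..110).
#'
#' @param query_sum non-negative total sum of the query fingerprint.
#' @param max_cbd non-negative distance bound.
#' @return integer vector `c(low, high)`.
#' @export
bucket_range <- function(query_sum, max_cbd) {
  if (query_sum < 0 || max_cbd < 0) stop("query_sum and max_cbd must be >= 0")
  c(low = max(0L, as.integer(query_sum) - as.integer(max_cbd)),
    high = as.integer(query_sum) + as.integer(max_cbd))
}

#' Build a sum-keyed fingerprint index
#'
#' @param records a `mol_records` data frame (see [annotate_molecules()]).
#' @param space fingerprint space to index.
#' @param graphs optional pre-parsed graphs from [mol_graphs()] matching
#'   `records$smiles`, shared when building several spaces over one
#'   library.
#' @return a `sum_key_index`: records, fingerprint matrix, total sums and
#'   the key -> row-index bucket map.
#' @export
build_index <- function(records, space = c("sfp", "ecfp4", "mqn", "smifp"),
                        graphs = NULL) {
  space <- match.arg(space)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty mol_records data frame")
  }
  fps <- fingerprint_matrix(records$smiles, space, graphs = graphs,
                            assume_canonical = TRUE)
  buckets <- split(seq_len(nrow(records)), fps$total_sum)
  structure(list(space = space, records = records, fp = fps$values,
                 sums = fps$total_sum, buckets = buckets,
                 size = nrow(records)),
            class = "sum_key_index")
}

#' @export
print.sum_key_index <- function(x, ...) {
  cat(sprintf("<sum_key_index %s: %d molecules, %d buckets, keys %d..%d>\n",
              x$space, x$size, length(x$buckets),
              min(x$sums), max(x$sums)))
  invisible(x)
}

#' Construct a search query
#'
#' @param smiles query molecule as a SMILES string (taken as drawn; not
#'   re-ionized), or a single-row `mol_records` data frame.
#' @param space fingerprint space to search.
#' @param mode `"count"` (Max Count) or `"distance"` (Max Distance).
#' @param limit number of hits (count mode, clamped to 1000) or CBD bound
#'   (distance mode).
#' @param vendors wanted 9-bit vendor mask in `[1, 511]`; a record
#'   matches when `bitwAnd(record mask, wanted mask) != 0`.
#' @param lock_formula,lock_hba,lock_hbd require hits to share the query
#'   molecule's formula / HBA count / HBD count.
#' @param oxygen,nitrogen optional exact oxygen / nitrogen atom counts.
#' @return a `search_query` object.
#' @export
search_query <- function(smiles, space = c("sfp", "ecfp4", "mqn", "smifp"),
                         mode = c("count", "distance"), limit = 100L,
                         vendors = 511L, lock_formula = FALSE,
                         lock_hba = FALSE, lock_hbd = FALSE,
                         oxygen = NULL, nitrogen = NULL) {
  space <- match.arg(space)
  mode <- match.arg(mode)
  vendors <- as.integer(vendors)
  if (is.na(vendors) || vendors < 1L || vendors > 511L) {
    stop("vendors must be a bit mask in [1, 511]")
  }
  limit <- as.integer(limit)
  if (is.na(limit) || limit < 0L) stop("limit must be a non-negative integer")
  if (mode == "count") {
    if (limit < 1L) stop("count limit must be >= 1")
    if (limit > MAX_HITS) {
      warning("Max Count clamped to ", MAX_HITS, " hits")
      limit <- MAX_HITS
    }
  }
  rec <- if (is.data.frame(smiles)) {
    smiles[1L, , drop = FALSE]
  } else {
    annotate_molecules(smiles, id = "query", vendor_mask = 511L)
  }
  structure(list(record = rec, space = space, mode = mode, limit = limit,
                 vendors = vendors,
                 filters = list(lock_formula = isTRUE(lock_formula),
                                lock_hba = isTRUE(lock_hba),
                                lock_hbd = isTRUE(lock_hbd),
                                oxygen = if (is.null(oxygen)) NULL else
                                  as.integer(oxygen),
                                nitrogen = if (is.null(nitrogen)) NULL else
                                  as.integer(nitrogen))),
            class = "search_query")
}

#' Vendor and property filter predicate
#'
#' @param records a `mol_records` data frame (any number of rows).
#' @param query a `search_query`.
#' @return logical vector: which records pass the query's vendor mask and
#'   property filters.
#' @export
passes_filters <- function(records, query) {
  q <- query$record
  f <- query$filters
  ok <- bitwAnd(records$vendor_mask, query$vendors) != 0L
  if (f$lock_formula) ok <- ok & records$formula == q$formula
  if (f$lock_hba) ok <- ok & records$hba == q$hba
  if (f$lock_hbd) ok <- ok & records$hbd == q$hbd
  if (!is.null(f$oxygen)) ok <- ok & records$n_oxygen == f$oxygen
  if (!is.null(f$nitrogen)) ok <- ok & records$n_nitrogen == f$nitrogen
  ok
}

.result <- function(hits, space, mode, limit, truncated) {
  structure(list(hits = hits, histogram = cbd_histogram_hits(hits),
                 space = space, mode = mode, limit = limit,
                 truncated = truncated),
            class = "fp_search_result")
}

cbd_histogram_hits <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(hits$cbd)
  stats::setNames(as.integer(tab), names(tab))
}

#' Count-per-CBD histogram of a search result
#'
#' @param result an `fp_search_result`.
#' @return named integer vector, names are CBD values; counts sum to the
#'   number of hits.
#' @export
cbd_histogram <- function(result) {
  stopifnot(inherits(result, "fp_search_result"))
  result$histogram
}

#' @export
print.fp_search_result <- function(x, ...) {
  cat(sprintf("<search result: %d hits (%s, %s mode)%s>\n", nrow(x$hits),
              x$space, x$mode, if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Exact nearest-neighbour search
#'
#' Scans index buckets in order of increasing difference in total sum from
#' the query. Distance mode returns all filter-passing records with
#' `CBD <= limit`; count mode returns exactly `min(limit, available)`
#' records with provably smallest CBD (ring expansion stops only when the
#' running k-th smallest CBD is no larger than the next ring's lower
#' bound). At most 1000 hits are returned in either mode; a distance-mode
#' result above that is truncated to the 1000 nearest with a warning.
#' Hits are sorted by increasing CBD, ties by id.
#'
#' @param index a `sum_key_index`.
#' @param query a `search_query` whose space matches the index.
#' @return an `fp_search_result` with `hits` (data frame `smiles`, `id`,
#'   `cbd`) and `histogram`.
#' @export
search_index <- function(index, query) {
  stopifnot(inherits(index, "sum_key_index"), inherits(query, "search_query"))
  if (index$space != query$space) {
    stop("index space (", index$space, ") does not match query space (",
         query$space, ")")
  }
  qfp <- fingerprint(query$record$smiles, query$space)
  qsum <- qfp$total_sum
  pass <- passes_filters(index$records, query)
  keys <- as.integer(names(index$buckets))

  empty <- data.frame(smiles = character(0), id = character(0),
                      cbd = integer(0), stringsAsFactors = FALSE)

  cand_rows <- function(sel_keys) {
    rows <- unlist(index$buckets[as.character(sel_keys)], use.names = FALSE)
    rows[pass[rows]]
  }
  cbd_rows <- function(rows) {
    if (length(rows) == 0L) return(integer(0))
    as.integer(colSums(abs(t(index$fp[rows, , drop = FALSE]) - qfp$values)))
  }
  finish <- function(rows, d, truncated = FALSE) {
    ord <- order(d, index$records$id[rows])
    rows <- rows[ord]; d <- d[ord]
    if (length(rows) > MAX_HITS) {
      warning("result truncated to the ", MAX_HITS, " nearest neighbours")
      rows <- rows[seq_len(MAX_HITS)]
      d <- d[seq_len(MAX_HITS)]
      truncated <- TRUE
    }
    hits <- data.frame(smiles = index$records$smiles[rows],
                       id = index$records$id[rows], cbd = d,
                       stringsAsFactors = FALSE, row.names = NULL)
    .result(hits, index$space, query$mode, query$limit, truncated)
  }

  if (query$mode == "distance") {
    rng <- bucket_range(qsum, query$limit)
    rows <- cand_rows(keys[keys >= rng["low"] & keys <= rng["high"]])
    d <- cbd_rows(rows)
    keep <- d <= query$limit
    return(finish(rows[keep], d[keep]))
  }

  ## count mode: ring expansion over |key - qsum| = 0, 1, 2, ...
  k <- query$limit
  dks <- sort(unique(abs(keys - qsum)))
  rows_all <- integer(0)
  d_all <- integer(0)
  for (ri in seq_along(dks)) {
    dk <- dks[ri]
    sel <- keys[abs(keys - qsum) == dk]
    rows <- cand_rows(sel)
    rows_all <- c(rows_all, rows)
    d_all <- c(d_all, cbd_rows(rows))
    if (length(d_all) >= k) {
      kth <- sort(d_all, partial = k)[k]
      next_lb <- if (ri < length(dks)) dks[ri + 1L] else Inf
      ## strict: an unexplored ring could still tie at the k-th CBD and
      ## win the id tie-break, so only stop once it provably cannot
      if (kth < next_lb) break
    }
  }
  if (length(rows_all) == 0L) return(finish(integer(0), integer(0)))
  ord <- order(d_all, index$records$id[rows_all])
  take <- ord[seq_len(min(k, length(ord)))]
  finish(rows_all[take], d_all[take])
}

## ---- persistence ----------------------------------------------------------

#' Write an index to a directory
#'
#' One fingerprint dump TSV per space (rows in ascending total-sum order)
#' plus a `records.tsv` with the annotated library.
#'
#' @param index a `sum_key_index`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_index <- function(index, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- order(index$sums, index$records$id)
  fps <- list(space = index$space,
              values = index$fp[ord, , drop = FALSE],
              total_sum = index$sums[ord])
  write_fingerprints(index$records$id[ord], fps,
                     file.path(dir, paste0(index$space, ".tsv")))
  rec_path <- file.path(dir, "records.tsv")
  utils::write.table(as.data.frame(index$records), rec_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an index from a directory
#'
#' @param dir directory written by [write_index()].
#' @param space fingerprint space to load.
#' @return a `sum_key_index`.
#' @export
read_index <- function(dir, space = c("sfp", "ecfp4", "mqn", "smifp")) {
  space <- match.arg(space)
  rec <- .read_tsv(file.path(dir, "records.tsv"),
                   colClasses = c(id = "character", smiles = "character",
                                  formula = "character"))
  class(rec) <- c("mol_records", "data.frame")
  dump <- read_fingerprints(file.path(dir, paste0(space, ".tsv")))
  ord <- match(rec$id, dump$ids)
  if (anyNA(ord)) stop("records.tsv and ", space, ".tsv ids do not match")
  fp <- dump$fps$values[ord, , drop = FALSE]
  sums <- dump$fps$total_sum[ord]
  buckets <- split(seq_len(nrow(rec)), sums)
  structure(list(space = space, records = rec, fp = fp, sums = sums,
                 buckets = buckets, size = nrow(rec)),
            class = "sum_key_index")
}

#' Write a hit list TSV
#'
#' Columns `smiles`, `id`, `cbd`, as in the browser's save-to-file
#' format.
#'
#' @param result an `fp_search_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hits <- function(result, path) {
  utils::write.table(result$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a hit list TSV
#'
#' @param path path written by [write_hits()].
#' @return data frame with `smiles`, `id`, `cbd`.
#' @export
read_hits <- function(path) {
  .read_tsv(path, colClasses = c(smiles = "character", id = "character",
                                 cbd = "integer"))
}

## TSV reader that skips whole '#' comment lines but leaves '#' inside
## fields (triple-bond SMILES!) alone.
.read_tsv <- function(path, colClasses = NA) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    colClasses = colClasses, comment.char = "")
}
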