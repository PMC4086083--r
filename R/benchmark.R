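## Ligand-based virtual screening evaluation: rank a deck of actives and
## decoys by similarity to a query, then score the ranking with the
## rank-sum ROC AUC and enrichment factors.

#' Assemble a screening deck
#'
#' @param actives,decoys `mol_records` data frames with disjoint id sets.
#' @param query query molecule: SMILES string or single-row
#'   `mol_records`.
#' @return a `screening_deck`.
#' @export
screening_deck <- function(actives, decoys, query) {
  stopifnot(is.data.frame(actives), is.data.frame(decoys),
            nrow(actives) > 0L, nrow(decoys) > 0L)
  if (length(intersect(actives$id, decoys$id)) > 0L) {
    stop("actives and decoys must have disjoint id sets")
  }
  rec <- if (is.data.frame(query)) query[1L, , drop = FALSE] else
    annotate_molecules(query, id = "query")
  structure(list(actives = actives, decoys = decoys, query = rec),
            class = "screening_deck")
}

#' Rank a deck by similarity to the query
#'
#' Orders all deck molecules by ascending city-block distance or
#' descending Tanimoto similarity to the query fingerprint; ties broken
#' by id.
#'
#' @param deck a `screening_deck`.
#' @param space fingerprint space.
#' @param scorer `"cbd"` or `"tanimoto"`.
#' @return data frame `id`, `score`, `is_active` in rank order.
#' @export
rank_deck <- function(deck, space = c("sfp", "ecfp4", "mqn", "smifp"),
                      scorer = c("cbd", "tanimoto")) {
  space <- match.arg(space)
  scorer <- match.arg(scorer)
  stopifnot(inherits(deck, "screening_deck"))
  all_rec <- rbind(as.data.frame(deck$actives), as.data.frame(deck$decoys))
  is_active <- c(rep(TRUE, nrow(deck$actives)), rep(FALSE, nrow(deck$decoys)))
  fps <- fingerprint_matrix(all_rec$smiles, space, assume_canonical = TRUE)
  qfp <- fingerprint(deck$query$smiles, space)
  score <- if (scorer == "cbd") {
    as.numeric(colSums(abs(t(fps$values) - qfp$values)))
  } else {
    apply(fps$values, 1L, function(v) {
      suppressWarnings(tanimoto(as.integer(v), qfp$values))
    })
  }
  ord <- if (scorer == "cbd") order(score, all_rec$id) else
    order(-score, all_rec$id)
  out <- data.frame(id = all_rec$id[ord], score = score[ord],
                    is_active = is_active[ord], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "higher_is_better") <- scorer != "cbd"
  out
}

.goodness <- function(ranked) {
  ## ranked is ordered best-first. rank_deck() tags the score direction;
  ## hand-built rankings fall back on sortedness (CBD-style scores
  ## ascend, similarity scores descend). Returns "higher = better".
  s <- ranked$score
  hib <- attr(ranked, "higher_is_better")
  if (is.null(hib)) hib <- !is.unsorted(rev(s))
  if (hib) s else -s
}

#' ROC AUC of a ranked deck
#'
#' Rank-sum (Mann-Whitney) AUC with midrank tie correction: the
#' probability that a random active scores better than a random decoy,
#' ties counted one half.
#'
#' @param ranked data frame from [rank_deck()] (columns `score`,
#'   `is_active`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(ranked) {
  act <- ranked$is_active
  na <- sum(act)
  nd <- sum(!act)
  if (na == 0L || nd == 0L) {
    stop("roc_auc needs at least one active and one decoy")
  }
  g <- .goodness(ranked)
  r <- rank(g, ties.method = "average")
  (sum(r[act]) - na * (na + 1) / 2) / (na * nd)
}

#' ROC curve points of a ranked deck
#'
#' Steps through the ranking best-first, grouping tied scores, and
#' returns cumulative (false-positive rate, true-positive rate) pairs
#' starting at (0, 0). The trapezoidal area under these points equals
#' [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return data frame with `fpr` and `tpr`, both monotone non-decreasing.
#' @export
roc_points <- function(ranked) {
  act <- ranked$is_active
  na <- sum(act)
  nd <- sum(!act)
  if (na == 0L || nd == 0L) {
    stop("roc_points needs at least one active and one decoy")
  }
  g <- .goodness(ranked)
  grp <- cumsum(!duplicated(-g))  # tie groups in best-first order
  tp <- cumsum(tapply(act, grp, sum))
  fp <- cumsum(tapply(!act, grp, sum))
  data.frame(fpr = c(0, unname(fp) / nd), tpr = c(0, unname(tp) / na))
}

#' Enrichment factor at a fraction of the screened deck
#'
#' `EF_f = (actives among the top ceiling(f * N) molecules / total
#' actives) / f`. The selection boundary follows the deterministic rank
#' order (ties broken by id at ranking time), not fractional counting.
#'
#' @inheritParams roc_auc
#' @param fraction screened fraction in `(0, 1]` (e.g. 0.001 for EF 0.1%).
#' @return non-negative enrichment factor; 1 when `fraction = 1`.
#' @export
enrichment_factor <- function(ranked, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  n <- nrow(ranked)
  na <- sum(ranked$is_active)
  if (na == 0L) stop("enrichment_factor needs at least one active")
  top <- ceiling(fraction * n)
  (sum(ranked$is_active[seq_len(top)]) / na) / fraction
}

#' Benchmark a deck across spaces and scorers
#'
#' @param deck a `screening_deck`.
#' @param spaces fingerprint spaces to evaluate.
#' @param scorers scoring functions to evaluate.
#' @param fractions enrichment-factor fractions.
#' @return data frame with one row per space x scorer: `space`, `scorer`,
#'   `auc` and one `ef_<fraction>` column per fraction.
#' @export
benchmark_deck <- function(deck, spaces = FP_SPACES,
                           scorers = c("cbd", "tanimoto"),
                           fractions = c(0.001, 0.01)) {
  rows <- list()
  for (sp in spaces) {
    for (sc in scorers) {
      ranked <- rank_deck(deck, sp, sc)
      row <- data.frame(space = sp, scorer = sc, auc = roc_auc(ranked),
                        stringsAsFactors = FALSE)
      for (f in fractions) {
        row[[sprintf("ef_%g", f)]] <- enrichment_factor(ranked, f)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
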