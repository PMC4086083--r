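## Similarity measures between fingerprint vectors.

.fp_values <- function(x) {
  if (inherits(x, "fpvec")) x$values else as.integer(x)
}
.fp_space <- function(x) if (inherits(x, "fpvec")) x$space else NA_character_

.check_pair <- function(a, b) {
  sa <- .fp_space(a); sb <- .fp_space(b)
  if (!is.na(sa) && !is.na(sb) && sa != sb) {
    stop("fingerprint space mismatch: ", sa, " vs ", sb)
  }
  va <- .fp_values(a); vb <- .fp_values(b)
  if (length(va) != length(vb)) stop("fingerprint length mismatch")
  list(a = va, b = vb)
}

#' City-block distance between two fingerprints
#'
#' `CBD(A, B) = sum_j |A_j - B_j|`. The index pruning bound guarantees
#' `|sum(A) - sum(B)| <= CBD(A, B)`, which is what makes total-sum bucket
#' pruning exact.
#'
#' @param a,b `fpvec` objects or plain integer vectors of equal length
#'   (and, for `fpvec`, equal space).
#' @return non-negative integer distance.
#' @export
cbd <- function(a, b) {
  p <- .check_pair(a, b)
  sum(abs(p$a - p$b))
}

#' Tanimoto similarity between two fingerprints
#'
#' Generalized (count-vector) form
#' `T = sum(A*B) / (sum(A^2) + sum(B^2) - sum(A*B))`; for binary vectors
#' this reduces to the classic bit formula. Two all-zero vectors return 0
#' with a warning (degenerate molecules).
#'
#' @inheritParams cbd
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  p <- .check_pair(a, b)
  ab <- sum(as.numeric(p$a) * p$b)
  denom <- sum(as.numeric(p$a)^2) + sum(as.numeric(p$b)^2) - ab
  if (denom == 0) {
    warning("Tanimoto of two all-zero fingerprints defined as 0")
    return(0)
  }
  ab / denom
}
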