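ranked_df <- function(score, is_active, higher_is_better) {
  ord <- order(if (higher_is_better) -score else score)
  out <- data.frame(id = sprintf("m%02d", seq_along(score))[ord],
                    score = score[ord], is_active = is_active[ord])
  attr(out, "higher_is_better") <- higher_is_better
  out
}

test_that("deck construction validates its inputs", {
  a <- annotate_molecules(c("CCO", "CCN"), c("a1", "a2"))
  d <- annotate_molecules(c("CCC", "CCCC"), c("d1", "d2"))
  expect_s3_class(screening_deck(a, d, "CCO"), "screening_deck")
  dup <- annotate_molecules("CCC", "a1")
  expect_error(screening_deck(a, dup, "CCO"), "disjoint")
  expect_error(screening_deck(a[0, ], d, "CCO"))
})

test_that("the query's own structure ranks first under both scorers", {
  lib <- small_library()
  actives <- lib[1:10, ]
  decoys <- lib[11:110, ]
  deck <- screening_deck(actives, decoys, actives[1L, ])
  for (sp in c("sfp", "mqn")) {
    for (sc in c("cbd", "tanimoto")) {
      r <- rank_deck(deck, sp, sc)
      expect_equal(r$id[1], actives$id[1])
      expect_true(r$is_active[1])
    }
  }
})

test_that("ranking order matches pairwise metric evaluation", {
  smi <- c("CCO", "CCCO", "CCCCO", "c1ccccc1", "CCN")
  rec <- annotate_molecules(smi, sprintf("m%d", 1:5))
  deck <- screening_deck(rec[1:2, ], rec[3:5, ], rec[1L, ])
  r <- rank_deck(deck, "mqn", "cbd")
  fps <- lapply(rec$smiles, fingerprint, space = "mqn")
  d <- vapply(fps, cbd, integer(1), b = fps[[1]])
  want <- rec$id[order(d, rec$id)]
  expect_equal(r$id, want)
  expect_equal(r$score, sort(as.numeric(d)))
})

test_that("AUC equals exhaustive pair counting, including ties", {
  # perfect separation and full inversion
  r_perfect <- ranked_df(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE), TRUE)
  expect_equal(roc_auc(r_perfect), 1.0)
  r_inverted <- ranked_df(c(9, 10, 1, 2), c(FALSE, FALSE, TRUE, TRUE), TRUE)
  expect_equal(roc_auc(r_inverted), 0.0)
  # one tied active-decoy pair: oracle gives (1 + 1 + 1 + 0.5)/4
  r_tie <- ranked_df(c(5, 3, 3, 1), c(TRUE, TRUE, FALSE, FALSE), TRUE)
  expect_equal(roc_auc(r_tie), pair_count_auc(r_tie$score, r_tie$is_active))
  expect_equal(roc_auc(r_tie), 0.875)

  withr::local_seed(2024)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    score <- sample(0:12, n, replace = TRUE)
    act <- seq_len(n) %in% sample(n, sample(1:(n - 1), 1))
    r <- ranked_df(score, act, higher_is_better = FALSE)
    g <- -r$score
    expect_equal(roc_auc(r), pair_count_auc(g, r$is_active))
  }

  expect_error(roc_auc(ranked_df(1:3, c(TRUE, TRUE, TRUE), TRUE)),
               "at least one")
})

test_that("ROC points are monotone and integrate to the rank-sum AUC", {
  withr::local_seed(7)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    r <- ranked_df(sample(0:8, n, replace = TRUE),
                   seq_len(n) %in% sample(n, sample(2:(n - 2), 1)),
                   higher_is_better = TRUE)
    pts <- roc_points(r)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[nrow(pts)], 1)
    trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                   utils::tail(pts$tpr, -1)) / 2)
    expect_equal(trap, roc_auc(r))
  }
})

test_that("enrichment factors follow the ceiling convention", {
  # 10 actives in 1000, top 1% (10 molecules) all active -> EF = 100
  act <- c(rep(TRUE, 10), rep(FALSE, 990))
  r <- ranked_df(seq_len(1000), act, higher_is_better = FALSE)
  expect_equal(enrichment_factor(r, 0.01), 100)
  # none of the actives in the selected fraction
  r2 <- ranked_df(seq_len(1000), rev(act), higher_is_better = FALSE)
  expect_equal(enrichment_factor(r2, 0.01), 0)
  # whole deck
  expect_equal(enrichment_factor(r, 1), 1)
  # ceiling: fraction 0.0015 of 1000 -> top 2
  expect_equal(enrichment_factor(r, 0.0015),
               (2 / 10) / 0.0015)
  expect_error(enrichment_factor(r, 0), "fraction")
  expect_error(enrichment_factor(r, 1.5), "fraction")
})

test_that("randomly labeled decks average to chance AUC", {
  score <- seq_len(200)
  aucs <- vapply(1:200, function(s) {
    act <- withr::with_seed(s, seq_len(200) %in% sample(200, 20))
    roc_auc(ranked_df(score, act, higher_is_better = FALSE))
  }, numeric(1))
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})

test_that("benchmark_deck reports every space/scorer/fraction combination", {
  lib <- small_library()
  deck <- screening_deck(lib[1:8, ], lib[9:88, ], lib[1L, ])
  rep_ <- benchmark_deck(deck, spaces = c("mqn", "smifp"),
                         scorers = c("cbd", "tanimoto"),
                         fractions = c(0.05, 1))
  expect_equal(nrow(rep_), 4L)
  expect_true(all(c("space", "scorer", "auc", "ef_0.05", "ef_1") %in%
                    names(rep_)))
  expect_true(all(rep_$auc >= 0 & rep_$auc <= 1))
  expect_true(all(rep_$ef_1 == 1))
})
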