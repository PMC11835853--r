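# IAP/AUC, cross-validation schemes, grid search and threshold metrics.

test_that("iap matches hand-computed pairwise probabilities", {
  expect_equal(iap(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(iap(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)   # separated
  expect_equal(iap(rep(2, 6), rep(c(1, 0), 3)), 0.5)     # all ties
  expect_error(iap(1:3, c(1, 1, 1)), "each class")
})

test_that("iap equals the brute-force pairwise count and pROC, ties included", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    scores <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)  # heavy ties
    labels <- c(1, 0, stats::rbinom(n - 2, 1, 0.5))
    expect_equal(iap(scores, labels), iap_brute(scores, labels),
                 tolerance = 1e-14)
    proc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(iap(scores, labels), proc, tolerance = 1e-12)
  }
})

test_that("iap is invariant under strictly monotone score transforms", {
  set.seed(13)
  scores <- stats::rnorm(30)
  labels <- stats::rbinom(30, 1, 0.5)
  labels[1:2] <- c(1, 0)
  expect_equal(iap(exp(scores), labels), iap(scores, labels))
  expect_equal(iap(rank(scores), labels), iap(scores, labels))
})

test_that("fast-path LOO equals retrain-from-scratch LOO bit-exactly", {
  set.seed(207)
  for (rep in 1:12) {
    n <- sample(6:30, 1)
    ex <- random_examples(n, vocab_size = sample(6:15, 1),
                          frac_path = stats::runif(1, 0.3, 0.7))
    fast <- loo_auc(ex, pl = 5, level = 5, method = "fast")
    slow <- loo_auc(ex, pl = 5, level = 5, method = "refit")
    expect_identical(fast$per_example_scores$score, slow$per_example_scores$score)
    expect_identical(fast$auc, slow$auc)
  }
})

test_that("disjoint-descriptor classes give all-zero held-out scores, AUC 0.5", {
  ex <- list(list(id = "p1", dset = dset_of("a"), label = "pathogenic"),
             list(id = "p2", dset = dset_of("b"), label = "pathogenic"),
             list(id = "b1", dset = dset_of("c"), label = "benign"),
             list(id = "b2", dset = dset_of("d"), label = "benign"))
  res <- loo_auc(ex, pl = 5, level = 5)
  expect_true(all(res$per_example_scores$score == 0))
  expect_equal(res$auc, 0.5)
})

test_that("duplicating a separable dataset does not hurt the LOO AUC", {
  # separable: the two classes use distinct vocabularies, two examples per
  # signature so support survives exclusion
  ex <- c(lapply(1:4, function(i)
    list(id = paste0("p", i), dset = dset_of(c("pa", paste0("px", (i + 1) %/% 2))),
         label = "pathogenic")),
    lapply(1:4, function(i)
      list(id = paste0("b", i), dset = dset_of(c("bn", paste0("bx", (i + 1) %/% 2))),
           label = "benign")))
  single <- loo_auc(ex, pl = 5, level = 5)
  doubled <- c(ex, lapply(ex, function(e) { e$id <- paste0(e$id, "-copy"); e }))
  expect_gte(loo_auc(doubled, pl = 5, level = 5)$auc, single$auc)
})

test_that("LOO rejects classes that exclusion would empty", {
  ex <- c(random_examples(5, frac_path = 0.2))   # 1 pathogenic
  expect_error(loo_auc(ex, pl = 5, level = 5), "2 examples per class")
})

test_that("k-fold CV is deterministic and order-independent", {
  set.seed(303)
  ex <- random_examples(30)
  a <- kfold_auc(ex, k = 5, seed = 9, pl = 5, level = 5)
  b <- kfold_auc(ex[sample(30)], k = 5, seed = 9, pl = 5, level = 5)
  expect_identical(a$auc, b$auc)
  expect_identical(a$per_example_scores, b$per_example_scores)
  c_ <- kfold_auc(ex, k = 5, seed = 10, pl = 5, level = 5)
  expect_false(identical(a$per_example_scores$score, c_$per_example_scores$score))
})

test_that("k = n reduces to leave-one-out", {
  set.seed(404)
  ex <- random_examples(10)
  kf <- kfold_auc(ex, k = 10, seed = 1, pl = 5, level = 5)
  loo <- loo_auc(ex, pl = 5, level = 5)
  ord <- order(loo$per_example_scores$id, method = "radix")
  expect_identical(kf$per_example_scores$score,
                   loo$per_example_scores$score[ord])
  expect_identical(kf$auc, loo$auc)
})

test_that("k-fold rejects degenerate inputs", {
  ex <- random_examples(10)
  expect_error(kfold_auc(ex, k = 1, seed = 1, pl = 5, level = 5), ">= 2")
  expect_error(kfold_auc(ex, k = 11, seed = 1, pl = 5, level = 5), "exceeds")
})

test_that("the default grid enumerates 154 configurations", {
  f <- formals(grid_search)
  pls <- eval(f$pls)
  levels <- eval(f$levels)
  expect_equal(length(pls), 14L)
  expect_equal(length(levels), 11L)
  expect_equal(length(pls) * length(levels), 154L)
})

test_that("grid search selects the best cell with a deterministic tie-break", {
  set.seed(55)
  data5 <- lapply(random_examples(12), function(e)
    list(id = e$id, graph = build_molecular_graph(random_peptide(3)),
         label = e$label))
  # same dataset for every pl: AUC identical across pl at fixed level, so
  # the tie must break toward the smaller pl
  provider <- function(pl) data5
  gr <- grid_search(provider, pls = c(5, 7), levels = c(5, 6))
  expect_equal(gr$n_cells, 4L)
  expect_true(all(gr$cells$valid))
  expect_equal(gr$best$pl, 5L)
  by_level <- split(gr$cells$auc_loo, gr$cells$level)
  for (lv in names(by_level))
    expect_equal(by_level[[lv]][1], by_level[[lv]][2])

  single <- grid_search(provider, pls = 5, levels = 5)
  expect_equal(single$n_cells, 1L)
  expect_equal(single$best$pl, 5L)
  expect_equal(single$best$level, 5L)
})

test_that("grid cells violating CV preconditions are marked invalid", {
  set.seed(56)
  good <- lapply(random_examples(10), function(e)
    list(id = e$id, graph = build_molecular_graph(random_peptide(2)),
         label = e$label))
  bad <- lapply(good, function(e) { e$label <- "pathogenic"; e })
  provider <- function(pl) if (pl == 5) bad else good
  gr <- grid_search(provider, pls = c(5, 7), levels = 5)
  expect_false(gr$cells$valid[gr$cells$pl == 5])
  expect_true(gr$cells$valid[gr$cells$pl == 7])
  expect_equal(gr$best$pl, 7L)

  all_bad <- function(pl) bad
  expect_error(grid_search(all_bad, pls = 5, levels = 5), "no valid grid cell")
})

test_that("classification metrics match the stated formulas", {
  perfect <- classification_metrics(c(1, 1, -1, -1), c(1, 1, 0, 0))
  expect_equal(perfect$ba, 1); expect_equal(perfect$mcc, 1); expect_equal(perfect$f, 1)

  # TP=3 FN=1 FP=1 TN=3
  m <- classification_metrics(c(1, 1, 1, -1, 1, -1, -1, -1),
                              c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(m$ba, 0.75); expect_equal(m$mcc, 0.5); expect_equal(m$f, 0.75)

  # everything predicted positive on balanced labels
  all_pos <- classification_metrics(rep(1, 8), rep(c(1, 0), 4))
  expect_equal(all_pos$ba, 0.5)
  expect_equal(all_pos$mcc, 0)      # empty marginal convention
  expect_equal(all_pos$f, 2 / 3)

  expect_error(classification_metrics(c(1, -1), c(1, 1)), "both classes")
})

test_that("metrics agree with independent textbook computations", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(6:60, 1)
    labels <- c(1, 0, stats::rbinom(n - 2, 1, stats::runif(1, 0.2, 0.8)))
    conf <- stats::rnorm(n) + labels
    m <- classification_metrics(conf, labels)
    pred <- as.integer(conf > 0)
    # MCC is the Pearson correlation of the binary vectors
    mcc_ind <- suppressWarnings(stats::cor(pred, labels))
    if (is.na(mcc_ind)) mcc_ind <- 0
    expect_equal(m$mcc, mcc_ind, tolerance = 1e-12)
    # BA from the two recalls
    ba_ind <- mean(c(mean(pred[labels == 1] == 1), mean(pred[labels == 0] == 0)))
    expect_equal(m$ba, ba_ind, tolerance = 1e-12)
    # F from precision and recall
    prec <- if (sum(pred) == 0) NA else sum(pred & labels) / sum(pred)
    rec <- sum(pred & labels) / sum(labels)
    f_ind <- if (is.na(prec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(m$f, f_ind, tolerance = 1e-12)
  }
})
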