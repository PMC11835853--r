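# Model validation: IAP/ROC-AUC, leave-one-out and stratified k-fold
# cross-validation, grid search over (peptide length, MNA level), and
# threshold classification metrics.

#' Invariant Accuracy of Prediction (tie-corrected ROC AUC)
#'
#' The probability that a randomly chosen positive example outscores a
#' randomly chosen negative one, with ties counted half:
#' `(#\{s_p > s_n\} + 0.5 * #\{s_p = s_n\}) / (n_pos * n_neg)`.
#' Numerically equal to the ROC AUC.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive (pathogenic).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' iap(c(3, 1, 2, 0), c(1, 1, 0, 0))  # 0.75
iap <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("iap needs at least one example of each class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

new_cv_result <- function(auc, scheme, per_example) {
  structure(list(auc = auc, scheme = scheme, per_example_scores = per_example),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", paste(unlist(x$scheme), collapse = "/"),
      "AUC =", format(x$auc, digits = 4),
      "on", nrow(x$per_example_scores), "examples\n")
  invisible(x)
}

check_examples <- function(examples, level) {
  labels <- vapply(examples, function(e) e$label, "")
  if (!all(labels %in% c("pathogenic", "benign")))
    stop("labels must be 'pathogenic' or 'benign'", call. = FALSE)
  lv <- vapply(examples, function(e) e$dset$level, 0L)
  if (any(lv != as.integer(level)))
    stop("mixed descriptor levels", call. = FALSE)
  labels == "pathogenic"
}

example_ids <- function(examples) {
  ids <- vapply(seq_along(examples), function(i)
    as.character(examples[[i]]$id %||% i), "")
  if (anyDuplicated(ids)) stop("duplicate example ids", call. = FALSE)
  ids
}

#' Leave-one-out cross-validated AUC
#'
#' Each example is scored by the model fitted on all other examples. The
#' default fast path decrements the fitted descriptor counts instead of
#' refitting, which is algebraically identical to a full refit (and is
#' verified to be bit-exact against `method = "refit"` in the test suite).
#'
#' @param examples Training examples as in [fit_sspr()].
#' @param pl,level Model configuration.
#' @param method `"fast"` (count decrement) or `"refit"` (naive oracle).
#' @return A `cv_result` with the pooled held-out AUC.
#' @export
loo_auc <- function(examples, pl, level, method = c("fast", "refit")) {
  method <- match.arg(method)
  is_path <- check_examples(examples, level)
  if (sum(is_path) < 2L || sum(!is_path) < 2L)
    stop("leave-one-out needs at least 2 examples per class", call. = FALSE)
  ids <- example_ids(examples)
  n <- length(examples)

  scores <- if (method == "fast") {
    items <- lapply(examples, function(e) unique(e$dset$items))
    vocab <- sort_c(unique(unlist(items)))
    idx <- lapply(items, match, vocab)
    n_d <- tabulate(unlist(idx), nbins = length(vocab))
    n_d_path <- tabulate(unlist(idx[is_path]), nbins = length(vocab))
    vapply(seq_len(n), function(e) {
      j <- idx[[e]]
      nd <- n_d[j] - 1L
      ndp <- n_d_path[j] - as.integer(is_path[[e]])
      mean((2 * ndp - nd) / (nd + 2))   # as in sspr_score
    }, 0)
  } else {
    vapply(seq_len(n), function(e) {
      m <- fit_sspr(examples[-e], pl = pl, level = level)
      sspr_score(m, examples[[e]]$dset)
    }, 0)
  }

  per <- data.frame(id = ids, score = scores,
                    label = ifelse(is_path, "pathogenic", "benign"),
                    stringsAsFactors = FALSE)
  new_cv_result(iap(scores, is_path), list(scheme = "loo"), per)
}

#' Stratified k-fold cross-validated AUC
#'
#' Examples are sorted canonically by id, shuffled per class with the
#' given seed, and dealt cyclically into `k` stratified folds (each
#' class's members continue the cycle where the previous class stopped,
#' so fold sizes stay even and `k = n` reduces exactly to leave-one-out);
#' the pooled out-of-fold scores give a single AUC. Deterministic for a
#' given seed and independent of the input order.
#'
#' @param examples Training examples as in [fit_sspr()].
#' @param k Number of folds (2 to the number of examples; every class
#'   needs at least 2 members so no training split loses a class).
#' @param seed Integer seed for the fold shuffle.
#' @param pl,level Model configuration.
#' @return A `cv_result`.
#' @export
kfold_auc <- function(examples, k = 5L, seed = 42L, pl, level) {
  if (!is.numeric(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > length(examples)) stop("k exceeds the number of examples", call. = FALSE)
  is_path <- check_examples(examples, level)
  if (min(sum(is_path), sum(!is_path)) < 2L)
    stop("each class needs at least 2 members", call. = FALSE)
  ids <- example_ids(examples)
  ord <- order(ids, method = "radix")   # canonical, input-order independent
  examples <- examples[ord]
  ids <- ids[ord]
  is_path <- is_path[ord]

  fold <- integer(length(examples))
  set.seed(seed)
  offset <- 0L
  for (cls in c(TRUE, FALSE)) {
    members <- which(is_path == cls)
    members <- members[sample.int(length(members))]
    fold[members] <- (offset + seq_along(members) - 1L) %% k + 1L
    offset <- offset + length(members)
  }

  scores <- numeric(length(examples))
  for (f in seq_len(k)) {
    test <- which(fold == f)
    m <- fit_sspr(examples[-test], pl = pl, level = level)
    scores[test] <- vapply(test, function(e) sspr_score(m, examples[[e]]$dset), 0)
  }
  per <- data.frame(id = ids, score = scores,
                    label = ifelse(is_path, "pathogenic", "benign"),
                    stringsAsFactors = FALSE)
  new_cv_result(iap(scores, is_path),
                list(scheme = "kfold", k = as.integer(k), seed = as.integer(seed)),
                per)
}

#' Grid search over peptide length and MNA level
#'
#' Evaluates the leave-one-out AUC of every (PL, level) cell and selects
#' the best model; the default odd peptide lengths 5-31 crossed with MNA
#' levels 5-15 give the full 154-cell grid. Ties are broken toward the
#' smaller peptide length, then the smaller level (prefer the simpler
#' model). Cells whose dataset violates the leave-one-out preconditions
#' are marked invalid and excluded from the argmax.
#'
#' @param provider Function `function(pl)` returning the dataset for one
#'   peptide length: a list of examples, each a list with `graph` (a
#'   `molgraph`), `label` and optional `id`.
#' @param pls Peptide lengths (default odd 5..31).
#' @param levels MNA levels (default 5..15).
#' @return A `grid_result`: `cells` data frame (`pl`, `level`, `auc_loo`,
#'   `valid`), `best` (list `pl`, `level`, `auc_loo`) and `n_cells`.
#' @export
grid_search <- function(provider, pls = seq(5L, 31L, by = 2L), levels = 5L:15L) {
  stopifnot(is.function(provider), length(pls) > 0L, length(levels) > 0L)
  max_level <- max(levels)
  cells <- expand.grid(level = sort(unique(as.integer(levels))),
                       pl = sort(unique(as.integer(pls))))[, c("pl", "level")]
  cells$auc_loo <- NA_real_
  cells$valid <- FALSE

  for (pl in sort(unique(as.integer(pls)))) {
    dataset <- provider(pl)
    key_sets <- lapply(dataset, function(e)
      mna_key_level_sets(e$graph, max_level))
    for (lv in sort(unique(as.integer(levels)))) {
      ex <- lapply(seq_along(dataset), function(i) {
        list(id = dataset[[i]]$id %||% i,
             dset = new_descriptor_set(key_sets[[i]][[lv + 1L]], lv, "key"),
             label = dataset[[i]]$label)
      })
      row <- which(cells$pl == pl & cells$level == lv)
      res <- tryCatch(loo_auc(ex, pl = pl, level = lv), error = function(e) NULL)
      if (!is.null(res)) {
        cells$auc_loo[row] <- res$auc
        cells$valid[row] <- TRUE
      }
    }
  }
  if (!any(cells$valid))
    stop("no valid grid cell: every dataset violates the CV preconditions",
         call. = FALSE)
  ok <- cells[cells$valid, ]
  ok <- ok[order(-ok$auc_loo, ok$pl, ok$level), ]
  best <- list(pl = ok$pl[[1]], level = ok$level[[1]], auc_loo = ok$auc_loo[[1]])
  structure(list(cells = cells, best = best, n_cells = nrow(cells)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", x$n_cells, "cells;",
      sum(x$cells$valid), "valid\n  best: PL", x$best$pl,
      "level", x$best$level, "AUC_LOO", format(x$best$auc_loo, digits = 4), "\n")
  invisible(x)
}

#' Threshold classification metrics
#'
#' Confusion-matrix metrics at `confidence > threshold` => predicted
#' pathogenic: balanced accuracy `BA = (TPR + TNR) / 2`, the Matthews
#' correlation coefficient (0 when any marginal is empty) and the
#' F-measure (0 when precision + recall = 0).
#'
#' @param confidences Numeric confidence values (Pa - Pi).
#' @param labels Logical or 0/1, `TRUE`/1 = pathogenic.
#' @param threshold Decision threshold, default 0.
#' @return List with `ba`, `mcc`, `f`, and the confusion counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(confidences, labels, threshold = 0) {
  labels <- as.logical(labels)
  stopifnot(length(confidences) == length(labels))
  if (all(labels) || !any(labels))
    stop("both classes must be present", call. = FALSE)
  pred <- confidences > threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  ba <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(ba = ba, mcc = mcc, f = f, tp = tp, fp = fp, tn = tn, fn = fn)
}
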