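# PASS-style naive-Bayes classifier over MNA descriptor sets.
#
# Per-descriptor evidence uses Laplace-smoothed class conditionals,
# P(path | d) = (n_d_path + 1) / (n_d + 2), pooled by the arithmetic mean
# of 2*P - 1 over the query's descriptors; descriptors unseen in training
# contribute 0. Pa and Pi are tie-half-weighted ECDF functionals of the
# per-class training-score distributions, so Confidence = Pa - Pi is a
# rank statistic of the raw score S.

#' Fit an SSPR naive-Bayes model
#'
#' @param examples List of training examples, each a list with `dset` (a
#'   `descriptor_set` from [mna_descriptor_set()]) and `label`
#'   (`"pathogenic"` or `"benign"`); an optional `id` is kept for
#'   reporting.
#' @param pl Peptide length the descriptor sets were built from (stored as
#'   model configuration).
#' @param level MNA level; must match every example's descriptor set.
#' @param min_count Drop descriptors occurring in fewer than `min_count`
#'   training examples (default 1 = keep all).
#' @return An object of class `sspr_model`.
#' @export
fit_sspr <- function(examples, pl, level, min_count = 1L) {
  if (!length(examples)) stop("no training examples", call. = FALSE)
  labels <- vapply(examples, function(e) e$label, "")
  if (!all(labels %in% c("pathogenic", "benign")))
    stop("labels must be 'pathogenic' or 'benign'", call. = FALSE)
  n_path <- sum(labels == "pathogenic")
  n_ben <- sum(labels == "benign")
  if (n_path == 0L || n_ben == 0L)
    stop("single-class training set: need both pathogenic and benign examples",
         call. = FALSE)
  lv <- vapply(examples, function(e) e$dset$level, 0L)
  if (any(lv != as.integer(level)))
    stop("mixed descriptor levels in training set", call. = FALSE)

  items <- lapply(examples, function(e) unique(e$dset$items))
  vocab <- sort_c(unique(unlist(items)))
  idx <- lapply(items, match, vocab)
  is_path <- labels == "pathogenic"
  n_d <- tabulate(unlist(idx), nbins = length(vocab))
  n_d_path <- tabulate(unlist(idx[is_path]), nbins = length(vocab))
  if (min_count > 1L) {
    keep <- n_d >= min_count
    vocab <- vocab[keep]
    n_d <- n_d[keep]
    n_d_path <- n_d_path[keep]
  }

  model <- structure(
    list(config = list(pl = as.integer(pl), level = as.integer(level),
                       min_count = as.integer(min_count)),
         n_path = n_path, n_ben = n_ben,
         vocab = vocab, n_d = n_d, n_d_path = n_d_path,
         score_path = numeric(0), score_ben = numeric(0),
         meta = list()),
    class = "sspr_model"
  )
  scores <- vapply(examples, function(e) sspr_score(model, e$dset), 0)
  model$score_path <- sort(scores[is_path])
  model$score_ben <- sort(scores[!is_path])
  model
}

#' @export
print.sspr_model <- function(x, ...) {
  cat("<sspr_model> PL", x$config$pl, "/ MNA level", x$config$level, "\n",
      " training:", x$n_path, "pathogenic,", x$n_ben, "benign;",
      length(x$vocab), "descriptors\n")
  if (!is.null(x$meta$auc_loo))
    cat("  AUC (leave-one-out):", format(x$meta$auc_loo, digits = 4), "\n")
  invisible(x)
}

#' Raw evidence score of a descriptor set
#'
#' `S = mean_d (2 * (n_d_path + 1) / (n_d + 2) - 1)` over the query's
#' descriptors; unseen descriptors contribute 0, so S lies in (-1, 1).
#'
#' @param model An `sspr_model`.
#' @param dset A `descriptor_set` (same level as the model).
#' @return Numeric scalar.
#' @export
sspr_score <- function(model, dset) {
  stopifnot(inherits(model, "sspr_model"), inherits(dset, "descriptor_set"))
  items <- unique(dset$items)
  if (!length(items)) stop("empty descriptor set", call. = FALSE)
  j <- match(items, model$vocab)
  nd <- ifelse(is.na(j), 0L, model$n_d[j])
  ndp <- ifelse(is.na(j), 0L, model$n_d_path[j])
  # (2*ndp - nd) / (nd + 2) == 2 * (ndp + 1) / (nd + 2) - 1, but with an
  # integer numerator, so class swap negates the score bit-exactly
  mean((2 * ndp - nd) / (nd + 2))
}

#' Predict Pa, Pi and Confidence for a descriptor set
#'
#' Pa is the tie-half-weighted fraction of pathogenic training scores
#' below the query score S; Pi the fraction of benign training scores
#' above S. Confidence = Pa - Pi; a positive Confidence classifies the
#' substitution as pathogenic.
#'
#' @param object An `sspr_model`.
#' @param dset A `descriptor_set`.
#' @param ... Unused.
#' @return List with `pa`, `pi`, `confidence`, `score`.
#' @export
predict.sspr_model <- function(object, dset, ...) {
  s <- sspr_score(object, dset)
  pa <- (sum(object$score_path < s) + 0.5 * sum(object$score_path == s)) /
    object$n_path
  pi_ <- (sum(object$score_ben > s) + 0.5 * sum(object$score_ben == s)) /
    object$n_ben
  list(pa = pa, pi = pi_, confidence = pa - pi_, score = s)
}

#' Serialize / restore an SSPR model
#'
#' Models are written as versioned JSON; score lists are stored as
#' 17-significant-digit strings, so `read_sspr_model(write_sspr_model(m))`
#' reproduces predictions bit-exactly. Gene metadata attached under
#' `model$meta` (gene, sequence, identifiers, cross-validated AUC) is
#' preserved.
#'
#' @param model An `sspr_model`.
#' @param path Destination file.
#' @return `write_sspr_model`: invisibly, `path`; `read_sspr_model`: the
#'   restored `sspr_model`.
#' @export
write_sspr_model <- function(model, path) {
  stopifnot(inherits(model, "sspr_model"))
  payload <- list(
    format = "mnapred-sspr-model", version = 1L,
    config = model$config,
    n_path = model$n_path, n_ben = model$n_ben,
    vocab = model$vocab, n_d = model$n_d, n_d_path = model$n_d_path,
    # %.17g round-trips IEEE doubles exactly; JSON numeric output does not
    score_path = sprintf("%.17g", model$score_path),
    score_ben = sprintf("%.17g", model$score_ben),
    meta = model$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sspr_model
#' @export
read_sspr_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mnapred-sspr-model"))
    stop("not an mnapred model file: ", path, call. = FALSE)
  structure(
    list(config = list(pl = as.integer(p$config$pl),
                       level = as.integer(p$config$level),
                       min_count = as.integer(p$config$min_count)),
         n_path = as.integer(p$n_path), n_ben = as.integer(p$n_ben),
         vocab = as.character(p$vocab),
         n_d = as.integer(p$n_d), n_d_path = as.integer(p$n_d_path),
         score_path = as.numeric(p$score_path),
         score_ben = as.numeric(p$score_ben),
         meta = as.list(p$meta)),
    class = "sspr_model"
  )
}
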