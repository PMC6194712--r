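#' Label candidate pairs against a gold standard
#'
#' A pair is `TP` when both proteins are co-members of at least one gold
#' complex, `FP` when both proteins occur somewhere in the gold database
#' but never share a complex (e.g. a ribosomal protein paired with a
#' proteasomal protein), and `unlabeled` otherwise.
#'
#' @param pairs Canonical pair data frame of candidate pairs.
#' @param db A [complex_db] restricted to the gold complexes in use
#'   (pass the subset's complexes when training on a derived subset).
#' @return Character vector of labels, one per pair, with attribute
#'   `counts` (named TP/FP/unlabeled totals).
#' @export
label_pairs <- function(pairs, db) {
  stopifnot(inherits(db, "complex_db"))
  if (length(db$complexes) == 0L) stop("empty gold standard")
  gold_keys <- pair_df_keys(complex_to_pairs(db))
  db_prot <- unique(unlist(db$complexes))
  keys <- pair_df_keys(pairs)
  both_in <- pairs$a %in% db_prot & pairs$b %in% db_prot
  labels <- ifelse(keys %in% gold_keys, "TP",
                   ifelse(both_in, "FP", "unlabeled"))
  attr(labels, "counts") <- c(TP = sum(labels == "TP"),
                              FP = sum(labels == "FP"),
                              unlabeled = sum(labels == "unlabeled"))
  labels
}

#' Similarity features for candidate pairs
#'
#' Per pair and dataset: zero-filled Pearson correlation, min-max
#' Euclidean distance and co-apex distance (absolute difference of the
#' maximum-intensity fractions). Features are averaged over the datasets
#' in which both profiles are computable; pairs computable in no dataset
#' are dropped.
#'
#' @param datasets List of filtered [cf_dataset] objects (or a single
#'   one).
#' @param pairs Canonical pair data frame.
#' @return Data frame `a`, `b`, `pearson_r`, `euclidean_d`, `coapex_d`,
#'   `n_datasets`; attribute `n_dropped` counts discarded pairs.
#' @export
build_features <- function(datasets, pairs) {
  if (inherits(datasets, "cf_dataset")) datasets <- list(datasets)
  acc <- matrix(0, nrow(pairs), 3L)
  cnt <- numeric(nrow(pairs))
  for (ds in datasets) {
    prot <- rownames(ds$mat)
    ia <- match(pairs$a, prot)
    ib <- match(pairs$b, prot)
    present <- !is.na(ia) & !is.na(ib)
    if (!any(present)) next
    zf <- ds$mat
    zf[is.na(zf)] <- 0
    cm <- dataset_cor_matrix(ds)
    nm <- t(apply(zf, 1L, minmax_norm))
    apex <- apply(zf, 1L, which.max)
    r <- cm[cbind(ia[present], ib[present])]
    d <- sqrt(rowSums((nm[ia[present], , drop = FALSE] -
                       nm[ib[present], , drop = FALSE])^2))
    ca <- abs(apex[ia[present]] - apex[ib[present]])
    ok <- !is.na(r) & !is.na(d)
    w <- which(present)[ok]
    acc[w, 1L] <- acc[w, 1L] + r[ok]
    acc[w, 2L] <- acc[w, 2L] + d[ok]
    acc[w, 3L] <- acc[w, 3L] + ca[ok]
    cnt[w] <- cnt[w] + 1
  }
  keep <- cnt > 0
  out <- data.frame(a = pairs$a[keep], b = pairs$b[keep],
                    pearson_r = acc[keep, 1L] / cnt[keep],
                    euclidean_d = acc[keep, 2L] / cnt[keep],
                    coapex_d = acc[keep, 3L] / cnt[keep],
                    n_datasets = as.integer(cnt[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

feature_cols <- c("pearson_r", "euclidean_d", "coapex_d")

#' Gaussian Naive Bayes for protein-pair classification
#'
#' Fits per-class feature means and variances (variance floor 1e-9) and
#' class priors from labelled pairs. The posterior probability of the
#' positive class is the classifier score used to rank candidate
#' interactions.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Character/factor vector of class labels (`"TP"` / `"FP"`).
#' @return Object of class `cf_nb`.
#' @export
naive_bayes_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("need exactly two classes")
  stats <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xi),
         var = pmax(apply(xi, 2L, stats::var), 1e-9),
         prior = nrow(xi) / nrow(x))
  })
  names(stats) <- classes
  structure(list(classes = classes, stats = stats,
                 features = colnames(x)), class = "cf_nb")
}

#' @export
print.cf_nb <- function(x, ...) {
  cat("Gaussian Naive Bayes:", paste(x$classes, collapse = " vs "),
      "on", length(x$features), "features\n")
  for (cl in x$classes) {
    cat("  ", cl, " (prior ", round(x$stats[[cl]]$prior, 3), "): mean = [",
        paste(signif(x$stats[[cl]]$mean, 3), collapse = ", "), "]\n",
        sep = "")
  }
  invisible(x)
}

#' Posterior probability of the positive class
#'
#' @param object A `cf_nb` model.
#' @param newdata Feature matrix/data frame with the training columns.
#' @param positive Class whose posterior is returned (default `"TP"`).
#' @param ... Unused.
#' @return Numeric vector of posterior probabilities.
#' @export
predict.cf_nb <- function(object, newdata, positive = "TP", ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  loglik <- vapply(object$classes, function(cl) {
    s <- object$stats[[cl]]
    ll <- rep(log(s$prior), nrow(x))
    for (j in seq_along(object$features)) {
      ll <- ll + stats::dnorm(x[, j], s$mean[j], sqrt(s$var[j]), log = TRUE)
    }
    ll
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) loglik <- matrix(loglik, nrow = 1L,
                                      dimnames = list(NULL, object$classes))
  m <- apply(loglik, 1L, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  post[, positive]
}

# Stratified fold assignment: each class is spread evenly over folds.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Cross-validated classifier scores for all pairs
#'
#' Labelled pairs are scored out-of-fold under stratified k-fold
#' cross-validation (so no pair is scored by a model that saw its
#' label); unlabeled pairs are scored by the model trained on all
#' labelled pairs.
#'
#' @param features Output of [build_features()].
#' @param labels Label vector from [label_pairs()] aligned with
#'   `features` rows.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @return `features` with added columns `label` and `score`.
#' @export
train_score_cv <- function(features, labels, n_folds = 10L, seed = 1L) {
  stopifnot(nrow(features) == length(labels))
  if (sum(labels == "TP") < 10L || sum(labels == "FP") < 10L) {
    stop("need >= 10 TP and >= 10 FP labelled pairs")
  }
  x <- as.matrix(features[, feature_cols])
  score <- rep(NA_real_, nrow(features))
  lab_idx <- which(labels != "unlabeled")
  y <- labels[lab_idx]
  n_folds <- min(n_folds, min(table(y)))
  set.seed(seed)
  folds <- stratified_folds(y, n_folds)
  for (f in seq_len(n_folds)) {
    train <- lab_idx[folds != f]
    test <- lab_idx[folds == f]
    fit <- naive_bayes_fit(x[train, , drop = FALSE], labels[train])
    score[test] <- predict(fit, x[test, , drop = FALSE])
  }
  if (any(labels == "unlabeled")) {
    fit_all <- naive_bayes_fit(x[lab_idx, , drop = FALSE], y)
    un <- which(labels == "unlabeled")
    score[un] <- predict(fit_all, x[un, , drop = FALSE])
  }
  out <- features
  out$label <- labels
  out$score <- score
  out
}

#' Precision-recall bookkeeping over ranked pairs
#'
#' Ranks pairs by descending classifier score (ties broken by canonical
#' pair order, so the ranking is deterministic) and accumulates TP/FP
#' counts over labelled pairs. Precision at rank k is `TP_k / (TP_k +
#' FP_k)` over the labelled pairs among the top k (`NA` before the first
#' labelled pair); recall is `TP_k / TP_total`. Unlabeled pairs occupy
#' ranks but never enter precision.
#'
#' @param scored Output of [train_score_cv()] (needs `a`, `b`, `score`,
#'   `label`).
#' @return `scored` sorted by rank with added columns `cum_tp`,
#'   `cum_fp`, `precision`, `recall`.
#' @export
precision_recall <- function(scored) {
  if (!any(scored$label == "TP")) stop("need at least one TP")
  ord <- order(-scored$score, scored$a, scored$b)
  out <- scored[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$cum_tp <- cumsum(out$label == "TP")
  out$cum_fp <- cumsum(out$label == "FP")
  denom <- out$cum_tp + out$cum_fp
  out$precision <- ifelse(denom > 0, out$cum_tp / denom, NA_real_)
  out$recall <- out$cum_tp / sum(out$label == "TP")
  out
}

#' Interactome at a fixed precision
#'
#' Finds the deepest rank whose cumulative precision still meets the
#' target and returns every pair above it — labelled and unlabeled alike
#' (unlabeled predictions count toward interactome size, not toward
#' precision).
#'
#' @param ranked Output of [precision_recall()].
#' @param target_precision Precision target in (0, 1].
#' @return List with `size`, `pairs` (data frame of the selected
#'   ranks) and `rank` (0 when the target is never reached).
#' @export
interactome_at_precision <- function(ranked, target_precision) {
  stopifnot(target_precision > 0, target_precision <= 1)
  ok <- which(!is.na(ranked$precision) &
                ranked$precision >= target_precision)
  if (length(ok) == 0L) {
    return(list(size = 0L, pairs = ranked[0, , drop = FALSE], rank = 0L))
  }
  k <- max(ok)
  list(size = k, pairs = ranked[seq_len(k), , drop = FALSE], rank = k)
}
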