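#' Pearson correlation of zero-filled chromatograms
#'
#' Missing fractions are replaced by zeros before computing the standard
#' Pearson correlation over the full fraction axis. Zero-filling treats
#' non-quantification as absence of protein, which is the conservative
#' reading for SILAC ratio chromatograms. If either vector has zero
#' variance after filling the correlation is undefined and `NA` is
#' returned; callers building tables exclude (and count) such pairs.
#'
#' @param x,y Numeric vectors on the same fraction axis; `NA` = missing.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @examples
#' pearson_zero_fill(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1))  # 1
#' @export
pearson_zero_fill <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must share the fraction axis")
  x <- zero_fill(x)
  y <- zero_fill(y)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

zero_fill <- function(x) {
  x[is.na(x)] <- 0
  x
}

# Min-max normalization to [0, 1]; constant vectors are degenerate (NA).
minmax_norm <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L]) return(rep(NA_real_, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Euclidean distance of min-max-normalized chromatograms
#'
#' Each chromatogram is zero-filled, then rescaled to minimum 0 and
#' maximum 1, and the Euclidean distance between the rescaled vectors is
#' returned. Constant profiles cannot be rescaled; such pairs yield `NA`
#' and are excluded from tables.
#'
#' @inheritParams pearson_zero_fill
#' @return Nonnegative distance, or `NA` if either profile is constant.
#' @examples
#' euclidean_minmax(c(0, 1, 0), c(1, 0, 1))  # sqrt(3)
#' @export
euclidean_minmax <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must share the fraction axis")
  x <- minmax_norm(zero_fill(x))
  y <- minmax_norm(zero_fill(y))
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  sqrt(sum((x - y)^2))
}

# All-vs-all zero-filled Pearson matrix for a dataset. Rows with zero
# variance after filling get NA rows/columns. Fast path used by the
# complex-level statistics, where every within-complex pair is needed.
dataset_cor_matrix <- function(dataset) {
  m <- dataset$mat
  m[is.na(m)] <- 0
  v <- apply(m, 1L, stats::var)
  ok <- v > 0
  cm <- matrix(NA_real_, nrow(m), nrow(m),
               dimnames = list(rownames(m), rownames(m)))
  if (sum(ok) >= 2L) cm[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  cm
}

#' Pairwise similarity table for a dataset
#'
#' Computes zero-filled Pearson correlation and min-max Euclidean
#' distance for every requested pair whose proteins are both present in
#' the dataset, labelling each pair `gold` or `non-gold`. Pairs with an
#' undefined metric (constant profile) are excluded; the number excluded
#' is attached as attribute `n_excluded`.
#'
#' @param dataset A [cf_dataset], already filtered (see
#'   [filter_min_fractions()]).
#' @param pairs Canonical pair data frame of candidate pairs.
#' @param gold Canonical pair data frame of gold-standard pairs.
#' @return Data frame with columns `a`, `b`, `dataset_id`, `pearson_r`,
#'   `euclidean_d`, `label`.
#' @export
pair_similarity_table <- function(dataset, pairs, gold) {
  stopifnot(inherits(dataset, "cf_dataset"))
  prot <- rownames(dataset$mat)
  keep <- pairs$a %in% prot & pairs$b %in% prot
  pairs <- pairs[keep, , drop = FALSE]
  n0 <- nrow(pairs)
  if (n0 == 0L) {
    out <- data.frame(a = character(0), b = character(0),
                      dataset_id = character(0), pearson_r = numeric(0),
                      euclidean_d = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  zf <- dataset$mat
  zf[is.na(zf)] <- 0
  cm <- dataset_cor_matrix(dataset)
  nm <- t(apply(zf, 1L, minmax_norm))
  ia <- match(pairs$a, prot)
  ib <- match(pairs$b, prot)
  r <- cm[cbind(ia, ib)]
  d <- sqrt(rowSums((nm[ia, , drop = FALSE] - nm[ib, , drop = FALSE])^2))
  gold_keys <- pair_df_keys(gold)
  out <- data.frame(a = pairs$a, b = pairs$b,
                    dataset_id = dataset$dataset_id,
                    pearson_r = r, euclidean_d = d,
                    label = ifelse(pair_df_keys(pairs) %in% gold_keys,
                                   "gold", "non-gold"),
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$pearson_r) & !is.na(out$euclidean_d)
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!ok)
  res
}

#' Fraction of anti-correlated pairs
#'
#' The share of pairs whose co-fractionation Pearson correlation falls
#' below a threshold — below 0, a conservative signature of
#' non-interaction.
#'
#' @param table A pair similarity table (or any data frame with a
#'   `pearson_r` column).
#' @param r_threshold Correlation threshold (default 0).
#' @return List with `fraction`, `n_below`, `n_total`.
#' @export
anticorrelated_fraction <- function(table, r_threshold = 0) {
  r <- table$pearson_r
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("empty similarity table: fraction undefined")
  n_below <- sum(r < r_threshold)
  list(fraction = n_below / length(r), n_below = n_below,
       n_total = length(r))
}

#' Per-evidence-code anti-correlation summary
#'
#' Groups gold pairs by the experimental evidence code behind each
#' database entry and reports, per code and dataset, the fraction of
#' anti-correlated pairs and the mean correlation. Codes with too few
#' pairs in a dataset are omitted for that dataset (default fewer than
#' 100, so only well-populated codes are summarized).
#'
#' @param table Pair similarity table covering one or more datasets.
#' @param codes Character vector, one evidence code per row of `table`.
#' @param r_threshold Anti-correlation threshold (default 0).
#' @param min_pairs_per_code Minimum pairs per (code, dataset) cell.
#' @return Data frame with columns `dataset_id`, `evidence_code`,
#'   `n_pairs`, `frac_anticorrelated`, `mean_r`.
#' @export
stratify_by_evidence_code <- function(table, codes, r_threshold = 0,
                                      min_pairs_per_code = 100L) {
  if (length(codes) != nrow(table)) stop("one evidence code per table row required")
  key <- paste(table$dataset_id, codes, sep = "\r")
  groups <- split(table$pearson_r, key)
  rows <- lapply(names(groups), function(g) {
    r <- groups[[g]][!is.na(groups[[g]])]
    if (length(r) < min_pairs_per_code) return(NULL)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    data.frame(dataset_id = parts[1L],
               evidence_code = parts[2L],
               n_pairs = length(r),
               frac_anticorrelated = mean(r < r_threshold),
               mean_r = mean(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(dataset_id = character(0), evidence_code = character(0),
                      n_pairs = integer(0), frac_anticorrelated = numeric(0),
                      mean_r = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(out$dataset_id, out$evidence_code), , drop = FALSE]
}
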