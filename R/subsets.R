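#' Co-fractionation-specific gold-standard subset
#'
#' Selects the complexes that are significantly enriched for interactions
#' (hypergeometric p below `threshold`) in *every* chosen interactome,
#' and derives the unique within-complex pair set of the selection. At
#' `threshold = 1` the criterion reduces to having at least one
#' within-complex edge in each interactome. An any-k-of-n mode is
#' available through `min_supporting` but conjunction over all
#' interactomes is the default.
#'
#' @param db A [complex_db].
#' @param records List of [enrich_complexes()] outputs for the chosen
#'   interactomes (e.g. the three external CF studies).
#' @param threshold P-value threshold; the conventional ladder is
#'   1, 1e-2, 1e-6, 1e-10.
#' @param min_supporting Number of interactomes that must support a
#'   complex (`NULL` = all of them).
#' @return An object of class `gold_subset`: list with `threshold`,
#'   `complex_ids`, `pairs` (canonical pair data frame), `provenance`.
#' @export
cf_specific_subset <- function(db, records, threshold,
                               min_supporting = NULL) {
  stopifnot(inherits(db, "complex_db"), length(records) >= 1L,
            threshold > 0)
  if (is.null(min_supporting)) min_supporting <- length(records)
  support <- lapply(records, function(r) {
    if (threshold >= 1) r$complex_id[r$predicted_flag]
    else r$complex_id[r$p_hyper < threshold]
  })
  tab <- table(unlist(support))
  ids <- sort(names(tab)[tab >= min_supporting])
  sub_db <- db
  sub_db$complexes <- db$complexes[ids]
  sub_db$names <- db$names[ids]
  structure(list(threshold = threshold,
                 complex_ids = ids,
                 pairs = complex_to_pairs(sub_db),
                 provenance = vapply(records, function(r) {
                   if (nrow(r) > 0L) r$interactome_label[1L] else NA_character_
                 }, "")),
            class = "gold_subset")
}

#' @export
print.gold_subset <- function(x, ...) {
  cat("gold_subset (p < ", format(x$threshold), "): ",
      length(x$complex_ids), " complexes, ", nrow(x$pairs),
      " unique pairs [", paste(x$provenance, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Random gold-standard pair subset
#'
#' Uniform sample of unique gold pairs without replacement; the
#' size-matched control for a derived subset.
#'
#' @param pairs Canonical pair data frame (the full gold pair pool).
#' @param size Number of pairs to draw (`0 <= size <= nrow(pairs)`).
#' @param seed Integer seed.
#' @return Canonical pair data frame of `size` rows.
#' @export
random_subset <- function(pairs, size, seed = 1L) {
  if (size > nrow(pairs)) stop("size exceeds the pair pool")
  set.seed(seed)
  out <- pairs[sample.int(nrow(pairs), size), , drop = FALSE]
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a threshold ladder of gold subsets
#'
#' Writes a TSV with one row per complex in the loosest subset and one
#' boolean column per threshold, mirroring the usual supplementary-table
#' layout for consistently co-fractionating complexes.
#'
#' @param subsets List of `gold_subset` objects (any order; columns are
#'   emitted loosest to strictest).
#' @param db A [complex_db] supplying complex names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_subset <- function(subsets, db, path) {
  stopifnot(length(subsets) >= 1L,
            all(vapply(subsets, inherits, TRUE, "gold_subset")))
  thr <- vapply(subsets, `[[`, 0, "threshold")
  ord <- order(thr, decreasing = TRUE)
  subsets <- subsets[ord]
  thr <- thr[ord]
  ids <- subsets[[1L]]$complex_ids
  df <- data.frame(complex_id = ids,
                   complex_name = unname(db$names[ids]),
                   stringsAsFactors = FALSE)
  for (i in seq_along(subsets)) {
    df[[paste0("p < ", format(thr[i]))]] <- ids %in% subsets[[i]]$complex_ids
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported subset table
#'
#' @param path Path written by [export_subset()].
#' @return Data frame with `complex_id`, `complex_name` and one logical
#'   column per threshold.
#' @export
read_subset_export <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  for (j in seq_len(ncol(df))[-(1:2)]) df[[j]] <- as.logical(df[[j]])
  df
}
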