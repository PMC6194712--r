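#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items from a
#' population of `N` containing `K` successes.
#'
#' @param k Observed success count, `0 <= k <= min(n, K)`.
#' @param K Successes in the population.
#' @param n Draws.
#' @param N Population size.
#' @return Probability in (0, 1]; `k = 0` always gives 1.
#' @examples
#' hypergeometric_upper_tail(3, 4, 3, 10)  # choose(4,3)/choose(10,3)
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || n > N || K > N || k > min(n, K)) {
    stop("invalid hypergeometric parameters (need 0 <= k <= min(n, K), n <= N, K <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Map interactome edges onto complexes
#'
#' The universe is the set of proteins that appear in the interactome's
#' edge list and belong to at least one complex. For each complex with at
#' least one within-complex pair inside that universe, counts the pairs
#' possible and the pairs actually present as edges. Complexes with
#' fewer than two members in the universe are unobserved and absent from
#' the result.
#'
#' @param intx An [interactome].
#' @param db A [complex_db].
#' @return Data frame with columns `complex_id`, `n_members_in_universe`,
#'   `n_pairs_possible`, `n_pairs_predicted`.
#' @export
map_edges_to_complexes <- function(intx, db) {
  stopifnot(inherits(intx, "interactome"), inherits(db, "complex_db"))
  members_all <- unique(unlist(db$complexes))
  universe <- intersect(unique(c(intx$edges$a, intx$edges$b)), members_all)
  edge_keys <- pair_df_keys(intx$edges)
  rows <- lapply(names(db$complexes), function(cid) {
    m <- intersect(db$complexes[[cid]], universe)
    if (length(m) < 2L) return(NULL)
    idx <- utils::combn(sort(m), 2L)
    keys <- pair_key(idx[1L, ], idx[2L, ])
    data.frame(complex_id = cid,
               n_members_in_universe = length(m),
               n_pairs_possible = length(keys),
               n_pairs_predicted = sum(keys %in% edge_keys),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(complex_id = character(0),
                      n_members_in_universe = integer(0),
                      n_pairs_possible = integer(0),
                      n_pairs_predicted = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-complex enrichment of interactome edges
#'
#' Tests, per complex, whether the interactome places more edges among
#' the complex's members than the database-wide average rate. With `K`
#' the total number of predicted within-complex pairs and `N` the total
#' possible across all observed complexes, each complex's
#' `n_pairs_predicted` is referred to Hypergeometric(N, K,
#' `n_pairs_possible`). The universe is deliberately restricted to
#' within-complex pairs over proteins seen in the interactome, making
#' "the average rate" the within-database edge density.
#'
#' @inheritParams map_edges_to_complexes
#' @return Data frame: the [map_edges_to_complexes()] columns plus
#'   `interactome_label`, `p_hyper`, `predicted_flag` (>= 1 edge) and
#'   `could_predict`.
#' @export
enrich_complexes <- function(intx, db) {
  counts <- map_edges_to_complexes(intx, db)
  N <- sum(counts$n_pairs_possible)
  K <- sum(counts$n_pairs_predicted)
  counts$interactome_label <- rep(intx$label, nrow(counts))
  counts$p_hyper <- vapply(seq_len(nrow(counts)), function(i) {
    hypergeometric_upper_tail(counts$n_pairs_predicted[i], K,
                              counts$n_pairs_possible[i], N)
  }, 0)
  counts$predicted_flag <- counts$n_pairs_predicted >= 1L
  counts$could_predict <- vapply(counts$complex_id, function(cid) {
    could_predict(db$complexes[[cid]], intx)
  }, TRUE)
  counts
}

#' Could a complex have been predicted by a study?
#'
#' Technique-specific control for expression and bait choice. CF: at
#' least two co-complex members present in the quantified raw data.
#' AP-MS (matrix model): at least two members present among the
#' interactome's proteins. Y2H: at least one member used as a bait.
#'
#' @param members Character vector of complex member accessions.
#' @param intx An [interactome]; CF requires its `quantified` roster,
#'   Y2H its `baits`.
#' @return Logical scalar.
#' @export
could_predict <- function(members, intx) {
  stopifnot(inherits(intx, "interactome"))
  switch(intx$technique,
    "CF" = {
      if (is.null(intx$quantified)) stop("CF interactome needs a quantified-protein roster")
      sum(members %in% intx$quantified) >= 2L
    },
    "AP-MS" = {
      prots <- unique(c(intx$edges$a, intx$edges$b))
      sum(members %in% prots) >= 2L
    },
    "Y2H" = {
      if (is.null(intx$baits)) stop("Y2H interactome needs a bait list")
      any(members %in% intx$baits)
    })
}

# predicted_flag records (one enrich_complexes() output per interactome)
# -> complexes x interactomes logical matrix, FALSE where unobserved.
predicted_flag_matrix <- function(records) {
  labels <- vapply(records, function(r) r$interactome_label[1L], "")
  if (anyDuplicated(labels)) stop("duplicate interactome labels")
  complexes <- sort(unique(unlist(lapply(records, `[[`, "complex_id"))))
  flags <- matrix(FALSE, length(complexes), length(records),
                  dimnames = list(complexes, labels))
  for (j in seq_along(records)) {
    r <- records[[j]]
    flags[r$complex_id[r$predicted_flag], j] <- TRUE
  }
  flags
}

# Default "at least 2/3 of the technique's interactomes" rule.
default_min_within <- function(n_within) as.integer(ceiling(2 / 3 * n_within))

#' Technique-specific complex selection
#'
#' Selects complexes predicted (at least one within-complex edge) by at
#' least `min_within` interactomes of the focal technique while being
#' predicted by at most `max_other` interactomes of each other
#' technique. The default `min_within` is two-thirds of the technique's
#' interactomes (4 of 6 CF, 2 of 3 AP-MS or Y2H).
#'
#' @param records List of [enrich_complexes()] outputs, one per
#'   interactome.
#' @param techniques Character vector, one technique per record.
#' @param technique Focal technique.
#' @param min_within Minimum predicting interactomes within the focal
#'   technique (`NULL` = two-thirds rule).
#' @param max_other Maximum predicting interactomes per other technique
#'   (default 1).
#' @return Character vector of selected complex IDs.
#' @export
technique_specific_complexes <- function(records, techniques, technique,
                                         min_within = NULL, max_other = 1L) {
  flags <- predicted_flag_matrix(records)
  selected_from_flags(flags, techniques, technique, min_within, max_other)
}

selected_from_flags <- function(flags, techniques, technique,
                                min_within = NULL, max_other = 1L) {
  if (length(techniques) != ncol(flags)) stop("one technique per interactome required")
  within <- flags[, techniques == technique, drop = FALSE]
  if (ncol(within) == 0L) stop("no interactome of technique ", technique)
  if (is.null(min_within)) min_within <- default_min_within(ncol(within))
  ok <- rowSums(within) >= min_within
  for (other in setdiff(unique(techniques), technique)) {
    cnt <- rowSums(flags[, techniques == other, drop = FALSE])
    ok <- ok & cnt <= max_other
  }
  rownames(flags)[ok]
}

#' Bootstrap chance model for technique-specific selection
#'
#' Estimates how many technique-specific complexes the selection rule
#' would return by chance. Each bootstrap independently permutes, within
#' every interactome, which complexes carry a predicted flag — keeping
#' each interactome's number of predicted complexes fixed — and re-runs
#' the selection. The p-value is the add-one fraction of bootstrap
#' counts at least as large as the observed count.
#'
#' @inheritParams technique_specific_complexes
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return List with `observed`, `expected` (bootstrap mean count), `p`,
#'   and the vector of `boot_counts`.
#' @export
technique_specific_chance <- function(records, techniques, technique,
                                      min_within = NULL, max_other = 1L,
                                      n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  flags <- predicted_flag_matrix(records)
  observed <- length(selected_from_flags(flags, techniques, technique,
                                         min_within, max_other))
  set.seed(seed)
  boot_counts <- vapply(seq_len(n_boot), function(b) {
    perm <- apply(flags, 2L, sample)
    rownames(perm) <- rownames(flags)
    length(selected_from_flags(perm, techniques, technique,
                               min_within, max_other))
  }, 0L)
  list(observed = observed,
       expected = mean(boot_counts),
       p = (1 + sum(boot_counts >= observed)) / (1 + n_boot),
       boot_counts = boot_counts)
}
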