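# Quantified-protein roster of a dataset for complex statistics: proteins
# whose zero-filled profile has nonzero variance (a defined correlation).
cs_roster <- function(cor_mat) {
  rownames(cor_mat)[!is.na(diag(cor_mat))]
}

# Precompute per-dataset correlation matrices once; every complex-level
# statistic below is a mean over entries of these matrices.
cs_prepare <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  lapply(datasets, dataset_cor_matrix)
}

# Mean of within-set pairwise correlations from a correlation matrix,
# plus the comparison count. idx: integer row indices, all defined.
set_mean_r <- function(cm, idx) {
  m <- length(idx)
  if (m < 2L) return(c(sum = 0, n = 0))
  sub <- cm[idx, idx]
  c(sum = (sum(sub) - m) / 2, n = m * (m - 1) / 2)
}

#' Mean internal correlation of a complex
#'
#' Pools every within-complex pairwise zero-filled Pearson correlation
#' across all datasets in which both proteins are quantified, and
#' returns the flat (per-comparison) average together with the number of
#' pooled comparisons. A complex needs at least two quantified members
#' in at least one dataset to be observed.
#'
#' @param members Character vector of member accessions.
#' @param datasets List of filtered [cf_dataset] objects.
#' @return List with `mean_r` and `n_pairwise`, or `NULL` if the complex
#'   is unobserved (no computable pair in any dataset).
#' @export
complex_internal_correlation <- function(members, datasets) {
  cms <- cs_prepare(datasets)
  acc <- c(sum = 0, n = 0)
  for (cm in cms) {
    idx <- which(rownames(cm) %in% members & !is.na(diag(cm)))
    acc <- acc + set_mean_r(cm, idx)
  }
  if (acc[["n"]] == 0) return(NULL)
  list(mean_r = acc[["sum"]] / acc[["n"]], n_pairwise = as.integer(acc[["n"]]))
}

#' Permutation null for the pooled mean pairwise correlation
#'
#' Each permutation draws a random protein set of the given size from the
#' quantified proteins of every dataset (independently per dataset),
#' computes all within-set pairwise correlations, and pools them across
#' datasets exactly as the observed complex statistic does. Resampling
#' protein identities — rather than shuffling fractions — keeps each
#' dataset's marginal profile statistics intact, so the null describes a
#' random protein set of matched size.
#'
#' @param datasets List of filtered [cf_dataset] objects.
#' @param n_members Size of each random protein set; datasets with fewer
#'   quantified proteins are skipped (an error if all are skipped).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for reproducibility.
#' @return Numeric vector of `n_perm` null pooled means.
#' @export
permutation_null <- function(datasets, n_members, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L, n_members >= 2L)
  cms <- cs_prepare(datasets)
  rosters <- lapply(cms, function(cm) which(!is.na(diag(cm))))
  usable <- vapply(rosters, length, 0L) >= n_members
  if (!any(usable)) stop("no dataset has ", n_members, " quantified proteins")
  set.seed(seed)
  null_pooled_means(cms[usable], rosters[usable],
                    rep(n_members, sum(usable)), n_perm)
}

# Core permutation loop shared by permutation_null() and
# complex_significance(): sizes[i] proteins are drawn from rosters[[i]]
# of dataset i, and means are pooled flat over comparisons.
null_pooled_means <- function(cms, rosters, sizes, n_perm) {
  vapply(seq_len(n_perm), function(p) {
    acc_sum <- 0
    acc_n <- 0
    for (i in seq_along(cms)) {
      if (sizes[i] < 2L) next
      idx <- rosters[[i]][sample.int(length(rosters[[i]]), sizes[i])]
      sm <- set_mean_r(cms[[i]], idx)
      acc_sum <- acc_sum + sm[["sum"]]
      acc_n <- acc_n + sm[["n"]]
    }
    acc_sum / acc_n
  }, 0)
}

#' Complex-level co-fractionation significance
#'
#' For every complex observed in the data (at least two quantified
#' members in at least one dataset), computes the pooled mean internal
#' correlation and tests it against a permutation null of random protein
#' sets of matched per-dataset size. Two one-sided permutation p-values
#' (add-one rule) are corrected with Benjamini-Hochberg separately for
#' the high and low families, and each complex is classed `enriched`
#' (more internally correlated than chance), `depleted`, or `neither`.
#'
#' @param datasets List of filtered [cf_dataset] objects.
#' @param db A [complex_db].
#' @param alpha FDR level used for classing (default 0.05).
#' @param n_perm Permutations per complex (default 1000).
#' @param seed Integer seed.
#' @return Data frame with one row per observed complex: `complex_id`,
#'   `n_observed_members`, `n_pairwise`, `mean_r`, `null_mean`,
#'   `null_q025`, `null_q975`, `p_high`, `p_low`, `q_high`, `q_low`,
#'   `class`.
#' @export
complex_significance <- function(datasets, db, alpha = 0.05,
                                 n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(db, "complex_db"), n_perm >= 1L)
  cms <- cs_prepare(datasets)
  rosters <- lapply(cms, function(cm) which(!is.na(diag(cm))))
  set.seed(seed)
  rows <- lapply(names(db$complexes), function(cid) {
    members <- db$complexes[[cid]]
    idxs <- lapply(cms, function(cm) {
      which(rownames(cm) %in% members & !is.na(diag(cm)))
    })
    sizes <- vapply(idxs, length, 0L)
    if (!any(sizes >= 2L)) return(NULL)
    acc <- c(sum = 0, n = 0)
    for (i in seq_along(cms)) acc <- acc + set_mean_r(cms[[i]], idxs[[i]])
    obs <- acc[["sum"]] / acc[["n"]]
    null <- null_pooled_means(cms, rosters, sizes, n_perm)
    obs_members <- Reduce(union, lapply(seq_along(cms), function(i) {
      rownames(cms[[i]])[idxs[[i]]]
    }))
    data.frame(complex_id = cid,
               n_observed_members = length(obs_members),
               n_pairwise = as.integer(acc[["n"]]),
               mean_r = obs,
               null_mean = mean(null),
               null_q025 = stats::quantile(null, 0.025, names = FALSE),
               null_q975 = stats::quantile(null, 0.975, names = FALSE),
               p_high = (1 + sum(null >= obs)) / (1 + n_perm),
               p_low = (1 + sum(null <= obs)) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no complex observed in the supplied datasets")
  out$q_high <- stats::p.adjust(out$p_high, method = "BH")
  out$q_low <- stats::p.adjust(out$p_low, method = "BH")
  out$class <- ifelse(out$q_high < alpha, "enriched",
                      ifelse(out$q_low < alpha, "depleted", "neither"))
  rownames(out) <- NULL
  out
}

#' Housekeeping complexes across tissues
#'
#' A complex is called housekeeping when its internal correlation is
#' significantly higher than chance (one-sided permutation p below
#' `alpha`, uncorrected) in every tissue supplied. Complexes must be
#' observed in every tissue to qualify.
#'
#' @param tissue_datasets Named list: tissue -> list of filtered
#'   [cf_dataset] objects (or a single `cf_dataset`).
#' @param db A [complex_db].
#' @param alpha Per-tissue significance level (default 0.05).
#' @param n_perm Permutations per complex and tissue.
#' @param seed Integer seed.
#' @return Character vector of housekeeping complex IDs.
#' @export
housekeeping_complexes <- function(tissue_datasets, db, alpha = 0.05,
                                   n_perm = 1000L, seed = 1L) {
  if (length(tissue_datasets) < 2L) stop("need >= 2 tissues")
  per_tissue <- lapply(seq_along(tissue_datasets), function(i) {
    ds <- tissue_datasets[[i]]
    if (inherits(ds, "cf_dataset")) ds <- list(ds)
    complex_significance(ds, db, alpha = alpha, n_perm = n_perm,
                         seed = seed + i)
  })
  sig_all <- Reduce(intersect, lapply(per_tissue, function(st) {
    st$complex_id[st$p_high < alpha]
  }))
  sort(sig_all)
}

#' Connection matrix of a complex
#'
#' Symmetric matrix of mean pairwise correlations between complex
#' members, averaged over the datasets in which both proteins are
#' quantified; `NA` marks pairs never jointly detected. Rows and columns
#' are ordered by decreasing average pairwise correlation, so the most
#' connected members come first.
#'
#' @param members Character vector of member accessions.
#' @param datasets List of filtered [cf_dataset] objects.
#' @return Square numeric matrix (unit diagonal) over the observed
#'   members.
#' @export
connection_matrix <- function(members, datasets) {
  cms <- cs_prepare(datasets)
  obs <- sort(unique(unlist(lapply(cms, function(cm) {
    intersect(members, cs_roster(cm))
  }))))
  if (length(obs) < 2L) stop("need >= 2 observed members")
  sum_m <- matrix(0, length(obs), length(obs), dimnames = list(obs, obs))
  cnt_m <- sum_m
  for (cm in cms) {
    idx <- intersect(obs, cs_roster(cm))
    if (length(idx) < 2L) next
    sub <- cm[idx, idx]
    sum_m[idx, idx] <- sum_m[idx, idx] + sub
    cnt_m[idx, idx] <- cnt_m[idx, idx] + 1
  }
  avg <- sum_m / cnt_m
  avg[cnt_m == 0] <- NA_real_
  diag(avg) <- 1
  ord <- order(rowMeans(avg, na.rm = TRUE), decreasing = TRUE)
  avg[ord, ord]
}
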