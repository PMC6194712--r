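# Shared fixture builders. Everything is generated in code at test time.

# Random chromatogram matrix with controllable missingness.
random_profile_matrix <- function(n_prot, n_frac, missing_rate = 0,
                                  ids = sprintf("P%05d", seq_len(n_prot))) {
  mat <- matrix(stats::rexp(n_prot * n_frac), n_prot, n_frac,
                dimnames = list(ids, NULL))
  if (missing_rate > 0) {
    mat[stats::runif(length(mat)) < missing_rate] <- NA_real_
  }
  mat
}

random_cf_dataset <- function(n_prot, n_frac, missing_rate = 0,
                              dataset_id = "fix") {
  cf_dataset(random_profile_matrix(n_prot, n_frac, missing_rate), dataset_id)
}

# Tiny three-complex database used across modules.
toy_db <- function() {
  complex_db(list(C1 = c("A", "B", "C"),
                  C2 = c("C", "D"),
                  C3 = c("E", "F", "G", "H")),
             source_label = "toy")
}

# Independent naive Pearson oracle: two-pass, drops nothing, zero-fills.
oracle_pearson <- function(x, y) {
  x[is.na(x)] <- 0
  y[is.na(y)] <- 0
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Independent Euclidean oracle: explicit normalize-then-distance.
oracle_euclidean <- function(x, y) {
  f <- function(v) {
    v[is.na(v)] <- 0
    (v - min(v)) / (max(v) - min(v))
  }
  sqrt(sum((f(x) - f(y))^2))
}

# Sorted-data closed form for the Gini coefficient.
oracle_gini <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

# Exhaustive-enumeration hypergeometric upper tail (small N only).
oracle_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Benjamini-Hochberg step-up oracle returning the rejection set.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= alpha * seq_len(m) / m)
  rejected <- logical(m)
  if (length(passed) > 0L) rejected[ord[seq_len(max(passed))]] <- TRUE
  rejected
}
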