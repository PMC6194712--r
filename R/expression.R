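#' Gini coefficient of an expression vector
#'
#' Inequality of expression across tissues:
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))` over the non-missing
#' values. 0 means perfectly even expression; values approach 1 as
#' expression concentrates in a single tissue. Undefined (`NA`) with
#' fewer than two non-missing values or an all-zero vector.
#'
#' @param x Nonnegative numeric vector; `NA` allowed (dropped).
#' @return Gini coefficient in \[0, 1), or `NA` when undefined.
#' @examples
#' gini(c(5, 5, 5, 5))      # 0
#' gini(c(0, 0, 0, 1))      # (n-1)/n = 0.75
#' @export
gini <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L || sum(x) == 0) return(NA_real_)
  if (any(x < 0)) stop("gini requires nonnegative values")
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Per-protein Gini coefficients of an expression matrix
#'
#' @param mat Numeric matrix, proteins x tissues.
#' @return Data frame `protein_id`, `gini`, `n_tissues_used`; proteins
#'   with undefined Gini are dropped.
#' @export
expression_gini <- function(mat) {
  if (ncol(mat) < 2L) stop("need >= 2 tissue columns")
  g <- apply(mat, 1L, gini)
  n_used <- rowSums(!is.na(mat))
  out <- data.frame(protein_id = rownames(mat), gini = g,
                    n_tissues_used = n_used, stringsAsFactors = FALSE)
  out <- out[!is.na(out$gini), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare expression consistency between protein groups
#'
#' Computes per-protein Gini coefficients across tissues and compares
#' the co-fractionation-specific group against other complex members
#' with a Welch (unequal-variance) two-sample t-test. Proteins belonging
#' to both groups are assigned to the co-fractionation-specific group.
#'
#' @param mat Expression matrix, proteins x tissues.
#' @param cf_proteins Accessions in co-fractionation-specific complexes.
#' @param other_proteins Accessions in other complexes.
#' @return List with `mean_gini` (named: cf_specific, other_complex),
#'   `t`, `p`, `df` and the per-protein data frame `records`.
#' @export
group_gini_comparison <- function(mat, cf_proteins, other_proteins) {
  other_proteins <- setdiff(other_proteins, cf_proteins)
  gg <- expression_gini(mat)
  gg$group <- ifelse(gg$protein_id %in% cf_proteins, "cf_specific",
                     ifelse(gg$protein_id %in% other_proteins,
                            "other_complex", NA_character_))
  gg <- gg[!is.na(gg$group), , drop = FALSE]
  g_cf <- gg$gini[gg$group == "cf_specific"]
  g_ot <- gg$gini[gg$group == "other_complex"]
  if (length(g_cf) < 2L || length(g_ot) < 2L) {
    stop("both groups need >= 2 proteins with a defined Gini coefficient")
  }
  tt <- stats::t.test(g_cf, g_ot, var.equal = FALSE)
  list(mean_gini = c(cf_specific = mean(g_cf), other_complex = mean(g_ot)),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), records = gg)
}

#' Hypergeometric overlap of two sets
#'
#' Upper-tail probability of observing at least the seen intersection
#' when `|B|` items are drawn from a universe of `universe_size`
#' containing `|A|` marked items.
#'
#' @param set_a,set_b Character vectors (deduplicated internally).
#' @param universe_size Population size; must be at least `|A|` and
#'   `|B|`.
#' @return List with `n_overlap` and `p`.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("sets cannot exceed the universe")
  }
  k <- length(intersect(set_a, set_b))
  list(n_overlap = k,
       p = hypergeometric_upper_tail(k, length(set_a), length(set_b),
                                     universe_size))
}
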