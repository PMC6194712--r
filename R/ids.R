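#' Normalize a protein identifier
#'
#' Strips a single trailing isoform tag of the form `-<digits>` from
#' UniProt-style accessions (e.g. `"P07900-2"` becomes `"P07900"`).
#' Identifiers that do not look like a UniProt accession plus isoform
#' suffix are passed through unchanged; case is preserved. The operation
#' is idempotent.
#'
#' @param raw Character vector of raw protein identifiers. Must be
#'   non-empty strings.
#' @return Character vector of normalized accessions, same length as `raw`.
#' @examples
#' normalize_protein_id(c("P07900-2", "P11021", "GENE1"))
#' @export
normalize_protein_id <- function(raw) {
  if (!is.character(raw)) stop("protein IDs must be character")
  if (length(raw) == 0L) return(character(0))
  if (anyNA(raw) || any(!nzchar(raw))) {
    stop("empty or missing protein ID")
  }
  # UniProt accession: 6- or 10-character form, optionally "-<digits>" isoform
  uniprot <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})-[0-9]+$"
  has_isoform <- grepl(uniprot, raw)
  raw[has_isoform] <- sub("-[0-9]+$", "", raw[has_isoform])
  raw
}

#' Canonical unordered protein pairs
#'
#' Returns a two-column data frame in which each pair is stored exactly
#' once, with `a < b` lexicographically, duplicates removed, and
#' self-pairs dropped.
#'
#' @param a,b Character vectors of equal length giving pair endpoints.
#' @return A data frame with character columns `a` and `b`.
#' @examples
#' protein_pairs(c("B", "A"), c("A", "B"))  # one canonical pair
#' @export
protein_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  a <- as.character(a)
  b <- as.character(b)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  df <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Canonical string key for a pair; used internally for set operations.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

pair_df_keys <- function(pairs) {
  pair_key(pairs$a, pairs$b)
}

# Inverse of pair_key(); returns a canonical pair data frame.
keys_to_pairs <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1L),
             b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' All within-complex pairs of a complex database
#'
#' Expands every complex into its unordered member pairs and returns the
#' union, deduplicated across complexes: a pair co-occurring in several
#' complexes is reported once.
#'
#' @param db A [complex_db] object.
#' @return A canonical pair data frame (columns `a`, `b`).
#' @examples
#' db <- complex_db(list(C1 = c("A", "B", "C"), C2 = c("A", "B")))
#' complex_to_pairs(db)  # 3 unique pairs
#' @export
complex_to_pairs <- function(db) {
  stopifnot(inherits(db, "complex_db"))
  pieces <- lapply(db$complexes, function(members) {
    m <- sort(members)
    n <- length(m)
    if (n < 2L) return(NULL)
    idx <- utils::combn(n, 2L)
    data.frame(a = m[idx[1L, ]], b = m[idx[2L, ]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
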