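#' Co-fractionation dataset
#'
#' A co-fractionation dataset holds one chromatogram per protein: SILAC
#' ratios quantified over successive fractions of a separation gradient.
#' Internally it is a numeric matrix with proteins as rows (unique,
#' normalized accessions) and fractions as columns (1-based, in
#' separation order); `NA` marks fractions where a protein was not
#' quantified.
#'
#' @param mat Numeric matrix, proteins x fractions; rownames are protein
#'   accessions; values nonnegative or `NA`.
#' @param dataset_id Character scalar identifying the dataset
#'   (condition x replicate).
#' @return An object of class `cf_dataset`.
#' @export
cf_dataset <- function(mat, dataset_id) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  if (is.null(rownames(mat))) stop("mat must have protein rownames")
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1L]
    stop("duplicate protein ID in dataset: ", dup)
  }
  if (any(mat < 0, na.rm = TRUE)) stop("negative ratio values not allowed")
  colnames(mat) <- paste0("frac", seq_len(ncol(mat)))
  structure(list(dataset_id = as.character(dataset_id), mat = mat),
            class = "cf_dataset")
}

#' @export
print.cf_dataset <- function(x, ...) {
  cat("cf_dataset '", x$dataset_id, "': ", nrow(x$mat), " proteins x ",
      ncol(x$mat), " fractions (",
      round(100 * mean(is.na(x$mat)), 1), "% missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.cf_dataset <- function(x) dim(x$mat)

#' Number of quantified fractions per protein
#'
#' @param dataset A [cf_dataset].
#' @return Named integer vector: non-missing fraction count per protein.
#' @export
quantified_count <- function(dataset) {
  stopifnot(inherits(dataset, "cf_dataset"))
  rowSums(!is.na(dataset$mat))
}

na_tokens <- c("", "NA", "NaN")

#' Read a chromatogram table
#'
#' Reads a delimited table whose first column holds protein IDs and whose
#' remaining columns are fractions in separation order. Empty cells,
#' `"NA"` and `"NaN"` are treated as missing. Protein IDs are normalized
#' (isoform tags stripped); protein-group rows (semicolon-separated
#' accessions) are resolved to their first accession. Duplicate protein
#' rows after normalization are an error.
#'
#' @param path Path to a CSV (`.csv`) or TSV file.
#' @param dataset_id Dataset identifier; defaults to the file name.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A [cf_dataset].
#' @export
read_chromatograms <- function(path, dataset_id = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (ncol(raw) < 2L) stop("chromatogram file needs a protein column plus fractions: ", path)
  ids <- raw[[1L]]
  if (any(!nzchar(ids))) stop("empty protein ID at row ", which(!nzchar(ids))[1L])
  ids <- vapply(strsplit(ids, ";", fixed = TRUE), `[`, "", 1L)
  ids <- normalize_protein_id(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate protein ID '", ids[duplicated(ids)][1L],
         "' at row ", which(duplicated(ids))[1L], " of ", path)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% na_tokens] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("unparseable value '", vals[bad[1L, 1L], bad[1L, 2L]], "' at row ",
         bad[1L, 1L], ", column ", bad[1L, 2L] + 1L, " of ", path)
  }
  rownames(num) <- ids
  cf_dataset(num, dataset_id)
}

#' Write a chromatogram table
#'
#' Missing values are written as empty cells. Column layout matches
#' [read_chromatograms()]: `protein,frac1..fracN`.
#'
#' @param dataset A [cf_dataset].
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @export
write_chromatograms <- function(dataset, path) {
  stopifnot(inherits(dataset, "cf_dataset"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(protein = rownames(dataset$mat), dataset$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Keep proteins quantified in at least k fractions
#'
#' Chromatograms quantified in too few fractions carry little
#' co-elution signal; the conventional cutoff is five fractions.
#'
#' @param dataset A [cf_dataset].
#' @param k Minimum number of non-missing fractions (default 5).
#' @return A [cf_dataset] restricted to passing proteins.
#' @export
filter_min_fractions <- function(dataset, k = 5L) {
  stopifnot(inherits(dataset, "cf_dataset"), k >= 1L)
  keep <- quantified_count(dataset) >= k
  cf_dataset(dataset$mat[keep, , drop = FALSE], dataset$dataset_id)
}

#' Complex database
#'
#' A named collection of protein complexes (CORUM-core style): complex ID
#' mapped to a member set of normalized accessions. Member lists are
#' deduplicated and complexes with fewer than two distinct members after
#' ID normalization are dropped.
#'
#' @param complexes Named list; each element a character vector of member
#'   accessions.
#' @param complex_names Optional named character vector of display names.
#' @param source_label Label for the database source.
#' @return An object of class `complex_db`.
#' @export
complex_db <- function(complexes, complex_names = NULL, source_label = "unnamed") {
  if (is.null(names(complexes)) || any(!nzchar(names(complexes)))) {
    stop("complexes must be a named list")
  }
  complexes <- lapply(complexes, function(m) unique(normalize_protein_id(as.character(m))))
  sizes <- lengths(complexes)
  if (any(sizes < 2L)) {
    complexes <- complexes[sizes >= 2L]
  }
  if (is.null(complex_names)) {
    complex_names <- stats::setNames(names(complexes), names(complexes))
  }
  structure(list(complexes = complexes,
                 names = complex_names[names(complexes)],
                 source_label = source_label),
            class = "complex_db")
}

#' @export
print.complex_db <- function(x, ...) {
  cat("complex_db '", x$source_label, "': ", length(x$complexes),
      " complexes, ", length(unique(unlist(x$complexes))),
      " distinct proteins\n", sep = "")
  invisible(x)
}

#' @export
length.complex_db <- function(x) length(x$complexes)

#' Read / write a complex database table
#'
#' TSV layout: `complex_id<TAB>complex_name<TAB>members`, members being
#' semicolon-separated accessions.
#'
#' @param path File path.
#' @param source_label Source label recorded on the returned object.
#' @return `read_complex_db()` returns a [complex_db].
#' @export
read_complex_db <- function(path, source_label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  if (ncol(df) < 3L) stop("complex DB needs columns complex_id, complex_name, members")
  members <- strsplit(df[[3L]], ";", fixed = TRUE)
  names(members) <- df[[1L]]
  complex_db(members,
             complex_names = stats::setNames(df[[2L]], df[[1L]]),
             source_label = source_label)
}

#' @rdname read_complex_db
#' @param db A [complex_db] to write.
#' @export
write_complex_db <- function(db, path) {
  stopifnot(inherits(db, "complex_db"))
  df <- data.frame(complex_id = names(db$complexes),
                   complex_name = unname(db$names),
                   members = vapply(db$complexes, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published interactome
#'
#' An interactome is a set of unordered protein-pair edges with a
#' technique tag (`CF`, `AP-MS` or `Y2H`), plus optional bait and
#' quantified-protein rosters used by the could-be-predicted controls.
#'
#' @param edges Pair data frame (columns `a`, `b`) or two character
#'   vectors via `a`/`b`; canonicalized and deduplicated.
#' @param label Interactome label (e.g. "CF4").
#' @param technique One of `"CF"`, `"AP-MS"`, `"Y2H"`.
#' @param baits Optional character vector of bait accessions.
#' @param quantified Optional character vector of proteins present in the
#'   underlying raw data.
#' @return An object of class `interactome`.
#' @export
interactome <- function(edges, label, technique = c("CF", "AP-MS", "Y2H"),
                        baits = NULL, quantified = NULL) {
  technique <- match.arg(technique)
  edges <- protein_pairs(normalize_protein_id(edges$a),
                         normalize_protein_id(edges$b))
  if (!is.null(baits)) baits <- unique(normalize_protein_id(baits))
  if (!is.null(quantified)) quantified <- unique(normalize_protein_id(quantified))
  structure(list(label = as.character(label), technique = technique,
                 edges = edges, baits = baits, quantified = quantified),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome '", x$label, "' (", x$technique, "): ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Read an interactome edge list
#'
#' TSV with header `protein_a<TAB>protein_b[<TAB>n_publications]`.
#'
#' @inheritParams interactome
#' @param path Edge-list path.
#' @param min_pubs When the file carries an `n_publications` column,
#'   edges below this support are dropped before canonicalization
#'   (`NULL` keeps everything).
#' @return An [interactome].
#' @export
read_interactome <- function(path, label, technique, baits = NULL,
                             quantified = NULL, min_pubs = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("interactome file needs protein_a and protein_b columns")
  edges <- data.frame(a = df[[1L]], b = df[[2L]], stringsAsFactors = FALSE)
  if (!is.null(min_pubs)) {
    if (ncol(df) < 3L) stop("min_pubs given but no publication-count column in ", path)
    edges$n_publications <- as.integer(df[[3L]])
    edges <- filter_by_publication_count(edges, min_pubs)
  }
  interactome(edges, label = label, technique = technique,
              baits = baits, quantified = quantified)
}

#' Filter edges by publication support
#'
#' @param edges Data frame with columns `a`, `b` and `n_publications`.
#' @param min_pubs Minimum publication count (default 2, the usual
#'   "supported by at least two publications" rule).
#' @return The filtered edge data frame.
#' @export
filter_by_publication_count <- function(edges, min_pubs = 2L) {
  if (is.null(edges$n_publications) || anyNA(edges$n_publications)) {
    stop("every edge needs an n_publications annotation")
  }
  if (any(edges$n_publications < 1L)) stop("publication counts must be >= 1")
  out <- edges[edges$n_publications >= min_pubs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an expression matrix
#'
#' TSV layout `protein<TAB>tissue1..tissueT`; values are nonnegative
#' expression levels, empty cells missing. At least two tissue columns
#' are required (the Gini coefficient is undefined otherwise).
#'
#' @param path File path.
#' @return `read_expression()` returns a numeric matrix, proteins x
#'   tissues, with normalized rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  if (ncol(df) < 3L) stop("expression matrix needs >= 2 tissue columns")
  if (anyDuplicated(colnames(df)[-1L])) stop("tissue labels must be unique")
  ids <- normalize_protein_id(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals %in% na_tokens] <- NA_character_
  mat <- matrix(as.numeric(vals), nrow = nrow(vals),
                dimnames = list(ids, colnames(df)[-1L]))
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression values not allowed")
  mat
}

#' @rdname read_expression
#' @param mat Numeric matrix, proteins x tissues.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
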