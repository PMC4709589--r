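# Conservation scoring and grading from an aligned FASTA MSA.
#
# The per-column score is (1 - normalized Shannon entropy over non-gap
# residues) * (non-gap fraction): 1 for an invariant gap-free column, 0 for a
# 20-way uniform column, and proportionally penalized by gaps. Scores are then
# binned into 1-9 grades (9 = most conserved) by equal-frequency binning and
# collapsed to the Variable(1-3) / Average(4-6) / Conserved(7-9) bands.

GAP_CHARS <- c("-", ".")

#' Read an aligned FASTA alignment
#'
#' @param path Path to an aligned (equal-length) FASTA file of protein
#'   sequences; gaps are \code{-} or \code{.}.
#' @param reference Identifier (or 1-based index) of the reference row whose
#'   ungapped numbering positions are reported in. Defaults to the first row.
#' @return An \code{msa_alignment}: list with \code{ids}, a character matrix
#'   \code{seqs} (rows = sequences, columns = alignment columns) and
#'   \code{reference} (row index).
#' @export
read_msa <- function(path, reference = 1L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("alignment file contains no sequences", call. = FALSE)
  msa_alignment(stats::setNames(as.character(set), names(set)), reference)
}

#' Construct an alignment from named character strings
#'
#' @param sequences Named character vector of equal-length aligned rows.
#' @param reference Reference row id or index.
#' @return An \code{msa_alignment}.
#' @export
msa_alignment <- function(sequences, reference = 1L) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("alignment rows must all have equal length", call. = FALSE)
  if (is.character(reference)) {
    reference <- match(reference, names(sequences))
    if (is.na(reference)) stop("reference row not found in alignment", call. = FALSE)
  }
  if (reference < 1L || reference > length(sequences))
    stop("reference row index out of range", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(unname(sequences)), ""))
  rownames(mat) <- names(sequences)
  structure(list(ids = names(sequences), seqs = mat, reference = as.integer(reference)),
            class = "msa_alignment")
}

#' Score one alignment column
#'
#' Normalized-entropy conservation: with residue frequencies \eqn{p_a} over
#' the non-gap letters of the column, the score is
#' \deqn{(1 - H(p)/\log 20) \times f_{nongap}}
#' so identical gap-free columns score 1, a uniform spread over all 20
#' residues scores 0, and gaps shrink the score by the gapped fraction.
#' An all-gap column scores 0 and is flagged undefined.
#'
#' @param column Character vector of one-letter residues and gap characters.
#' @param weights Optional per-sequence weights (non-negative, recycled to
#'   the column length); default unweighted.
#' @return Numeric score in [0,1] with attribute \code{undefined = TRUE} when
#'   the column is all gaps.
#' @export
column_score <- function(column, weights = NULL) {
  stopifnot(length(column) > 0L)
  column <- toupper(column)
  if (is.null(weights)) weights <- rep(1, length(column))
  stopifnot(length(weights) == length(column), all(weights >= 0))
  gap <- column %in% GAP_CHARS
  w_total <- sum(weights)
  w_res <- sum(weights[!gap])
  if (w_res == 0 || w_total == 0)
    return(structure(0, undefined = TRUE))
  freq <- tapply(weights[!gap], column[!gap], sum) / w_res
  h <- -sum(freq * log(freq))
  score <- (1 - h / log(20)) * (w_res / w_total)
  max(0, min(1, score))
}

#' Map alignment columns to reference residue numbers
#'
#' @param aln An \code{msa_alignment}.
#' @return Named integer vector: names are alignment column indices at which
#'   the reference row has a residue, values the corresponding 1-based
#'   reference residue numbers (strictly increasing).
#' @export
map_to_reference <- function(aln) {
  stopifnot(inherits(aln, "msa_alignment"))
  ref <- aln$seqs[aln$reference, ]
  cols <- which(!ref %in% GAP_CHARS)
  stats::setNames(seq_along(cols), cols)
}

#' Grade conservation scores on the 1-9 scale
#'
#' Equal-frequency (rank-quantile) binning of scores into nine grades with
#' grade 9 the most conserved; tied scores share the lower grade. Grades
#' collapse to bands: 1-3 Variable, 4-6 Average, 7-9 Conserved. A degenerate
#' profile whose scores are all identical is assigned grade 5 throughout.
#'
#' @param scores Named (by position) or unnamed numeric vector of
#'   per-position conservation scores in [0,1].
#' @return A \code{conservation_profile}: data.frame with columns
#'   \code{position}, \code{score}, \code{grade}, \code{band}.
#' @export
grade_profile <- function(scores) {
  stopifnot(length(scores) >= 1L, all(scores >= 0 & scores <= 1))
  n <- length(scores)
  pos <- if (!is.null(names(scores))) as.integer(names(scores)) else seq_len(n)
  if (length(unique(scores)) == 1L) {
    grades <- rep(5L, n)
  } else {
    r <- rank(scores, ties.method = "min")
    grades <- as.integer(ceiling(r * 9 / n))
  }
  structure(
    data.frame(position = pos, score = as.numeric(scores), grade = grades,
               band = grade_band(grades), stringsAsFactors = FALSE),
    class = c("conservation_profile", "data.frame")
  )
}

#' Band of a 1-9 conservation grade
#'
#' @param grade Integer vector of grades in 1-9.
#' @return \code{"Variable"} for 1-3, \code{"Average"} for 4-6,
#'   \code{"Conserved"} for 7-9.
#' @export
grade_band <- function(grade) {
  stopifnot(all(grade >= 1L & grade <= 9L))
  c("Variable", "Average", "Conserved")[(as.integer(grade) - 1L) %/% 3L + 1L]
}

#' Conservation profile of an alignment in reference numbering
#'
#' Scores every column with [column_score()] (pluggable), drops columns where
#' the reference row is gapped, and grades the remainder with
#' [grade_profile()].
#'
#' @param aln An \code{msa_alignment}.
#' @param score_fun Column-scoring function with the [column_score()]
#'   signature.
#' @param weights Optional per-sequence weights passed through.
#' @return A \code{conservation_profile} in reference residue numbering.
#' @export
conservation_profile <- function(aln, score_fun = column_score, weights = NULL) {
  stopifnot(inherits(aln, "msa_alignment"))
  mapping <- map_to_reference(aln)
  cols <- as.integer(names(mapping))
  scores <- vapply(cols, function(j) as.numeric(score_fun(aln$seqs[, j], weights)),
                   numeric(1))
  grade_profile(stats::setNames(scores, mapping))
}
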