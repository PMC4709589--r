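#' Parse a protein variant token
#'
#' Parses substitution tokens in the conventional one-letter protein notation
#' used throughout the PHD2 literature, e.g. \code{"D254H"} (missense) or
#' \code{"R398X"} (nonsense; \code{X} or \code{*} denote the stop codon).
#'
#' @param text Single non-empty variant token, e.g. \code{"V138A"}.
#' @return An object of class \code{phd2_variant}: a list with fields
#'   \code{ref_aa}, \code{position}, \code{alt_aa} (\code{"X"} for stop) and
#'   \code{kind} (\code{"missense"} or \code{"nonsense"}).
#' @examples
#' parse_variant("D254H")
#' parse_variant("R398X")
#' @seealso [format.phd2_variant()], [annotate_region()]
#' @export
parse_variant <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("variant token must be a single non-empty string", call. = FALSE)
  tok <- toupper(trimws(text))
  m <- regexec("^([A-Z])([0-9]+)([A-Z*])$", tok)
  parts <- regmatches(tok, m)[[1]]
  if (length(parts) != 4L)
    stop(sprintf("malformed variant token '%s': expected <ref><position><alt>, e.g. D254H", text),
         call. = FALSE)
  ref <- parts[2]; pos <- as.integer(parts[3]); alt <- parts[4]
  if (alt == "*") alt <- "X"
  if (!ref %in% AA1)
    stop(sprintf("malformed variant token '%s': unknown reference residue '%s'", text, ref),
         call. = FALSE)
  if (!(alt %in% AA1 || alt == "X"))
    stop(sprintf("malformed variant token '%s': unknown alternate residue '%s'", text, alt),
         call. = FALSE)
  if (pos < 1L)
    stop(sprintf("malformed variant token '%s': position must be >= 1", text), call. = FALSE)
  if (ref == alt)
    stop(sprintf("variant '%s' is synonymous: reference and alternate residues are identical", text),
         call. = FALSE)
  structure(
    list(ref_aa = ref, position = pos, alt_aa = alt,
         kind = if (alt == "X") "nonsense" else "missense"),
    class = "phd2_variant"
  )
}

#' @export
format.phd2_variant <- function(x, ...) {
  paste0(x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.phd2_variant <- function(x, ...) {
  cat(sprintf("<variant> %s (%s)\n", format(x), x$kind))
  invisible(x)
}

#' Truncation length of a nonsense variant
#'
#' Number of residues removed by a stop-codon substitution, computed
#' arithmetically as \code{protein_length - position + 1} (the stop replaces
#' the residue at \code{position}).
#'
#' @param v A \code{phd2_variant} of kind \code{"nonsense"}.
#' @param protein_length Full-length protein size (426 for PHD2).
#' @return Integer count of residues lost.
#' @export
truncation_length <- function(v, protein_length = 426L) {
  stopifnot(inherits(v, "phd2_variant"))
  if (v$kind != "nonsense")
    stop("truncation_length() applies to nonsense variants only", call. = FALSE)
  as.integer(protein_length - v$position + 1L)
}

#' Default PHD2 region map
#'
#' Closed, 1-based residue intervals for the PHD2 domain organization: a long
#' intrinsically disordered N-terminal region (1-187), the catalytic oxygenase
#' domain (188-418) and the short C-terminal tail carrying a putative
#' PDZ-binding motif (419-426). The MYND-type finger inside the N-terminal
#' region can be added by the caller; its bounds are not part of the default.
#'
#' @param extra Optional named list of additional \code{c(start, end)}
#'   intervals, appended after the defaults (may overlap them; lookups match
#'   default regions first).
#' @return A \code{data.frame} with columns \code{region}, \code{start},
#'   \code{end}, of class \code{phd2_region_map}.
#' @export
phd2_region_map <- function(extra = NULL) {
  map <- data.frame(
    region = c("n_terminal_disordered", "oxygenase_domain", "c_terminal_tail"),
    start = c(1L, 188L, 419L),
    end = c(187L, 418L, 426L),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(!is.null(names(extra)), all(nzchar(names(extra))))
    ex <- data.frame(
      region = names(extra),
      start = vapply(extra, function(x) as.integer(x[1]), integer(1)),
      end = vapply(extra, function(x) as.integer(x[2]), integer(1)),
      stringsAsFactors = FALSE
    )
    map <- rbind(map, ex)
  }
  validate_region_map(map)
}

validate_region_map <- function(map) {
  stopifnot(all(c("region", "start", "end") %in% names(map)))
  if (any(map$start > map$end))
    stop("region map invalid: interval start exceeds end", call. = FALSE)
  class(map) <- c("phd2_region_map", "data.frame")
  map
}

#' Read a region map from a two-column TSV
#'
#' Expected columns: a region label and an interval written \code{start-end}
#' (closed, 1-based). Lines starting with \code{#} are skipped.
#'
#' @param path Path to the TSV file.
#' @return A \code{phd2_region_map}.
#' @export
read_region_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("region map file needs two columns: label, start-end", call. = FALSE)
  span <- strsplit(trimws(tab[[2]]), "-", fixed = TRUE)
  bad <- vapply(span, length, integer(1)) != 2L
  if (any(bad))
    stop(sprintf("region map: cannot parse interval '%s'", tab[[2]][which(bad)[1]]), call. = FALSE)
  validate_region_map(data.frame(
    region = trimws(tab[[1]]),
    start = as.integer(vapply(span, `[`, "", 1L)),
    end = as.integer(vapply(span, `[`, "", 2L)),
    stringsAsFactors = FALSE
  ))
}

#' Annotate a variant with its protein region
#'
#' @param v A \code{phd2_variant} (or bare integer position).
#' @param map A \code{phd2_region_map}; defaults to the PHD2 map.
#' @param fallthrough Optional label returned when the position lies outside
#'   every interval; without it an out-of-map position is an error.
#' @return The label of the first interval containing the position.
#' @examples
#' annotate_region(parse_variant("D254H"))  # "oxygenase_domain"
#' @export
annotate_region <- function(v, map = phd2_region_map(), fallthrough = NULL) {
  pos <- if (inherits(v, "phd2_variant")) v$position else as.integer(v)
  hit <- which(map$start <= pos & pos <= map$end)
  if (length(hit) == 0L) {
    if (!is.null(fallthrough)) return(fallthrough)
    stop(sprintf("position %d lies outside every region of the map", pos), call. = FALSE)
  }
  map$region[hit[1]]
}

#' Define a linear-motif pattern
#'
#' @param name Non-empty label for the motif class.
#' @param pattern Regular expression over one-letter residue codes. May end in
#'   \code{$} (or start with \code{^}) itself, or set \code{anchored}.
#' @param anchored One of \code{"none"}, \code{"C"} (must match at the C
#'   terminus) or \code{"N"} (at the N terminus).
#' @return A \code{motif_pattern} object.
#' @export
motif_pattern <- function(name, pattern, anchored = c("none", "C", "N")) {
  anchored <- match.arg(anchored)
  if (!nzchar(name)) stop("motif name must be non-empty", call. = FALSE)
  ok <- tryCatch({ grepl(pattern, "ACDEFG"); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("motif '%s': pattern does not compile: %s", name, pattern), call. = FALSE)
  structure(list(name = name, pattern = pattern, anchored = anchored),
            class = "motif_pattern")
}

#' Illustrative default motif set
#'
#' Two example patterns: a class-I C-terminal PDZ-binding motif (the PHD2 tail
#' 419-426 carries a putative instance, lost in the R398X truncation) and a
#' crude basic NLS-like stretch. These are illustrations of the scanner; real
#' scans should use curated patterns.
#'
#' @return List of \code{motif_pattern} objects.
#' @export
default_motifs <- function() {
  list(
    motif_pattern("pdz_binding_class1", "[ST].[VIL]$", anchored = "C"),
    motif_pattern("nls_basic", "[KR][KR][KR][KR]")
  )
}

#' Scan a protein sequence for linear motifs
#'
#' Reports every (possibly overlapping) match of each pattern as a 1-based
#' closed span. Patterns anchored at a terminus are only reported there.
#'
#' @param sequence Protein sequence (one-letter codes, single string).
#' @param patterns List of \code{motif_pattern} objects.
#' @return \code{data.frame} with columns \code{name}, \code{start}, \code{end}.
#' @export
scan_motifs <- function(sequence, patterns) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!grepl("^[A-Z]*$", sequence))
    stop("sequence must use one-letter residue codes", call. = FALSE)
  out <- list()
  for (p in patterns) {
    if (!inherits(p, "motif_pattern")) stop("patterns must be motif_pattern objects", call. = FALSE)
    pat <- p$pattern
    if (p$anchored == "C" && !endsWith(pat, "$")) pat <- paste0(pat, "$")
    if (p$anchored == "N" && !startsWith(pat, "^")) pat <- paste0("^", pat)
    # overlapping matches: attempt from every start offset
    n <- nchar(sequence)
    for (i in seq_len(n)) {
      m <- regexpr(pat, substring(sequence, i, n), perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        out[[length(out) + 1L]] <- data.frame(
          name = p$name, start = i, end = i + len - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(name = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  unique(res[order(res$name, res$start, res$end), , drop = FALSE])
}

#' Read a variant panel file
#'
#' Plain-text panel: one variant token per line; blank lines and \code{#}
#' comments (full-line or trailing) are ignored.
#'
#' @param path Path to the panel file.
#' @return List of \code{phd2_variant} objects, named by token.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vars <- lapply(lines, parse_variant)
  stats::setNames(vars, vapply(vars, format, ""))
}
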