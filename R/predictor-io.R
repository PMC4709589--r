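# Ingestion and normalization of heterogeneous predictor evidence.
#
# The eight supported tools and the shape of their printed outputs:
#   snap      categorical  Neutral / Non-Neutral
#   pmut      categorical  Neutral / Pathological
#   snps3d    labelled score, deleterious when the score is negative
#   imutant   direction (Increase/Decrease) + reliability index 0-10
#   polyphen  label (Benign / Possibly damaging / Probably damaging) + score in [0,1]
#   eris, foldx, neemo  ddG in kcal/mol, positive = destabilizing

PREDICTOR_TOOLS <- c("snap", "pmut", "snps3d", "imutant", "polyphen",
                     "eris", "foldx", "neemo")

# Canonical TSV column names (as in the published evidence table) -> tool ids.
PREDICTOR_COLUMNS <- c(
  Variant = "variant", SNAP = "snap", Pmut = "pmut", SNPS3D = "snps3d",
  `I-Mutant3.0` = "imutant", PolyPhen = "polyphen", Eris = "eris",
  FoldX = "foldx", NeEMO = "neemo", Conservation = "conservation",
  StructuralEffect = "structural_effect"
)

is_missing_cell <- function(x) {
  is.na(x) | !nzchar(trimws(x)) | toupper(trimws(x)) == "NA"
}

parse_number_cell <- function(x, row, column) {
  # tolerate the unicode minus sign used in typeset tables
  x <- gsub("−", "-", trimws(x))
  x <- sub("^ΔΔG\\s*", "", x)  # strip a leading "ddG" symbol if present
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val))
    stop(sprintf("row %s, column %s: cannot parse numeric cell '%s'", row, column, x),
         call. = FALSE)
  val
}

#' Read a predictor evidence table
#'
#' Reads a TSV with one row per variant and the columns \code{Variant},
#' \code{SNAP}, \code{Pmut}, \code{SNPS3D}, \code{I-Mutant3.0},
#' \code{PolyPhen}, \code{Eris}, \code{FoldX}, \code{NeEMO}, plus optional
#' \code{Conservation} and \code{StructuralEffect} annotations. \code{NA} or
#' empty cells (case-insensitive) mean the tool produced no output for that
#' variant. Composite cells keep their printed form: \code{"Decrease 2"}
#' (I-Mutant direction + reliability), \code{"Benign 0.032"} (PolyPhen label +
#' score), \code{"Tolerated 1.10"} / \code{"Deleterious -2.72"} (SNPs3D label +
#' signed score).
#'
#' @param path Path to the TSV file.
#' @param ignore_unknown Keep going when the header contains unrecognized
#'   columns (they are dropped); by default they are a schema error.
#' @return List of \code{evidence_record} objects, named by variant token.
#' @seealso [normalize_and_count()], [phd2_evidence_path()]
#' @export
read_predictor_table <- function(path, ignore_unknown = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  unknown <- setdiff(names(tab), names(PREDICTOR_COLUMNS))
  if (length(unknown) > 0L && !ignore_unknown)
    stop(sprintf("unknown column(s) in evidence table: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  tab <- tab[, intersect(names(tab), names(PREDICTOR_COLUMNS)), drop = FALSE]
  if (!"Variant" %in% names(tab))
    stop("evidence table must have a Variant column", call. = FALSE)
  records <- lapply(seq_len(nrow(tab)), function(i) {
    parse_evidence_row(as.list(tab[i, , drop = FALSE]))
  })
  stats::setNames(records, vapply(records, function(r) format(r$variant), ""))
}

parse_evidence_row <- function(row) {
  v <- parse_variant(row$Variant)
  tok <- format(v)
  get <- function(col) {
    x <- row[[col]]
    if (is.null(x) || is_missing_cell(x)) NULL else trimws(x)
  }
  split_label_number <- function(x, col) {
    parts <- strsplit(x, "\\s+")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("row %s, column %s: expected '<label> <number>', got '%s'", tok, col, x),
           call. = FALSE)
    list(label = paste(parts[-length(parts)], collapse = " "),
         value = parse_number_cell(parts[length(parts)], tok, col))
  }
  snap <- get("SNAP")
  if (!is.null(snap) && !snap %in% c("Neutral", "Non-Neutral"))
    stop(sprintf("row %s: SNAP value must be Neutral or Non-Neutral, got '%s'", tok, snap),
         call. = FALSE)
  pmut <- get("Pmut")
  if (!is.null(pmut) && !pmut %in% c("Neutral", "Pathological"))
    stop(sprintf("row %s: Pmut value must be Neutral or Pathological, got '%s'", tok, pmut),
         call. = FALSE)
  snps3d <- get("SNPS3D")
  if (!is.null(snps3d)) {
    s <- split_label_number(snps3d, "SNPS3D")
    snps3d <- list(label = s$label, score = s$value)
  }
  imutant <- get("I-Mutant3.0")
  if (!is.null(imutant)) {
    s <- split_label_number(imutant, "I-Mutant3.0")
    if (!s$label %in% c("Increase", "Decrease"))
      stop(sprintf("row %s: I-Mutant direction must be Increase or Decrease, got '%s'",
                   tok, s$label), call. = FALSE)
    rel <- as.integer(s$value)
    if (is.na(rel) || rel < 0L || rel > 10L)
      stop(sprintf("row %s: I-Mutant reliability must be an integer in 0-10", tok),
           call. = FALSE)
    imutant <- list(direction = s$label, reliability = rel)
  }
  polyphen <- get("PolyPhen")
  if (!is.null(polyphen)) {
    s <- split_label_number(polyphen, "PolyPhen")
    if (!s$label %in% c("Benign", "Possibly damaging", "Probably damaging"))
      stop(sprintf("row %s: PolyPhen label must be Benign / Possibly damaging / Probably damaging, got '%s'",
                   tok, s$label), call. = FALSE)
    if (s$value < 0 || s$value > 1)
      stop(sprintf("row %s: PolyPhen score %.3f outside [0,1]", tok, s$value), call. = FALSE)
    polyphen <- list(label = s$label, score = s$value)
  }
  ddg <- function(col) {
    x <- get(col)
    if (is.null(x)) NULL else parse_number_cell(x, tok, col)
  }
  cons <- get("Conservation")
  if (!is.null(cons) && !cons %in% c("Variable", "Average", "Conserved"))
    stop(sprintf("row %s: Conservation must be Variable / Average / Conserved, got '%s'",
                 tok, cons), call. = FALSE)
  eff <- get("StructuralEffect")
  evidence_record(
    variant = v, snap = snap, pmut = pmut, snps3d = snps3d, imutant = imutant,
    polyphen = polyphen, eris_ddg = ddg("Eris"), foldx_ddg = ddg("FoldX"),
    neemo_ddg = ddg("NeEMO"), conservation = cons,
    structural_flags = if (is.null(eff)) character() else eff
  )
}

#' Construct an evidence record
#'
#' Programmatic constructor for one variant's predictor evidence; fields left
#' \code{NULL} mean the tool produced no output. See [read_predictor_table()]
#' for field shapes.
#'
#' @param variant A \code{phd2_variant}.
#' @param snap,pmut Categorical calls or \code{NULL}.
#' @param snps3d List \code{(label, score)} or \code{NULL}; deleterious when
#'   the score is negative.
#' @param imutant List \code{(direction, reliability)} or \code{NULL}.
#' @param polyphen List \code{(label, score)} or \code{NULL}.
#' @param eris_ddg,foldx_ddg,neemo_ddg Free-energy changes (kcal/mol,
#'   positive = destabilizing) or \code{NULL}.
#' @param conservation Band \code{"Variable"|"Average"|"Conserved"} or \code{NULL}.
#' @param structural_flags Character vector of structural-effect labels.
#' @return An \code{evidence_record}.
#' @export
evidence_record <- function(variant, snap = NULL, pmut = NULL, snps3d = NULL,
                            imutant = NULL, polyphen = NULL, eris_ddg = NULL,
                            foldx_ddg = NULL, neemo_ddg = NULL,
                            conservation = NULL, structural_flags = character()) {
  stopifnot(inherits(variant, "phd2_variant"))
  structure(
    list(variant = variant, snap = snap, pmut = pmut, snps3d = snps3d,
         imutant = imutant, polyphen = polyphen, eris_ddg = eris_ddg,
         foldx_ddg = foldx_ddg, neemo_ddg = neemo_ddg,
         conservation = conservation, structural_flags = structural_flags),
    class = "evidence_record"
  )
}

#' @export
print.evidence_record <- function(x, ...) {
  cat(sprintf("<evidence> %s | conservation: %s | flags: %s\n",
              format(x$variant), x$conservation %||% "-",
              if (length(x$structural_flags)) paste(x$structural_flags, collapse = ";") else "-"))
  invisible(x)
}

#' Default normalization thresholds
#'
#' @param polyphen_score_cutoff Score at or above which PolyPhen votes
#'   deleterious when no label is available (default 0.5).
#' @param ddg_destabilizing_positive Per-tool logical vector: \code{TRUE}
#'   when positive ddG means destabilizing (the convention of the packaged
#'   table for all three tools).
#' @return Named list of thresholds consumed by [normalize_and_count()].
#' @export
normalization_config <- function(polyphen_score_cutoff = 0.5,
                                 ddg_destabilizing_positive = c(eris = TRUE, foldx = TRUE, neemo = TRUE)) {
  list(polyphen_score_cutoff = polyphen_score_cutoff,
       ddg_destabilizing_positive = ddg_destabilizing_positive)
}

#' Normalize predictor outputs into deleterious votes
#'
#' Applies one fixed rule per tool: SNAP \code{Non-Neutral}, Pmut
#' \code{Pathological}, SNPs3D score < 0, I-Mutant direction \code{Decrease}
#' (the reliability index is recorded but does not gate the vote), PolyPhen
#' label other than \code{Benign} (score >= cutoff as fallback when only a
#' score is present), and each ddG > 0 (destabilizing) vote deleterious;
#' any other present value votes neutral; absent tools stay missing.
#'
#' @param rec An \code{evidence_record}.
#' @param thresholds A [normalization_config()].
#' @return A \code{vote_summary}: sets \code{deleterious}, \code{neutral},
#'   \code{missing} partitioning the eight tools, plus counts
#'   \code{n_deleterious} and \code{n_available}.
#' @examples
#' recs <- read_predictor_table(phd2_evidence_path())
#' normalize_and_count(recs[["N203K"]])$n_deleterious  # 5
#' @export
normalize_and_count <- function(rec, thresholds = normalization_config()) {
  stopifnot(inherits(rec, "evidence_record"))
  vote <- function(tool) {
    switch(tool,
      snap = if (is.null(rec$snap)) NA else rec$snap == "Non-Neutral",
      pmut = if (is.null(rec$pmut)) NA else rec$pmut == "Pathological",
      snps3d = if (is.null(rec$snps3d)) NA else rec$snps3d$score < 0,
      imutant = if (is.null(rec$imutant)) NA else rec$imutant$direction == "Decrease",
      polyphen = if (is.null(rec$polyphen)) NA else {
        if (!is.null(rec$polyphen$label)) rec$polyphen$label != "Benign"
        else rec$polyphen$score >= thresholds$polyphen_score_cutoff
      },
      eris = ddg_vote(rec$eris_ddg, thresholds$ddg_destabilizing_positive[["eris"]]),
      foldx = ddg_vote(rec$foldx_ddg, thresholds$ddg_destabilizing_positive[["foldx"]]),
      neemo = ddg_vote(rec$neemo_ddg, thresholds$ddg_destabilizing_positive[["neemo"]])
    )
  }
  votes <- vapply(PREDICTOR_TOOLS, vote, logical(1))
  summary <- structure(
    list(deleterious = PREDICTOR_TOOLS[which(votes %in% TRUE)],
         neutral = PREDICTOR_TOOLS[which(votes %in% FALSE)],
         missing = PREDICTOR_TOOLS[is.na(votes)],
         n_deleterious = sum(votes, na.rm = TRUE),
         n_available = sum(!is.na(votes))),
    class = "vote_summary"
  )
  summary
}

ddg_vote <- function(ddg, positive_destabilizing) {
  if (is.null(ddg)) return(NA)
  if (isTRUE(positive_destabilizing)) ddg > 0 else ddg < 0
}

#' @export
print.vote_summary <- function(x, ...) {
  cat(sprintf("<votes> %d/%d deleterious (%s)\n", x$n_deleterious, x$n_available,
              if (length(x$deleterious)) paste(x$deleterious, collapse = ", ") else "none"))
  invisible(x)
}

#' Write evidence records back to a TSV
#'
#' Inverse of [read_predictor_table()]: non-missing cells round-trip exactly
#' up to numeric formatting.
#'
#' @param records List of \code{evidence_record} objects.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_predictor_table <- function(records, path) {
  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  row_of <- function(r) {
    c(Variant = format(r$variant),
      SNAP = r$snap %||% "NA",
      Pmut = r$pmut %||% "NA",
      SNPS3D = if (is.null(r$snps3d)) "NA" else paste(r$snps3d$label, fmt_num(r$snps3d$score)),
      `I-Mutant3.0` = if (is.null(r$imutant)) "NA" else paste(r$imutant$direction, r$imutant$reliability),
      PolyPhen = if (is.null(r$polyphen)) "NA" else paste(r$polyphen$label, fmt_num(r$polyphen$score)),
      Eris = if (is.null(r$eris_ddg)) "NA" else fmt_num(r$eris_ddg),
      FoldX = if (is.null(r$foldx_ddg)) "NA" else fmt_num(r$foldx_ddg),
      NeEMO = if (is.null(r$neemo_ddg)) "NA" else fmt_num(r$neemo_ddg),
      Conservation = r$conservation %||% "NA",
      StructuralEffect = if (length(r$structural_flags)) paste(r$structural_flags, collapse = "; ") else "NA")
  }
  rows <- do.call(rbind, lapply(records, row_of))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
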