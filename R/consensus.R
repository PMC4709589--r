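# Four-tier consensus classification of missense variants from normalized
# predictor votes, conservation band and structural evidence.
#
# The decision cascade operationalizes a multi-line-of-evidence policy:
# a variant is called Pathogenic only when the four pathogenicity-oriented
# tools, PolyPhen at its strongest label, conservation and the overall vote
# count all agree; Likely Pathogenic needs at least three deleterious votes
# backed by conservation or a structural flag; a strong predictor-vs-
# stability conflict (pathogenicity tools deleterious while all ddG values
# are stabilizing, at least one strongly) is Ambiguous, as is the absence of
# predictor data; Likely Neutral requires unanimity of the available tools.

VERDICT_LABELS <- c("Pathogenic", "Likely Pathogenic", "Ambiguous", "Likely Neutral")

#' Consensus rule thresholds
#'
#' The defaults are calibrated so that the packaged PHD2 polycythemia
#' evidence table classifies in full agreement with its published verdict
#' column; each can be re-weighed.
#'
#' @param pathogenic_min Minimum deleterious votes for a Pathogenic call
#'   (default 6, "more than six out of ten lines of evidence" counting
#'   conservation and structural analysis as the extra lines).
#' @param likely_pathogenic_min Minimum deleterious votes for Likely
#'   Pathogenic (default 3, "at least three lines of evidence").
#' @param strong_stabilization Cutoff (kcal/mol) below which a stabilizing
#'   ddG counts as strong evidence against destabilization (default -2.0).
#' @param polyphen_probably_min Score treated as "Probably damaging" when
#'   only a numeric PolyPhen score is available (default 0.95).
#' @return A \code{rule_config} list.
#' @export
rule_config <- function(pathogenic_min = 6L, likely_pathogenic_min = 3L,
                        strong_stabilization = -2.0,
                        polyphen_probably_min = 0.95) {
  stopifnot(pathogenic_min >= 0, pathogenic_min <= 8,
            likely_pathogenic_min >= 0, likely_pathogenic_min <= 8,
            is.finite(strong_stabilization), is.finite(polyphen_probably_min))
  structure(list(pathogenic_min = as.integer(pathogenic_min),
                 likely_pathogenic_min = as.integer(likely_pathogenic_min),
                 strong_stabilization = strong_stabilization,
                 polyphen_probably_min = polyphen_probably_min),
            class = "rule_config")
}

#' Classify one variant from its combined evidence
#'
#' Applies six rules in priority order; exactly one fires:
#' \enumerate{
#'   \item no predictor data (nonsense variant or all eight tools missing)
#'     -> Ambiguous;
#'   \item zero deleterious votes -> Likely Neutral (neutral requires
#'     unanimity);
#'   \item SNAP, Pmut, SNPs3D and I-Mutant all deleterious, PolyPhen at
#'     Probably damaging, conservation Conserved, and at least
#'     \code{pathogenic_min} deleterious votes -> Pathogenic;
#'   \item strong stability conflict — at least two of the four
#'     pathogenicity tools deleterious while all three ddG values are
#'     present, stabilizing (<= 0) and at least one at or below
#'     \code{strong_stabilization} -> Ambiguous;
#'   \item at least \code{likely_pathogenic_min} deleterious votes with
#'     conservation Conserved or any structural flag -> Likely Pathogenic;
#'   \item otherwise Likely Neutral when conservation is Variable with at
#'     most one deleterious vote, else Ambiguous.
#' }
#'
#' @param votes A \code{vote_summary} from [normalize_and_count()].
#' @param conservation Band (\code{"Variable"|"Average"|"Conserved"}) or
#'   \code{NULL}.
#' @param flags Character vector of structural-effect labels.
#' @param rec The underlying \code{evidence_record} (consulted for PolyPhen
#'   label and ddG magnitudes).
#' @param cfg A [rule_config()].
#' @return A \code{verdict}: list with \code{label}, \code{rule} (identifier
#'   of the rule that fired), \code{rationale}, and the evidence trail
#'   (\code{votes}, \code{conservation}, \code{flags}).
#' @export
classify_variant <- function(votes, conservation = NULL, flags = character(),
                             rec = NULL, cfg = rule_config()) {
  stopifnot(inherits(votes, "vote_summary"))
  verdict <- function(label, rule, rationale) {
    structure(list(label = label, rule = rule, rationale = rationale,
                   votes = votes, conservation = conservation, flags = flags),
              class = "verdict")
  }
  is_nonsense <- !is.null(rec) && rec$variant$kind == "nonsense"
  # (1) nothing to vote on
  if (votes$n_available == 0L || is_nonsense)
    return(verdict("Ambiguous", "no_predictor_data",
                   "no predictor output available (nonsense variant or empty evidence)"))
  # (2) unanimity of available tools on neutral
  if (votes$n_deleterious == 0L)
    return(verdict("Likely Neutral", "unanimous_neutral",
                   sprintf("all %d available predictors vote neutral", votes$n_available)))
  path_tools <- c("snap", "pmut", "snps3d", "imutant")
  n_path_del <- sum(path_tools %in% votes$deleterious)
  polyphen_probably <- FALSE
  if (!is.null(rec) && !is.null(rec$polyphen)) {
    polyphen_probably <- if (!is.null(rec$polyphen$label))
      rec$polyphen$label == "Probably damaging"
    else rec$polyphen$score >= cfg$polyphen_probably_min
  }
  # (3) full agreement across tool families, conservation and vote count
  if (n_path_del == 4L && polyphen_probably &&
      identical(conservation, "Conserved") &&
      votes$n_deleterious >= cfg$pathogenic_min)
    return(verdict("Pathogenic", "full_agreement",
                   sprintf("%d/%d deleterious; pathogenicity tools and PolyPhen unanimous; conserved position",
                           votes$n_deleterious, votes$n_available)))
  # (4) pathogenicity tools vs stability predictors in strong conflict
  ddg <- if (is.null(rec)) NULL else c(rec$eris_ddg, rec$foldx_ddg, rec$neemo_ddg)
  ddg <- ddg[!is.na(ddg)]
  if (n_path_del >= 2L && length(ddg) == 3L && all(ddg <= 0) &&
      min(ddg) <= cfg$strong_stabilization)
    return(verdict("Ambiguous", "stability_conflict",
                   sprintf("%d pathogenicity tools deleterious but all ddG stabilizing (min %.2f kcal/mol)",
                           n_path_del, min(ddg))))
  # (5) enough deleterious lines with supporting conservation or structure
  if (votes$n_deleterious >= cfg$likely_pathogenic_min &&
      (identical(conservation, "Conserved") || length(flags) > 0L))
    return(verdict("Likely Pathogenic", "supported_majority",
                   sprintf("%d/%d deleterious with %s", votes$n_deleterious, votes$n_available,
                           if (identical(conservation, "Conserved")) "conserved position"
                           else "structural support")))
  # (6) fallback
  if (identical(conservation, "Variable") && votes$n_deleterious <= 1L)
    return(verdict("Likely Neutral", "weak_minority",
                   sprintf("only %d/%d deleterious at a variable position",
                           votes$n_deleterious, votes$n_available)))
  verdict("Ambiguous", "unresolved",
          sprintf("%d/%d deleterious without consistent support", votes$n_deleterious,
                  votes$n_available))
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s [%s] %s\n", x$label, x$rule, x$rationale))
  invisible(x)
}

#' Run the full classification pipeline
#'
#' Orchestrates panel ingestion, vote normalization, conservation lookup,
#' structural flagging and consensus classification; optionally adds the
#' structural report sections (interaction-network neighborhood per mutated
#' residue, catalog neighbor pairs, exposed-patch clusters and interface
#' overlap).
#'
#' Conservation per variant comes from the profile when an alignment is
#' given, else from the evidence table's Conservation column. Structural
#' flags are the union of table annotations and, when a structure is given,
#' the rule-derived flags of [derive_structural_flags()].
#'
#' @param panel Path to a panel file, or a list of \code{phd2_variant}s.
#' @param evidence Path to an evidence TSV, or a named list of
#'   \code{evidence_record}s.
#' @param msa Optional path to an aligned FASTA (or \code{msa_alignment}).
#' @param structure Optional path to a PDB file (or \code{structure_model}).
#' @param catalog Optional catalog path or data.frame for neighbor analysis.
#' @param cfg A [rule_config()].
#' @param thresholds A [normalization_config()].
#' @param functional_sites Site sets for structural flagging.
#' @param neighbor_cutoff,interface_chain,interface_cutoff,exposure_min,link_cutoff
#'   Geometry parameters for the optional structural sections.
#' @return A \code{pipeline_report}: list with \code{verdicts} (named list),
#'   \code{table} (one row per variant), \code{uncovered} (panel variants
#'   without evidence), and optional \code{structural} sections.
#' @examples
#' rep <- run_pipeline(phd2_panel_path(), phd2_evidence_path(),
#'                     catalog = phd2_cancer_catalog_path())
#' rep$table[, c("variant", "verdict")]
#' @export
run_pipeline <- function(panel, evidence, msa = NULL, structure = NULL,
                         catalog = NULL, cfg = rule_config(),
                         thresholds = normalization_config(),
                         functional_sites = phd2_functional_sites(),
                         neighbor_cutoff = 5.0, interface_chain = NULL,
                         interface_cutoff = 5.0, exposure_min = 0.2,
                         link_cutoff = 12) {
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.character(evidence)) evidence <- read_predictor_table(evidence)
  panel_tokens <- vapply(panel, format, "")
  extra <- setdiff(names(evidence), panel_tokens)
  if (length(extra) > 0L)
    warning(sprintf("evidence rows without panel entry: %s", paste(extra, collapse = ", ")),
            call. = FALSE)
  uncovered <- setdiff(panel_tokens, names(evidence))
  covered <- intersect(panel_tokens, names(evidence))

  profile <- NULL
  if (!is.null(msa)) {
    if (is.character(msa)) msa <- read_msa(msa)
    profile <- conservation_profile(msa)
  }
  model <- NULL; sasa <- NULL; rin <- NULL
  if (!is.null(structure)) {
    model <- if (is.character(structure)) read_structure(structure) else structure
    sasa <- compute_sasa(model, exposure_min = exposure_min)
    rin <- build_rin(model)
  }
  if (is.character(catalog)) catalog <- read_catalog(catalog)

  verdicts <- list()
  for (tok in covered) {
    rec <- evidence[[tok]]
    votes <- normalize_and_count(rec, thresholds)
    cons <- rec$conservation
    if (!is.null(profile)) {
      hit <- match(rec$variant$position, profile$position)
      if (!is.na(hit)) cons <- profile$band[hit]
    }
    flags <- rec$structural_flags
    if (!is.null(model)) {
      derived <- suppressWarnings(derive_structural_flags(
        rec$variant, model, sasa, functional_sites, rin = rin,
        exposure_min = exposure_min))
      flags <- unique(c(flags, derived))
    }
    verdicts[[tok]] <- classify_variant(votes, cons, flags, rec, cfg)
  }
  tab <- do.call(rbind, lapply(covered, function(tok) {
    v <- verdicts[[tok]]
    data.frame(variant = tok,
               region = annotate_region(evidence[[tok]]$variant,
                                        fallthrough = "outside_map"),
               n_deleterious = v$votes$n_deleterious,
               n_available = v$votes$n_available,
               conservation = v$conservation %||% NA_character_,
               flags = paste(v$flags, collapse = ";"),
               verdict = v$label, rule = v$rule,
               stringsAsFactors = FALSE)
  })) %||% data.frame()

  structural <- NULL
  if (!is.null(model)) {
    positions <- vapply(evidence[covered], function(r) r$variant$position, integer(1))
    structural <- list(
      sasa = sasa,
      rin_neighborhoods = lapply(stats::setNames(as.list(positions), covered),
                                 function(p) rin_neighborhood(rin, p)),
      neighbor_pairs = if (!is.null(catalog))
        neighbor_analysis(model, unname(positions), catalog, cutoff = neighbor_cutoff)
      else NULL,
      interface = if (!is.null(interface_chain))
        interface_residues(model, interface_chain, interface_cutoff)
      else NULL
    )
    interface_set <- if (!is.null(structural$interface)) structural$interface$resno else NULL
    structural$patches <- cluster_exposed_patch(
      model, unname(positions), sasa, exposure_min = exposure_min,
      link_cutoff = link_cutoff, interface = interface_set)
  } else if (!is.null(catalog) && length(covered) > 0L) {
    structural <- list(neighbor_pairs = NULL)
  }

  report <- list(verdicts = verdicts, table = tab, uncovered = uncovered,
                 conservation = profile, structural = structural, config = cfg)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<report> %d variant(s) classified", nrow(x$table)))
  if (length(x$uncovered)) cat(sprintf(", %d uncovered (%s)", length(x$uncovered),
                                       paste(x$uncovered, collapse = ", ")))
  cat("\n")
  if (nrow(x$table) > 0L) {
    counts <- table(factor(x$table$verdict, levels = VERDICT_LABELS))
    cat("  ", paste(sprintf("%s: %d", names(counts), counts), collapse = " | "), "\n")
    print(x$table[, c("variant", "region", "n_deleterious", "n_available",
                      "conservation", "verdict")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A \code{pipeline_report}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    table = report$table,
    uncovered = report$uncovered,
    verdicts = lapply(report$verdicts, function(v) {
      list(label = v$label, rule = v$rule, rationale = v$rationale,
           n_deleterious = v$votes$n_deleterious, n_available = v$votes$n_available,
           deleterious = v$votes$deleterious, conservation = v$conservation,
           flags = v$flags)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null", pretty = TRUE,
                       digits = NA)
  invisible(path)
}
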