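# Accessors for the packaged PHD2 worked-example data: the published
# polycythemia variant panel, its predictor evidence table, the catalog of
# cancer-mutated neighbor positions, the functional-site configuration and
# the default region map.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "phd2screen")
  if (!nzchar(p)) stop(sprintf("packaged file '%s' not found", file), call. = FALSE)
  p
}

#' Path to the packaged PHD2 polycythemia variant panel
#'
#' Twelve variants reported in polycythemic patients, one token per line
#' (eleven missense plus the R398X nonsense truncation).
#'
#' @return File path.
#' @export
phd2_panel_path <- function() extdata_path("phd2_panel.txt")

#' Path to the packaged PHD2 predictor evidence table
#'
#' The published per-variant outputs of SNAP, Pmut, SNPs3D, I-Mutant3.0,
#' PolyPhen, Eris, FoldX and NeEMO, with conservation bands and
#' structural-effect annotations, transcribed from the source publication's
#' results table.
#'
#' @return File path.
#' @export
phd2_evidence_path <- function() extdata_path("phd2_evidence.tsv")

#' Path to the packaged cancer-position neighbor catalog
#'
#' COSMIC-derived PHD2 positions mutated in human cancers (202 bladder, 292
#' colon adenocarcinoma, 344 lung small cell carcinoma) with their source
#' annotations, for [neighbor_analysis()].
#'
#' @return File path.
#' @export
phd2_cancer_catalog_path <- function() extdata_path("phd2_cancer_catalog.tsv")

#' Path to the packaged functional-site configuration
#'
#' @return File path.
#' @seealso [phd2_functional_sites()]
#' @export
phd2_sites_path <- function() extdata_path("phd2_functional_sites.tsv")

#' Path to the packaged PHD2 region map
#'
#' @return File path.
#' @seealso [phd2_region_map()]
#' @export
phd2_region_map_path <- function() extdata_path("phd2_region_map.tsv")

#' The published verdicts for the packaged panel
#'
#' @return Named character vector: variant token -> published verdict label.
#' @export
phd2_published_verdicts <- function() {
  c(V138A = "Likely Neutral", P165S = "Likely Neutral", Q157H = "Likely Neutral",
    K423E = "Likely Pathogenic", P200Q = "Ambiguous", N203K = "Likely Pathogenic",
    D254H = "Likely Pathogenic", K291I = "Likely Pathogenic",
    P317R = "Pathogenic", R371H = "Pathogenic", H374R = "Pathogenic",
    R398X = "Ambiguous")
}
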