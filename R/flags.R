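# Rule-based structural-effect flags for a variant on a structure.

#' Default PHD2 functional-site configuration
#'
#' Residue-position sets used by [derive_structural_flags()], assembled from
#' the PHD2 catalytic architecture: the Fe(II)-coordinating facial triad
#' (His313, Asp315, His374), the 2-oxoglutarate-contacting Asp254, the
#' Cys201-Cys208 disulfide pair, and the substrate-selectivity beta2-beta3
#' loop (236-254). All sets are user-editable; the packaged TSV
#' (\code{phd2_functional_sites.tsv}) carries the same defaults.
#'
#' @return Named list of integer position vectors: \code{iron_triad},
#'   \code{og_contacts}, \code{disulfide_pair}, \code{beta2_beta3_loop},
#'   \code{catalytic} (union of triad and 2-OG contacts).
#' @export
phd2_functional_sites <- function() {
  sites <- list(
    iron_triad = c(313L, 315L, 374L),
    og_contacts = 254L,
    disulfide_pair = c(201L, 208L),
    beta2_beta3_loop = 236:254
  )
  sites$catalytic <- sort(unique(c(sites$iron_triad, sites$og_contacts)))
  sites
}

#' Read a functional-site configuration TSV
#'
#' Two columns: set name, comma-separated positions (ranges written
#' \code{a-b} allowed). A \code{catalytic} union is added when absent.
#'
#' @param path Path to the TSV.
#' @return Named list of integer vectors as in [phd2_functional_sites()].
#' @export
read_functional_sites <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  parse_positions <- function(x) {
    parts <- trimws(strsplit(x, ",")[[1]])
    unlist(lapply(parts, function(p) {
      if (grepl("-", p, fixed = TRUE)) {
        ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else as.integer(p)
    }))
  }
  sites <- stats::setNames(lapply(tab[[2]], parse_positions), trimws(tab[[1]]))
  if (!"catalytic" %in% names(sites))
    sites$catalytic <- sort(unique(c(sites$iron_triad, sites$og_contacts)))
  sites
}

#' Derive structural-effect flags for a variant
#'
#' Applies a fixed rule set on the variant's position in the structure:
#' \describe{
#'   \item{catalytic_site}{position is in the configured catalytic set, or
#'     within \code{proximity} A (minimal heavy-atom distance) of it.}
#'   \item{charge_inversion}{reference and alternate residues carry opposite
#'     formal charges (His counted positive).}
#'   \item{exposed_hydrophobic}{hydrophilic-to-hydrophobic substitution at a
#'     solvent-exposed position (relative SASA >= \code{exposure_min}).}
#'   \item{proline_loss}{the reference residue is proline.}
#'   \item{disulfide_perturbation}{position is within \code{proximity} A of a
#'     disulfide edge of the network (or is itself a disulfide partner).}
#' }
#' An unresolvable position yields the sequence-only flags
#' (charge_inversion, proline_loss, catalytic-set membership) with a warning.
#'
#' @param v A \code{phd2_variant}.
#' @param model A \code{structure_model}.
#' @param sasa \code{sasa_profile} on the same model.
#' @param functional_sites Site configuration, see [phd2_functional_sites()].
#' @param rin Optional precomputed \code{residue_network} (built on demand
#'   otherwise, only when a disulfide check is needed).
#' @param exposure_min Relative-SASA exposure threshold (default 0.2).
#' @param proximity Distance for "close to" rules in A (default 5.0).
#' @param chain Chain the variant position refers to (default first chain).
#' @return Character vector of flag labels (possibly empty).
#' @export
derive_structural_flags <- function(v, model, sasa,
                                    functional_sites = phd2_functional_sites(),
                                    rin = NULL, exposure_min = 0.2,
                                    proximity = 5.0, chain = NULL) {
  stopifnot(inherits(v, "phd2_variant"))
  flags <- character()
  charge_ref <- AA_CHARGE[v$ref_aa]; charge_ref[is.na(charge_ref)] <- 0L
  charge_alt <- AA_CHARGE[v$alt_aa]; charge_alt[is.na(charge_alt)] <- 0L
  if (charge_ref * charge_alt < 0L) flags <- c(flags, "charge_inversion")
  if (v$ref_aa == "P") flags <- c(flags, "proline_loss")
  in_catalytic_set <- v$position %in% functional_sites$catalytic
  resolved <- FALSE
  if (!is.null(model)) {
    chain <- chain %||% sort(unique(model$chain))[1]
    at <- residue_atoms(model, chain, v$position)
    resolved <- nrow(at) > 0L
  }
  if (!resolved) {
    if (in_catalytic_set) flags <- c(flags, "catalytic_site")
    warning(sprintf("position %d not resolvable in the model; sequence-only flags returned",
                    v$position), call. = FALSE)
    return(sort(unique(flags)))
  }
  axyz <- as.matrix(at[, c("x", "y", "z")])
  min_dist_to <- function(positions) {
    positions <- setdiff(positions, v$position)
    if (length(positions) == 0L) return(Inf)
    tgt <- model[model$chain == chain & model$resno %in% positions, c("x", "y", "z")]
    if (nrow(tgt) == 0L) return(Inf)
    min(pair_dist(axyz, as.matrix(tgt)))
  }
  if (in_catalytic_set || min_dist_to(functional_sites$catalytic) <= proximity)
    flags <- c(flags, "catalytic_site")
  rel <- sasa$rel_sasa[sasa$chain == chain & sasa$resno == v$position]
  exposed <- length(rel) == 1L && !is.na(rel) && rel >= exposure_min
  if (exposed && !v$ref_aa %in% AA_HYDROPHOBIC && v$alt_aa %in% AA_HYDROPHOBIC &&
      v$kind == "missense")
    flags <- c(flags, "exposed_hydrophobic")
  # disulfide proximity
  has_cys_pair <- any(model$resid == "CYS" & model$elety == "SG")
  if (has_cys_pair) {
    if (is.null(rin)) rin <- build_rin(model)
    ss <- rin[rin$type == "disulfide", , drop = FALSE]
    if (nrow(ss) > 0L) {
      partners <- unique(c(ss$resno1, ss$resno2))
      if (v$position %in% partners || min_dist_to(partners) <= proximity)
        flags <- c(flags, "disulfide_perturbation")
    }
  }
  sort(unique(flags))
}
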