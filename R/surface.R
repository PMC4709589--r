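# Interface extraction, neighbor analysis against an annotated residue
# catalog, and exposed-patch clustering on the protein surface.

#' Receptor residues at a ligand interface
#'
#' A receptor residue belongs to the interface iff any of its heavy atoms
#' lies within \code{cutoff} of any heavy atom of the ligand chain.
#'
#' @param model A \code{structure_model} with at least two chains.
#' @param ligand_chain Chain id of the ligand (e.g. a substrate peptide).
#' @param cutoff Heavy-atom distance cutoff in A (default 5.0).
#' @return data.frame of interface residues: \code{chain}, \code{resno},
#'   \code{resid}, \code{min_distance}.
#' @export
interface_residues <- function(model, ligand_chain, cutoff = 5.0) {
  stopifnot(inherits(model, "structure_model"))
  if (!ligand_chain %in% model$chain)
    stop(sprintf("ligand chain '%s' not present in the model", ligand_chain), call. = FALSE)
  if (all(model$chain == ligand_chain))
    stop("model has no receptor chain distinct from the ligand", call. = FALSE)
  lig <- as.matrix(model[model$chain == ligand_chain, c("x", "y", "z")])
  rec <- model[model$chain != ligand_chain, , drop = FALSE]
  res <- model_residues(rec)
  if (cutoff <= 0 || nrow(res) == 0L)
    return(res[integer(), c("chain", "resno", "resid")])
  dmin <- vapply(seq_len(nrow(res)), function(i) {
    at <- rec[rec$chain == res$chain[i] & rec$resno == res$resno[i], c("x", "y", "z")]
    min(pair_dist(as.matrix(at), lig))
  }, numeric(1))
  out <- res[dmin <= cutoff, , drop = FALSE]
  out$min_distance <- dmin[dmin <= cutoff]
  rownames(out) <- NULL
  out
}

#' Read an annotated residue catalog
#'
#' TSV with columns \code{variant} (optional source variant token),
#' \code{position}, \code{primary_site}, \code{histology}, \code{subtype},
#' \code{source_id}. Rows whose position is empty (positions printed as
#' dashes) are dropped.
#'
#' @param path Path to the catalog TSV.
#' @return data.frame catalog of annotated residue positions.
#' @seealso [phd2_cancer_catalog_path()] for the packaged catalog of
#'   cancer-mutated PHD2 neighbor positions.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot("position" %in% names(tab))
  tab <- tab[!is.na(suppressWarnings(as.integer(tab$position))), , drop = FALSE]
  tab$position <- as.integer(tab$position)
  if (any(tab$position < 1L)) stop("catalog positions must be >= 1", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Neighbor analysis of query positions against an annotated catalog
#'
#' Pairs each query residue with every catalog position whose minimal
#' heavy-atom distance in the model is at most \code{cutoff}; positions
#' adjacent in sequence (|query - catalog| = 1) always qualify, with the
#' measured distance when both are resolvable and \code{NA} otherwise.
#' Query positions absent from the model are reported in the
#' \code{unresolved} attribute rather than failing.
#'
#' @param model A \code{structure_model}.
#' @param query_positions Integer residue numbers of interest (e.g. mutated
#'   positions).
#' @param catalog Catalog data.frame from [read_catalog()].
#' @param cutoff Heavy-atom distance cutoff in A (default 5.0).
#' @param chain Chain to which positions refer (default first chain).
#' @return data.frame of pairs: \code{query}, \code{catalog_position},
#'   \code{distance}, plus the catalog's annotation columns; attribute
#'   \code{unresolved} lists query positions missing from the model.
#' @export
neighbor_analysis <- function(model, query_positions, catalog, cutoff = 5.0,
                              chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  chain <- chain %||% sort(unique(model$chain))[1]
  sub <- model[model$chain == chain, , drop = FALSE]
  present <- unique(sub$resno)
  unresolved <- setdiff(query_positions, present)
  ann_cols <- setdiff(names(catalog), c("position"))
  rows <- list()
  for (q in query_positions) {
    for (k in seq_len(nrow(catalog))) {
      cp <- catalog$position[k]
      if (q == cp) next
      adjacent <- abs(q - cp) == 1L
      d <- NA_real_
      if (q %in% present && cp %in% present) {
        aq <- as.matrix(sub[sub$resno == q, c("x", "y", "z")])
        ac <- as.matrix(sub[sub$resno == cp, c("x", "y", "z")])
        d <- min(pair_dist(aq, ac))
      }
      if (adjacent || (!is.na(d) && d <= cutoff)) {
        row <- data.frame(query = q, catalog_position = cp, distance = d,
                          stringsAsFactors = FALSE)
        for (cc in ann_cols) row[[cc]] <- catalog[[cc]][k]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    out0 <- data.frame(query = integer(), catalog_position = integer(),
                       distance = numeric(), stringsAsFactors = FALSE)
    for (cc in ann_cols) out0[[cc]] <- catalog[[cc]][integer()]
    out0
  }
  attr(out, "unresolved") <- unresolved
  out
}

#' Cluster exposed residues into surface patches
#'
#' Drops buried positions (relative SASA below \code{exposure_min}), then
#' single-linkage clusters the remainder on side-chain (C-beta; C-alpha for
#' glycine) distances, cutting at \code{link_cutoff}: two exposed residues
#' fall in the same patch iff a chain of exposed residues connects them with
#' consecutive distances at most the cutoff. Optionally reports the overlap
#' of each patch with an interface residue set.
#'
#' @param model A \code{structure_model}.
#' @param positions Residue numbers to consider (e.g. mutated positions).
#' @param sasa \code{sasa_profile} computed on the same model.
#' @param exposure_min Relative-SASA exposure threshold (default 0.2).
#' @param link_cutoff Single-linkage distance cutoff in A (default 12).
#' @param interface Optional integer vector of interface residue numbers for
#'   the overlap report.
#' @param chain Chain the positions refer to (default first chain).
#' @return A \code{patch_clusters} list: \code{clusters} (list of integer
#'   vectors, largest first), \code{buried} (excluded positions),
#'   \code{unresolved}, and \code{overlap} (per-cluster intersection with
#'   \code{interface}, or NULL).
#' @export
cluster_exposed_patch <- function(model, positions, sasa, exposure_min = 0.2,
                                  link_cutoff = 12, interface = NULL,
                                  chain = NULL) {
  stopifnot(inherits(model, "structure_model"), inherits(sasa, "sasa_profile"))
  chain <- chain %||% sort(unique(model$chain))[1]
  positions <- unique(as.integer(positions))
  present <- sasa$resno[sasa$chain == chain]
  unresolved <- setdiff(positions, present)
  positions <- intersect(positions, present)
  rel <- sasa$rel_sasa[match(paste(chain, positions), paste(sasa$chain, sasa$resno))]
  buried <- positions[is.na(rel) | rel < exposure_min]
  keep <- setdiff(positions, buried)
  clusters <- list()
  if (length(keep) == 1L) {
    clusters <- list(keep)
  } else if (length(keep) > 1L) {
    coords <- t(vapply(keep, function(p) residue_cb_coord(model, chain, p), numeric(3)))
    hc <- stats::hclust(stats::dist(coords), method = "single")
    memb <- stats::cutree(hc, h = link_cutoff)
    clusters <- unname(split(keep, memb))
    clusters <- clusters[order(-lengths(clusters), vapply(clusters, min, integer(1)))]
  }
  overlap <- NULL
  if (!is.null(interface))
    overlap <- lapply(clusters, function(cl) intersect(cl, as.integer(interface)))
  structure(list(clusters = clusters, buried = buried,
                 unresolved = unresolved, overlap = overlap),
            class = "patch_clusters")
}

#' @export
print.patch_clusters <- function(x, ...) {
  cat(sprintf("<patches> %d cluster(s)", length(x$clusters)))
  if (length(x$clusters))
    cat(": ", paste(vapply(x$clusters, function(cl) paste(cl, collapse = "+"), ""),
                    collapse = " | "), sep = "")
  cat(sprintf("; %d buried, %d unresolved\n", length(x$buried), length(x$unresolved)))
  invisible(x)
}

#' Serialize patch clusters (and overlap report) to JSON
#'
#' @param patches A \code{patch_clusters} object.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_patches <- function(patches, path) {
  jsonlite::write_json(unclass(patches), path, auto_unbox = FALSE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
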