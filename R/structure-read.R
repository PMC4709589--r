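#' Read a PDB-format structure into a plain atom table
#'
#' Thin wrapper around \code{bio3d::read.pdb} producing the flat atom table
#' the geometry engine works on. Hetero-atoms and waters are excluded by
#' default; alternate locations are resolved by keeping, per (chain, residue,
#' atom name), the record with highest occupancy (ties by altloc letter).
#' Hydrogens are dropped by default: all contact and accessibility
#' calculations are heavy-atom based.
#'
#' @param path Path to a PDB file with ATOM records (single model).
#' @param keep_hetero Keep HETATM records other than water.
#' @param keep_hydrogens Keep hydrogen atoms.
#' @return A \code{structure_model}: data.frame with columns \code{chain},
#'   \code{resno}, \code{resid} (three-letter), \code{elety} (atom name),
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{radius} (van der
#'   Waals, A).
#' @export
read_structure <- function(path, keep_hetero = FALSE, keep_hydrogens = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop(sprintf("cannot read PDB file '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop(sprintf("'%s' contains no ATOM records", path), call. = FALSE)
  water <- at$resid %in% c("HOH", "WAT", "DOD")
  keep <- at$type == "ATOM" & !water
  if (keep_hetero) keep <- keep | (at$type == "HETATM" & !water)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("'%s' contains no usable ATOM records", path), call. = FALSE)
  at$chain[is.na(at$chain) | !nzchar(at$chain)] <- "A"
  element <- toupper(trimws(at$elesy))
  miss <- is.na(element) | !nzchar(element)
  element[miss] <- element_from_name(at$elety[miss])
  if (!keep_hydrogens) {
    h <- element %in% c("H", "D")
    at <- at[!h, , drop = FALSE]
    element <- element[!h]
  }
  model <- data.frame(
    chain = at$chain, resno = as.integer(at$resno), resid = at$resid,
    elety = at$elety, element = element,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(model$x) | !is.finite(model$y) | !is.finite(model$z)))
    stop("structure contains non-finite coordinates", call. = FALSE)
  # altloc resolution: highest occupancy, ties to the alphabetically first altloc
  key <- paste(model$chain, model$resno, model$elety, sep = "\r")
  ord <- order(key, -model$o, model$alt)
  model <- model[ord, , drop = FALSE]
  model <- model[!duplicated(key[ord]), , drop = FALSE]
  model <- model[order(model$chain, model$resno, model$elety), , drop = FALSE]
  model$o <- NULL; model$alt <- NULL
  model$radius <- vdw_radius(model$element)
  rownames(model) <- NULL
  class(model) <- c("structure_model", "data.frame")
  model
}

element_from_name <- function(elety) {
  nm <- toupper(gsub("[^A-Z]", "", elety))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("FE", "ZN", "SE", "MG", "MN", "CL", "BR"), two,
         ifelse(nzchar(one), one, "C"))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure> %d atoms, %d residues, chain(s) %s\n",
              nrow(x), nrow(unique(x[, c("chain", "resno")])),
              paste(sort(unique(x$chain)), collapse = ",")))
  invisible(x)
}

#' Residues of a structure model
#'
#' @param model A \code{structure_model}.
#' @return data.frame with one row per residue: \code{chain}, \code{resno},
#'   \code{resid}.
#' @export
model_residues <- function(model) {
  res <- unique(model[, c("chain", "resno", "resid")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Atom subset for one residue (by chain + residue number).
residue_atoms <- function(model, chain, resno) {
  model[model$chain == chain & model$resno == resno, , drop = FALSE]
}

# Representative side-chain coordinate for patch clustering: CB, CA for Gly
# (or whenever CB is absent).
residue_cb_coord <- function(model, chain, resno) {
  at <- residue_atoms(model, chain, resno)
  if (nrow(at) == 0L) return(NULL)
  pick <- at[at$elety == "CB", , drop = FALSE]
  if (nrow(pick) == 0L) pick <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(pick) == 0L) pick <- at[1, , drop = FALSE]
  c(pick$x[1], pick$y[1], pick$z[1])
}

#' Backbone torsion angles
#'
#' Phi/psi dihedrals (degrees) per residue, computed from N/CA/C backbone
#' atoms. A utility measurement; no downstream rule consumes it.
#'
#' @param model A \code{structure_model}.
#' @param chain Chain to measure (default first chain).
#' @return data.frame with \code{resno}, \code{phi}, \code{psi} (NA at chain
#'   termini or where backbone atoms are missing).
#' @export
backbone_torsions <- function(model, chain = NULL) {
  chain <- chain %||% sort(unique(model$chain))[1]
  sub <- model[model$chain == chain, , drop = FALSE]
  resnos <- sort(unique(sub$resno))
  bb <- function(resno, name) {
    at <- sub[sub$resno == resno & sub$elety == name, , drop = FALSE]
    if (nrow(at) == 0L) return(NULL)
    c(at$x[1], at$y[1], at$z[1])
  }
  dihedral <- function(p1, p2, p3, p4) {
    if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) return(NA_real_)
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- n1 / sqrt(sum(n1^2)); m2 <- n2 / sqrt(sum(n2^2))
    b2u <- b2 / sqrt(sum(b2^2))
    x <- sum(m1 * m2); y <- sum(c(
      m1[2] * m2[3] - m1[3] * m2[2], m1[3] * m2[1] - m1[1] * m2[3],
      m1[1] * m2[2] - m1[2] * m2[1]) * b2u)
    atan2(y, x) * 180 / pi
  }
  out <- lapply(seq_along(resnos), function(i) {
    r <- resnos[i]
    prev_c <- if (i > 1L && resnos[i - 1L] == r - 1L) bb(resnos[i - 1L], "C") else NULL
    next_n <- if (i < length(resnos) && resnos[i + 1L] == r + 1L) bb(resnos[i + 1L], "N") else NULL
    data.frame(resno = r,
               phi = dihedral(prev_c, bb(r, "N"), bb(r, "CA"), bb(r, "C")),
               psi = dihedral(bb(r, "N"), bb(r, "CA"), bb(r, "C"), next_n))
  })
  do.call(rbind, out)
}
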