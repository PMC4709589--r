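# Residue interaction networks: residues as nodes, typed geometric contacts
# as edges. Contact typing follows common RIN conventions, all heavy-atom:
#   generic-contact  minimal inter-residue distance <= 5.0 A, sequence
#                    separation >= 2 within a chain (inter-chain always counts)
#   hydrogen-bond    donor/acceptor N or O pair <= 3.5 A (optional angle gate)
#   ionic            opposite-charge side-chain N/O pair <= 4.0 A
#   disulfide        CYS SG-SG <= 2.5 A

#' Default contact-type distance cutoffs (A)
#'
#' @return Named numeric vector with entries \code{generic}, \code{hbond},
#'   \code{ionic}, \code{disulfide}.
#' @export
rin_cutoffs <- function() {
  c(generic = 5.0, hbond = 3.5, ionic = 4.0, disulfide = 2.5)
}

#' Build a residue interaction network
#'
#' @param model A \code{structure_model}.
#' @param cutoffs Named cutoffs as in [rin_cutoffs()] (any subset overrides
#'   the defaults).
#' @param min_seq_sep Minimum residue-number separation within a chain for
#'   generic and hydrogen-bond contacts (default 2, i.e. bonded neighbors are
#'   not contacts).
#' @param hbond_max_angle Donor-acceptor-antecedent angle tolerance in
#'   degrees; 180 (default) disables the angle gate, appropriate for
#'   hydrogen-free coordinate sets.
#' @return A \code{residue_network}: data.frame of undirected edges, one row
#'   per (residue pair, type): \code{chain1}, \code{resno1}, \code{chain2},
#'   \code{resno2}, \code{type}, \code{distance}. Pairs are ordered so that
#'   (chain1, resno1) <= (chain2, resno2).
#' @export
build_rin <- function(model, cutoffs = rin_cutoffs(), min_seq_sep = 2L,
                      hbond_max_angle = 180) {
  stopifnot(inherits(model, "structure_model"), nrow(model) > 0L)
  co <- rin_cutoffs(); co[names(cutoffs)] <- cutoffs
  res <- model_residues(model)
  n <- nrow(res)
  edges <- list()
  add_edge <- function(i, j, type, dist) {
    edges[[length(edges) + 1L]] <<- data.frame(
      chain1 = res$chain[i], resno1 = res$resno[i],
      chain2 = res$chain[j], resno2 = res$resno[j],
      type = type, distance = dist, stringsAsFactors = FALSE)
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  res_idx <- lapply(seq_len(n), function(i)
    which(model$chain == res$chain[i] & model$resno == res$resno[i]))
  charged_idx <- function(i) {
    at <- CHARGED_SIDECHAIN_ATOMS[[res$resid[i]]]
    if (is.null(at)) return(integer())
    res_idx[[i]][model$elety[res_idx[[i]]] %in% at]
  }
  charge_of <- function(resid) {
    one <- AA3TO1[resid]
    if (is.na(one) || !one %in% names(AA_CHARGE)) 0L else AA_CHARGE[[one]]
  }
  max_cut <- max(co)
  for (i in seq_len(n - 1L)) {
    ai <- res_idx[[i]]
    for (j in seq(i + 1L, n)) {
      same_chain <- res$chain[i] == res$chain[j]
      seq_sep <- abs(res$resno[i] - res$resno[j])
      aj <- res_idx[[j]]
      dm <- pair_dist(xyz[ai, , drop = FALSE], xyz[aj, , drop = FALSE])
      dmin <- min(dm)
      if (dmin > max_cut) next
      long_range <- !same_chain || seq_sep >= min_seq_sep
      if (long_range && dmin <= co[["generic"]])
        add_edge(i, j, "generic-contact", dmin)
      # hydrogen bond: N/O vs N/O
      if (long_range) {
        no_i <- which(model$element[ai] %in% c("N", "O"))
        no_j <- which(model$element[aj] %in% c("N", "O"))
        if (length(no_i) && length(no_j)) {
          dno <- dm[no_i, no_j, drop = FALSE]
          if (min(dno) <= co[["hbond"]] && hbond_angle_ok(
                model, ai[no_i], aj[no_j], dno, co[["hbond"]], hbond_max_angle))
            add_edge(i, j, "hydrogen-bond", min(dno))
        }
      }
      # ionic: opposite formal charge side-chain N/O
      qi <- charge_of(res$resid[i]); qj <- charge_of(res$resid[j])
      if (qi * qj < 0L) {
        ci <- charged_idx(i); cj <- charged_idx(j)
        if (length(ci) && length(cj)) {
          dq <- min(pair_dist(xyz[ci, , drop = FALSE], xyz[cj, , drop = FALSE]))
          if (dq <= co[["ionic"]]) add_edge(i, j, "ionic", dq)
        }
      }
      # disulfide: SG-SG
      if (res$resid[i] == "CYS" && res$resid[j] == "CYS") {
        si <- ai[model$elety[ai] == "SG"]; sj <- aj[model$elety[aj] == "SG"]
        if (length(si) && length(sj)) {
          ds <- min(pair_dist(xyz[si, , drop = FALSE], xyz[sj, , drop = FALSE]))
          if (ds <= co[["disulfide"]]) add_edge(i, j, "disulfide", ds)
        }
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(chain1 = character(), resno1 = integer(), chain2 = character(),
               resno2 = integer(), type = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- co
  class(out) <- c("residue_network", "data.frame")
  out
}

# all-pairs euclidean distances between two coordinate matrices
pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Coarse hydrogen-bond plausibility gate: with hydrogens absent the default
# tolerance (180 deg) accepts any geometry; a tighter tolerance requires the
# donor->acceptor direction to make at most that angle with the acceptor's
# bonded-heavy-atom direction.
hbond_angle_ok <- function(model, donors, acceptors, dno, cutoff, max_angle) {
  if (max_angle >= 180) return(TRUE)
  hits <- which(dno <= cutoff, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    d_at <- donors[hits[k, 1]]; a_at <- acceptors[hits[k, 2]]
    a_res <- model[model$chain == model$chain[a_at] & model$resno == model$resno[a_at], ,
                   drop = FALSE]
    a_xyz <- c(model$x[a_at], model$y[a_at], model$z[a_at])
    d_xyz <- c(model$x[d_at], model$y[d_at], model$z[d_at])
    others <- a_res[a_res$elety != model$elety[a_at], , drop = FALSE]
    if (nrow(others) == 0L) return(TRUE)
    dd <- sqrt((others$x - a_xyz[1])^2 + (others$y - a_xyz[2])^2 + (others$z - a_xyz[3])^2)
    ant <- others[which.min(dd), , drop = FALSE]
    v1 <- d_xyz - a_xyz; v2 <- c(ant$x, ant$y, ant$z) - a_xyz
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (ang <= max_angle) return(TRUE)
  }
  FALSE
}

#' Difference between two residue interaction networks
#'
#' Edges are identified by (chain1, resno1, chain2, resno2, type); distances
#' are carried along but do not affect identity.
#'
#' @param a,b \code{residue_network} objects (e.g. wild-type and mutant).
#' @return List with data.frames \code{lost} (edges of \code{a} absent from
#'   \code{b}) and \code{gained} (edges of \code{b} absent from \code{a}).
#' @export
diff_rin <- function(a, b) {
  key <- function(x) paste(x$chain1, x$resno1, x$chain2, x$resno2, x$type, sep = "\r")
  ka <- key(a); kb <- key(b)
  list(lost = a[!ka %in% kb, , drop = FALSE],
       gained = b[!kb %in% ka, , drop = FALSE])
}

#' Edges incident to a residue
#'
#' @param rin A \code{residue_network}.
#' @param resno Residue number.
#' @param chain Optional chain filter.
#' @return Subset of the edge table touching the residue.
#' @export
rin_neighborhood <- function(rin, resno, chain = NULL) {
  hit <- (rin$resno1 == resno | rin$resno2 == resno)
  if (!is.null(chain))
    hit <- hit & (rin$chain1 == chain | rin$chain2 == chain)
  rin[hit, , drop = FALSE]
}

#' Write a residue interaction network as edge-list TSV
#'
#' @param rin A \code{residue_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rin <- function(rin, path) {
  utils::write.table(as.data.frame(rin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
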