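# Seed-deterministic generators for synthetic test inputs in standard
# formats: toy PDB coordinate sets with planted geometry, aligned FASTA MSAs
# with controlled per-column conservation, and predictor evidence tables
# with planted vote patterns. Fixtures are written to files so every
# pipeline stage is exercised through its real reader.

# run code under a fixed seed without disturbing the caller's RNG state
with_fixture_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fixture
#'
#' @param kind One of \code{"helix"}, \code{"planted-contacts"},
#'   \code{"cage"}, \code{"two-chain-complex"} (structural kinds for
#'   [make_structure_fixture()]), \code{"msa"}, \code{"predictor-table"}.
#' @param ... Kind-specific parameters (see the generator functions).
#' @param seed Integer random seed; the same spec always yields byte-identical
#'   output.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(kind = c("helix", "planted-contacts", "cage",
                                  "two-chain-complex", "msa", "predictor-table"),
                         ..., seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...), seed = as.integer(seed)),
            class = "fixture_spec")
}

# ---- PDB emission -----------------------------------------------------------

# minimal heavy-atom templates in local coordinates (A); CA at the origin
RESIDUE_TEMPLATES <- list(
  GLY = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0)),
  ALA = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0), CB = c(0, -0.77, -1.32)),
  CYS = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0), CB = c(0, -0.77, -1.32),
              SG = c(0, -2.21, -2.40)),
  ASP = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0), CB = c(0, -0.77, -1.32),
              CG = c(0, -1.97, -2.22), OD1 = c(1.05, -2.60, -2.40),
              OD2 = c(-1.05, -2.60, -2.40)),
  LYS = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0), CB = c(0, -0.77, -1.32),
              CG = c(0, -1.97, -2.22), CD = c(0, -3.17, -3.12),
              CE = c(0, -4.37, -4.02), NZ = c(0, -5.37, -4.82)),
  ARG = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0), CB = c(0, -0.77, -1.32),
              CG = c(0, -1.97, -2.22), CD = c(0, -3.17, -3.12),
              NE = c(0, -4.27, -3.92), CZ = c(0, -5.47, -4.40),
              NH1 = c(1.05, -6.10, -4.60), NH2 = c(-1.05, -6.10, -4.60)),
  SER = rbind(N = c(-1.20, 0.80, 0), CA = c(0, 0, 0), C = c(1.25, 0.60, 0),
              O = c(1.35, 1.83, 0), CB = c(0, -0.77, -1.32),
              OG = c(0, -1.97, -2.10))
)

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, element) {
  name_f <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name_f, resname, chain, resno, xyz[1], xyz[2], xyz[3], element)
}

emit_pdb <- function(atoms, path) {
  # atoms: data.frame chain, resno, resname, name, x, y, z
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    el <- element_from_name(atoms$name[i])
    lines[i] <- pdb_atom_line(i, atoms$name[i], atoms$resname[i], atoms$chain[i],
                              atoms$resno[i], c(atoms$x[i], atoms$y[i], atoms$z[i]), el)
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# proper rotation taking direction a onto direction b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {  # antiparallel: rotate pi about any orthogonal axis
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

place_residue <- function(resname, origin, chain, resno, rotation = NULL) {
  tpl <- RESIDUE_TEMPLATES[[resname]]
  if (is.null(tpl)) stop(sprintf("no template for residue '%s'", resname), call. = FALSE)
  xyz <- tpl
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  data.frame(chain = chain, resno = resno, resname = resname,
             name = rownames(tpl),
             x = xyz[, 1] + origin[1], y = xyz[, 2] + origin[2],
             z = xyz[, 3] + origin[3], stringsAsFactors = FALSE)
}

#' Generate a synthetic PDB-format structure fixture
#'
#' Four structural kinds:
#' \describe{
#'   \item{helix}{\code{n_residues} residues with C-alpha atoms on ideal
#'     alpha-helical geometry (rise 1.5 A, 100 degrees per residue, radius
#'     2.3 A) and plausible backbone/C-beta placements;
#'     \code{residue = "ALA"} by default.}
#'   \item{planted-contacts}{\code{pairs}: a list of
#'     \code{list(res1, res2, atom1, atom2, distance, resno1, resno2)} —
#'     each pair is placed so that the two named atoms sit at exactly the
#'     requested distance; successive pairs are 100 A apart.}
#'   \item{cage}{one central \code{target} residue (default ALA, resno 1)
#'     enclosed in a spherical shell of \code{n_shell} carbon pseudo-atoms
#'     at \code{cage_radius} A (default 6), burying it.}
#'   \item{two-chain-complex}{receptor chain A of \code{n_receptor} residues
#'     spaced 4 A apart; ligand chain B of \code{n_ligand} residues, the
#'     first \code{n_contact} of which face their receptor counterparts at
#'     exactly \code{gap} A, the rest displaced 40 A away.}
#' }
#'
#' @param spec A [fixture_spec()] of a structural kind.
#' @param path Output path (default a temp file); same spec gives
#'   byte-identical content.
#' @return The path to the written PDB file.
#' @examples
#' p <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
#'   list(res1 = "CYS", res2 = "CYS", atom1 = "SG", atom2 = "SG",
#'        distance = 2.04, resno1 = 201, resno2 = 208))))
#' build_rin(read_structure(p))
#' @export
make_structure_fixture <- function(spec, path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$params
  atoms <- switch(spec$kind,
    "helix" = {
      n <- p$n_residues %||% 10L
      resname <- p$residue %||% "ALA"
      start <- p$start_resno %||% 1L
      rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
      out <- list()
      ca <- function(i) c(radius * cos(twist * i), radius * sin(twist * i), rise * i)
      for (i in seq_len(n)) {
        cai <- ca(i)
        ni <- if (i > 1L) cai + 0.45 * (ca(i - 1L) - cai) else cai + c(-1.2, 0.5, -0.5)
        ci <- if (i < n) cai + 0.45 * (ca(i + 1L) - cai) else cai + c(1.2, 0.5, 0.5)
        oi <- ci + c(0, 0, 1.23)
        outward <- c(cai[1], cai[2], 0.3)
        outward <- outward / sqrt(sum(outward^2))
        rows <- data.frame(
          chain = "A", resno = start + i - 1L, resname = resname,
          name = c("N", "CA", "C", "O"),
          x = c(ni[1], cai[1], ci[1], oi[1]),
          y = c(ni[2], cai[2], ci[2], oi[2]),
          z = c(ni[3], cai[3], ci[3], oi[3]), stringsAsFactors = FALSE)
        if (resname != "GLY") {
          cb <- cai + 1.53 * outward
          rows <- rbind(rows, data.frame(chain = "A", resno = start + i - 1L, resname = resname,
                                         name = "CB", x = cb[1], y = cb[2], z = cb[3],
                                         stringsAsFactors = FALSE))
        }
        out[[i]] <- rows
      }
      do.call(rbind, out)
    },
    "planted-contacts" = {
      pairs <- p$pairs
      if (is.null(pairs) || length(pairs) == 0L)
        stop("planted-contacts fixture needs a 'pairs' list", call. = FALSE)
      out <- list()
      next_resno <- 1L
      for (k in seq_along(pairs)) {
        pr <- pairs[[k]]
        if (!is.finite(pr$distance) || pr$distance <= 0)
          stop("planted pair distances must be positive", call. = FALSE)
        r1 <- pr$resno1 %||% next_resno
        r2 <- pr$resno2 %||% (r1 + 3L)
        next_resno <- max(r1, r2) + 3L
        off <- c(0, 100 * (k - 1L), 0)
        a <- place_residue(pr$res1, off, "A", r1)
        t1 <- RESIDUE_TEMPLATES[[pr$res1]]
        t2 <- RESIDUE_TEMPLATES[[pr$res2]]
        if (!pr$atom1 %in% rownames(t1) || !pr$atom2 %in% rownames(t2))
          stop(sprintf("pair %d names an atom missing from its residue template", k),
               call. = FALSE)
        # contact axis: outward through atom1, away from residue 1's body
        u <- t1[pr$atom1, ]
        if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0) else u <- u / sqrt(sum(u^2))
        a1 <- t1[pr$atom1, ] + off
        a2 <- a1 + pr$distance * u
        # rotate residue 2 so its own atom2 direction points back along -u,
        # i.e. its body extends onward along +u, clear of residue 1
        v2 <- t2[pr$atom2, ]
        rot <- if (sqrt(sum(v2^2)) < 1e-6) diag(3) else rotation_between(v2, -u)
        t2r <- t2 %*% t(rot)
        origin2 <- a2 - t2r[pr$atom2, ]
        b <- place_residue(pr$res2, origin2, "A", r2, rotation = rot)
        out[[length(out) + 1L]] <- rbind(a, b)
      }
      do.call(rbind, out)
    },
    "cage" = {
      target <- p$target %||% "ALA"
      n_shell <- p$n_shell %||% 100L
      radius <- p$cage_radius %||% 6.0
      core <- place_residue(target, c(0, 0, 0), "A", 1L)
      pts <- sphere_lattice(n_shell) * radius
      shell <- data.frame(chain = "A", resno = 10L + seq_len(n_shell),
                          resname = "GLY", name = "CA",
                          x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          stringsAsFactors = FALSE)
      rbind(core, shell)
    },
    "two-chain-complex" = {
      n_rec <- p$n_receptor %||% 8L
      n_lig <- p$n_ligand %||% 4L
      n_contact <- p$n_contact %||% 3L
      gap <- p$gap %||% 4.0
      if (n_contact > min(n_rec, n_lig))
        stop("n_contact cannot exceed the chain lengths", call. = FALSE)
      if (gap <= 0) stop("interface gap must be positive", call. = FALSE)
      rec <- data.frame(chain = "A", resno = seq_len(n_rec), resname = "GLY",
                        name = "CA", x = 4 * seq_len(n_rec), y = 0, z = 0,
                        stringsAsFactors = FALSE)
      lig_y <- ifelse(seq_len(n_lig) <= n_contact, gap, gap + 40)
      lig <- data.frame(chain = "B", resno = seq_len(n_lig), resname = "GLY",
                        name = "CA", x = 4 * seq_len(n_lig), y = lig_y, z = 0,
                        stringsAsFactors = FALSE)
      rbind(rec, lig)
    },
    stop(sprintf("'%s' is not a structural fixture kind", spec$kind), call. = FALSE)
  )
  emit_pdb(atoms, path)
  path
}

#' Generate an aligned FASTA MSA with controlled conservation
#'
#' Each column has a designated majority residue (cycling through the amino
#' acid alphabet by column index); every sequence draws the majority residue
#' with probability equal to the column's conservation level and otherwise a
#' uniform draw from the remaining 19. Level 1 gives an invariant column.
#' The first sequence is the (gap-free) reference row.
#'
#' @param n_seqs Number of sequences.
#' @param length Number of columns.
#' @param levels Per-column conservation levels in [0,1], recycled.
#' @param seed Random seed (byte-identical output for identical arguments).
#' @param path Output path (default temp file).
#' @return The path to the written aligned FASTA.
#' @export
make_msa_fixture <- function(n_seqs, length, levels, seed = 1L,
                             path = tempfile(fileext = ".fasta")) {
  stopifnot(n_seqs >= 1L, length >= 1L, all(levels >= 0 & levels <= 1))
  levels <- rep_len(levels, length)
  mat <- with_fixture_seed(seed, {
    m <- matrix("", nrow = n_seqs, ncol = length)
    for (j in seq_len(length)) {
      major <- AA1[(j - 1L) %% 20L + 1L]
      others <- setdiff(AA1, major)
      take_major <- stats::runif(n_seqs) < levels[j]
      m[, j] <- ifelse(take_major, major,
                       others[sample.int(19L, n_seqs, replace = TRUE)])
    }
    m
  })
  ids <- sprintf("seq%03d", seq_len(n_seqs))
  lines <- character(0)
  for (i in seq_len(n_seqs))
    lines <- c(lines, paste0(">", ids[i]), paste(mat[i, ], collapse = ""))
  writeLines(lines, path)
  path
}

#' Generate a predictor evidence table with planted vote patterns
#'
#' Each pattern plants one table row realizing a chosen vote for every tool
#' and states the verdict the row must receive under the default rules. Vote
#' codes per tool: \code{"del"} / \code{"neut"} / \code{NA} (missing);
#' PolyPhen additionally accepts \code{"del_strong"} (Probably damaging);
#' the three ddG tools accept a numeric string to plant an exact value
#' (e.g. \code{"-2.5"}).
#'
#' @param patterns List of \code{list(variant =, votes =, conservation =,
#'   structural_effect =, expected =)} entries, where \code{votes} is a named
#'   character vector over the eight tool ids.
#' @param seed Random seed for the synthesized numeric magnitudes.
#' @param path Output TSV path (default temp file).
#' @return List with \code{path} (the TSV) and \code{key} (data.frame
#'   \code{variant}, \code{expected}).
#' @export
make_predictor_fixture <- function(patterns, seed = 1L,
                                   path = tempfile(fileext = ".tsv")) {
  rows <- with_fixture_seed(seed, lapply(patterns, function(pt) {
    votes <- pt$votes
    unknown <- setdiff(names(votes), PREDICTOR_TOOLS)
    if (length(unknown) > 0L)
      stop(sprintf("vote pattern references unknown tool(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    g <- function(tool) if (tool %in% names(votes)) votes[[tool]] else NA
    num <- function(lo, hi) round(stats::runif(1, lo, hi), 2)
    cell <- function(tool) {
      v <- g(tool)
      if (is.na(v)) return("NA")
      numeric_v <- suppressWarnings(as.numeric(v))
      switch(tool,
        snap = if (v == "del") "Non-Neutral" else "Neutral",
        pmut = if (v == "del") "Pathological" else "Neutral",
        snps3d = if (v == "del") sprintf("Deleterious %.2f", -num(0.5, 3.5))
                 else sprintf("Tolerated %.2f", num(0.3, 1.5)),
        imutant = if (v == "del") sprintf("Decrease %d", sample(1:9, 1))
                  else sprintf("Increase %d", sample(1:9, 1)),
        polyphen = if (v == "del_strong") sprintf("Probably damaging %.3f", num(0.96, 0.999))
                   else if (v == "del") sprintf("Possibly damaging %.3f", num(0.5, 0.95))
                   else sprintf("Benign %.3f", num(0.001, 0.3)),
        if (!is.na(numeric_v)) sprintf("%.2f", numeric_v)
        else if (v == "del") sprintf("%.2f", num(0.5, 4))
        else sprintf("%.2f", -num(0.1, 1.5))
      )
    }
    c(Variant = pt$variant,
      SNAP = cell("snap"), Pmut = cell("pmut"), SNPS3D = cell("snps3d"),
      `I-Mutant3.0` = cell("imutant"), PolyPhen = cell("polyphen"),
      Eris = cell("eris"), FoldX = cell("foldx"), NeEMO = cell("neemo"),
      Conservation = pt$conservation %||% "NA",
      StructuralEffect = pt$structural_effect %||% "NA")
  }))
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(path = path,
       key = data.frame(variant = vapply(patterns, `[[`, "", "variant"),
                        expected = vapply(patterns, `[[`, "", "expected"),
                        stringsAsFactors = FALSE))
}
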