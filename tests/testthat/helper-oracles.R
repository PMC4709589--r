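`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used to cross-check the package's geometry and scoring
# implementations. Deliberately brute-force / closed-form and kept free of
# package internals.

# Shannon-entropy conservation oracle, written from the closed form.
entropy_score_oracle <- function(column) {
  gap <- column %in% c("-", ".")
  if (all(gap)) return(0)
  p <- table(column[!gap]) / sum(!gap)
  h <- -sum(p * log(p))
  (1 - h / log(20)) * mean(!gap)
}

# Single-linkage clustering by union-find over the pairwise distance matrix.
union_find_clusters <- function(coords, cutoff) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq(i + 1L, n)) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# canonical form for comparing cluster partitions
canon_clusters <- function(cl) {
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  cl[order(vapply(cl, min, integer(1)))]
}

# All-pairs heavy-atom distance scan for interface extraction.
brute_interface <- function(model, ligand_chain, cutoff) {
  lig <- model[model$chain == ligand_chain, , drop = FALSE]
  rec <- model[model$chain != ligand_chain, , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
    d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 + (rec$z[i] - lig$z[j])^2)
    if (d <= cutoff) hits <- c(hits, paste(rec$chain[i], rec$resno[i]))
  }
  sort(unique(hits))
}

# Accessible area of two identical overlapping spheres of radius R at center
# distance d (spherical-cap closed form): each sphere loses a cap of height
# h = R - d/2, area 2*pi*R*h.
two_sphere_area_oracle <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Minimal hand-rolled PDB emitters for atom-level SASA oracles.
write_atoms_pdb <- function(xyz, elements, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    sprintf("ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, "CA", "GLY", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3], elements[i])
  }, "")
  writeLines(c(lines, "TER", "END"), path)
  path
}

# Brute-force sliding-window motif count oracle for unanchored literal motifs.
count_substring_oracle <- function(sequence, motif) {
  n <- nchar(sequence); k <- nchar(motif)
  sum(vapply(seq_len(max(n - k + 1L, 0L)),
             function(i) substring(sequence, i, i + k - 1L) == motif, logical(1)))
}

# random valid variant tokens for round-trip properties
random_variant_tokens <- function(n) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ref <- sample(aas, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(c(setdiff(aas, r), "X"), 1), "")
  paste0(ref, sample(1:999, n, replace = TRUE), alt)
}
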