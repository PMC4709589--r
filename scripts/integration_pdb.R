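#!/usr/bin/env Rscript
# Optional integration check on the deposited PHD2 crystal structures.
# Requires network access to fetch PDB entries 3HQU (beta2-beta3 loop open)
# and 3HQR (closed, with the HIF-1alpha CODD substrate peptide); it is not
# part of the offline test suite.
#
# Checks that the exposed mutated residues 203, 254, 291 and 371 form a
# single surface patch under the default exposure (0.2 relative SASA) and
# linkage (12 A) parameters, and that this patch is disjoint from the
# CODD-peptide interface extracted from 3HQR.
#
# Usage: Rscript scripts/integration_pdb.R [workdir]

suppressMessages(library(phd2screen))

workdir <- commandArgs(trailingOnly = TRUE)
workdir <- if (length(workdir)) workdir[1] else tempdir()
fetch <- function(id) {
  dest <- file.path(workdir, paste0(id, ".pdb"))
  if (!file.exists(dest))
    utils::download.file(sprintf("https://files.rcsb.org/download/%s.pdb", id),
                         dest, quiet = TRUE)
  dest
}

open_model <- read_structure(fetch("3HQU"))
closed_model <- read_structure(fetch("3HQR"))

# receptor chain = PHD2; the CODD peptide is the shorter chain of 3HQR
chains <- table(closed_model$chain)
peptide_chain <- names(chains)[which.min(chains)]
iface <- interface_residues(closed_model, peptide_chain, cutoff = 5.0)
cat(sprintf("CODD interface (3HQR, chain %s): %d residues\n",
            peptide_chain, nrow(iface)))

sasa <- compute_sasa(open_model)
positions <- c(203L, 254L, 291L, 371L)
patch <- cluster_exposed_patch(open_model, positions, sasa,
                               exposure_min = 0.2, link_cutoff = 12,
                               interface = iface$resno)
print(patch)
stopifnot(length(patch$clusters) == 1L,
          setequal(patch$clusters[[1]], setdiff(positions, patch$buried)),
          length(patch$overlap[[1]]) == 0L)
cat("single exposed patch, disjoint from the substrate interface: OK\n")
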