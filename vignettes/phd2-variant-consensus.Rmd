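---
title: "Consensus classification and surface mapping of PHD2 variants: methods and design"
author: "phd2screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus classification and surface mapping of PHD2 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phd2screen)
```

## Scope and model

PHD2 (EGLN1, 426 residues) is the oxygen sensor that hydroxylates HIF-1α
and thereby licenses its degradation. The protein splits into a long
intrinsically disordered N-terminal region (residues 1–187), the catalytic
oxygenase domain (188–418) and a short C-terminal tail (419–426) carrying a
putative PDZ-binding motif. Variants reported in polycythemic patients
scatter across all three regions, and the package's task is to triage them:
combine the printed outputs of eight in-silico predictors with conservation
and structural context into one of four verdicts, and characterize the
spatial arrangement of the mutated residues on the structure — in
particular whether exposed mutated positions co-locate into a surface patch
away from the substrate-binding site, the signature of a perturbed
non-catalytic interface.

The package deliberately does **not** run any external predictor: their
outputs are inputs, read from a TSV in the shape of the published evidence
table. Disorder/secondary-structure prediction, homology modelling of
mutants, electrostatics and ab-initio modelling of the LIMD1 partner are
out of scope.

## Vote normalization

Each tool's heterogeneous output is reduced to a single deleterious /
neutral / missing vote (`normalize_and_count()`):

| tool | deleterious when | notes |
|---|---|---|
| SNAP | `Non-Neutral` | |
| Pmut | `Pathological` | |
| SNPs3D | score < 0 | the tool's own sign convention |
| I-Mutant3.0 | direction `Decrease` | the 0–10 reliability index is recorded but does not gate the vote — reported vote counts in the source table include low-reliability calls |
| PolyPhen | label ≠ `Benign`; score ≥ 0.5 when only a score is present | the categorical label wins over the score |
| Eris / FoldX / NeEMO | ΔΔG > 0 kcal/mol | positive = destabilizing, configurable per tool |

The three sets (deleterious, neutral, missing) always partition the eight
tools; `NA` and empty cells mean missing. Normalization is monotone in each
ΔΔG: raising a value can only move the tool toward deleterious.

## The consensus cascade

`classify_variant()` applies six rules in priority order; exactly one
fires, and the verdict records which. The cascade operationalizes a
multi-line-of-evidence policy — predictors, conservation and structural
analysis must align for the stronger calls:

1. **no predictor data** (nonsense variant or all tools missing) →
   Ambiguous. A truncation's impact is not measurable by missense
   predictors, so the pipeline refuses to over-claim.
2. **unanimous neutral** (zero deleterious votes) → Likely Neutral.
   Neutrality requires unanimity of whatever tools returned a value.
3. **full agreement** — SNAP, Pmut, SNPs3D and I-Mutant all deleterious,
   PolyPhen at *Probably damaging*, conservation *Conserved*, and at least
   `pathogenic_min` (default 6) deleterious votes → Pathogenic.
4. **stability conflict** — at least two of the four pathogenicity tools
   deleterious while all three ΔΔG values are present, stabilizing (≤ 0)
   and at least one at or below `strong_stabilization` (default
   −2 kcal/mol) → Ambiguous. Strong predicted stabilization contradicts a
   destabilization-mediated mechanism and the evidence is left unresolved.
5. **supported majority** — at least `likely_pathogenic_min` (default 3)
   deleterious votes backed by *Conserved* or by any structural flag →
   Likely Pathogenic.
6. otherwise Likely Neutral when the position is *Variable* with at most
   one deleterious vote, else Ambiguous.

The thresholds live in `rule_config()` and are documented as a calibration:
with the defaults, the packaged twelve-variant panel classifies in full
agreement with its published verdict column (3 Likely Neutral, 4 Likely
Pathogenic, 3 Pathogenic, 2 Ambiguous). Three packaged rows pin down the
boundaries: D254H fails rule 3 only on PolyPhen's *Possibly damaging*
label, which is what separates it from P317R/R371H/H374R; P200Q enters
rule 4 through Eris at −4.46 kcal/mol; K291I avoids rule 4 because its most
stabilizing value (−1.53) is weaker than the −2 cutoff, and instead earns
Likely Pathogenic from its structural annotation at a *Variable* position.
Users re-weighing evidence change `rule_config()`, not code.

Two discrepancies inside the source material were resolved in favor of the
printed verdict table: its prose calls D254H "ambiguous" where the table
prints *Likely Pathogenic*, and it lists Q157H among conserved positions
where the table marks it *Variable*. The packaged fixture follows the
table. One typographic slip (a PolyPhen score printed without its decimal
point) was transcribed as the evident 0.002. The printed claim that the
R398X truncation removes 64 C-terminal residues is not reproducible from
the numbering (426 − 397 = 29); `truncation_length()` computes the
arithmetic value.

## Conservation scoring and grading

The per-column score is

$$s = \left(1 - \frac{H(p)}{\log 20}\right) \cdot f_{\text{non-gap}}$$

with $H(p)$ the Shannon entropy of the residue frequencies over the
non-gap letters. This gives 1 for an invariant gap-free column, 0 for a
uniform spread over all 20 residues, and a proportional penalty for gaps;
an all-gap column scores 0 and is flagged. The entropy form was chosen for
transparency and testability — the original analyses used external
conservation servers whose exact formulas are not restated here, and the
grading pipeline is deliberately formula-agnostic (`conservation_profile()`
accepts any column-scoring function). Optional per-sequence weights are
supported and off by default.

Grades 1–9 come from equal-frequency (rank) binning, ties toward the lower
grade, with the degenerate all-equal profile pinned to grade 5; bands are
Variable (1–3), Average (4–6), Conserved (7–9). A Bayesian/ML grading of
the ConSurf kind is out of scope. When no alignment is supplied the
pipeline consumes precomputed bands from the evidence table directly —
this is how the packaged worked example runs.

## Geometry engine

**SASA** is Shrake–Rupley sphere sampling on a deterministic golden-spiral
lattice (default 960 points per atom, probe 1.4 Å): reproducible to the
bit for fixed parameters, within 1% of the analytic sphere for an isolated
atom and within 2% of the two-sphere spherical-cap closed form. Relative
SASA divides by tabulated Gly-X-Gly theoretical maxima; the exposure flag
defaults to relative SASA ≥ 0.2.

**Residue interaction networks** use heavy-atom minimal distances:
generic contact ≤ 5.0 Å between residues at sequence separation ≥ 2
(inter-chain pairs always eligible), hydrogen bond as donor/acceptor N/O
pairs ≤ 3.5 Å, ionic as opposite-charge side-chain N/O pairs ≤ 4.0 Å
(histidine counted positive), disulfide as SG–SG ≤ 2.5 Å. All cutoffs are
configurable. The hydrogen-bond rule exposes an angle tolerance that
defaults to pass-all because deposited crystal structures and the synthetic
fixtures carry no hydrogens; tightening it enables a coarse
donor–acceptor–antecedent angle gate. Network diffs are exact set
subtraction on (pair, type) keys, for comparing wild-type against
user-supplied mutant coordinates — the package does not model mutant
structures itself.

**Interfaces and patches.** A receptor residue is at the ligand interface
iff any heavy atom is within the cutoff (default 5 Å) of the ligand chain.
Exposed-patch analysis drops buried positions and single-linkage clusters
the rest on Cβ distances (Cα for glycine) with a 12 Å default cutoff;
"forms one spatial patch" then means "one single-linkage cluster". The
original study asserted a restricted surface area by visual inspection;
single linkage at 12 Å is this package's explicit, parameterized
operationalization of that judgement, and both knobs are exposed. The
overlap report intersects each cluster with an interface set, so "patch
disjoint from the substrate site" is a computable claim.

**Neighbor analysis** pairs query positions with catalog positions within
5 Å heavy-atom distance; sequence-adjacent pairs (|Δ| = 1) always qualify,
so the analysis degrades gracefully when a model does not resolve both side
chains. The packaged catalog carries the three cancer-annotated positions
(202, 292, 344) with their histology annotations.

**Structural flags** (`derive_structural_flags()`) implement five fixed
rules: catalytic-site membership or proximity (≤ 5 Å of the configured
iron triad 313/315/374 and 2-OG contact 254), formal charge inversion,
hydrophilic→hydrophobic change at an exposed position, proline loss, and
proximity to a disulfide. The functional-site sets ship as an editable TSV;
the β2β3 substrate-selectivity loop is configured as 236–254 (the bounds
are not printed in the source narrative, which places residues 243 and 254
inside it). Backbone torsions are computed as a utility but feed no rule.

## Synthetic data: what it does and does not emulate

The generators produce standard-format files so every stage runs through
its real reader: ideal α-helices (rise 1.5 Å, 100°/residue — used as
generic folded-chain scaffolds), residue pairs planted at exact atom–atom
distances (contact-type detection), burial cages (a shell of pseudo-atoms
at 6 Å, default 100 shell points, burying the central residue below 0.05
relative SASA), two-chain complexes with an exact interface gap, MSAs whose
per-column majority probability equals a requested conservation level, and
predictor tables realizing requested vote patterns. All are
seed-deterministic to the byte.

These fixtures validate algorithmic correctness, not biological realism:
planted geometries have idealized bond lengths and no packing context, the
MSA model draws columns independently with no phylogenetic correlation,
and synthetic vote patterns are cleaner than real predictor disagreement.
Passing tests therefore demonstrate that the machinery computes what it
claims on known ground truth — conclusions about real structures still
depend on the quality of the supplied coordinates and alignments. The one
check that requires the deposited crystal structures (the four exposed
mutated residues forming a single patch disjoint from the substrate
interface on 3HQU/3HQR) ships as a separate script
(`scripts/integration_pdb.R`) because it needs to download the two PDB
entries; the offline suite exercises the same logic on planted complexes.

## Numerical choices and degenerate inputs

* Sphere sampling is a fixed lattice, so SASA has no run-to-run variance;
  accuracy scales as expected with `n_points` (≥ 100 enforced, default 960).
* Alternate locations resolve to the highest-occupancy atom (ties to the
  alphabetically first altloc); waters and, by default, hetero-atoms and
  hydrogens are excluded on reading.
* Single-linkage clustering is `hclust`/`cutree` at the distance cutoff and
  is verified against an independent union–find on random instances.
* Equal-frequency grading uses minimum ranks, so tied scores share the
  lower grade and the maximum always grades 9; an all-equal profile is
  grade 5 by convention.
* The classifier is total: every vote/conservation/flag combination reaches
  exactly one rule, including empty evidence.
* Test problem sizes (random clustering instances ≤ 50 positions, interface
  fixtures ≤ 500 atoms, helices of a few hundred residues) were chosen so
  the brute-force oracles stay exact and the suite completes in well under
  a minute.

## Known limitations

* The consensus thresholds are calibrated to one published twelve-variant
  panel; applying the cascade to other proteins will usually require
  re-weighing via `rule_config()` and a protein-specific functional-site
  configuration.
* The entropy conservation score ignores amino-acid similarity and
  phylogenetic structure; it is a transparent stand-alone metric, not a
  reimplementation of any server's scoring.
* Hydrogen-bond detection without explicit hydrogens is distance-based and
  over-inclusive by design.
* No mmCIF input, no π–π/cation–π contact types, and no mutant-structure
  generation.
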