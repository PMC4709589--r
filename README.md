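# phd2screen

Consensus impact classification and structural surface mapping for missense
variants of PHD2 (EGLN1), the primary cellular oxygen sensor.

## The problem

PHD2 hydroxylates HIF-1α prolines using Fe(II) and 2-oxoglutarate, marking
HIF-1α for pVHL-mediated degradation. Germline PHD2 mutations are found in
patients with secondary erythrocytosis (polycythemia), yet many of these
patients keep normal EPO levels and many of the mutations lie far from the
catalytic site — suggesting that some variants act not by killing catalysis
but by disrupting a non-catalytic protein–protein interface (the LIMD1
scaffold interaction is the leading candidate). Assessing such variants
requires combining heterogeneous evidence: stability and pathogenicity
predictors disagree with each other, conservation is informative but
indirect, and structural context (burial, catalytic proximity, disulfides,
surface patches) is decisive for interpretation.

`phd2screen` packages that workflow for R users in variant-effect triage:

* **Vote normalization** — the printed outputs of eight predictors (SNAP,
  Pmut, SNPs3D, I-Mutant3.0, PolyPhen, Eris, FoldX, NeEMO) are normalized
  into deleterious/neutral/missing votes. A tool votes deleterious when:
  SNAP = Non-Neutral, Pmut = Pathological, SNPs3D score < 0, I-Mutant
  direction = Decrease, PolyPhen label ≠ Benign (score ≥ 0.5 fallback), or
  ΔΔG > 0 kcal/mol (positive = destabilizing) for the three stability tools.
* **Consensus classifier** — a six-rule priority cascade maps the vote
  summary, the ConSurf-style conservation band, and structural flags to one
  of four verdicts: *Pathogenic*, *Likely Pathogenic*, *Ambiguous*,
  *Likely Neutral*. Pathogenic demands agreement of all four
  pathogenicity-oriented tools, PolyPhen at "Probably damaging",
  a conserved position and ≥ 6 deleterious votes; a strong
  pathogenicity-vs-stability conflict (all ΔΔG ≤ 0, min ≤ −2 kcal/mol)
  is Ambiguous; Likely Neutral requires unanimity of the available tools.
* **Conservation grading** — per-column scores from an aligned FASTA MSA
  (1 − normalized Shannon entropy, gap-penalized), equal-frequency binned
  into grades 1–9 and banded Variable (1–3) / Average (4–6) / Conserved (7–9).
* **Structure layer** — Shrake–Rupley SASA with relative exposure against
  Gly-X-Gly maxima; typed residue interaction networks (generic ≤ 5 Å,
  H-bond ≤ 3.5 Å, ionic ≤ 4 Å, disulfide SG–SG ≤ 2.5 Å) and their diffs;
  substrate-interface extraction; neighbor analysis of mutated positions
  against a catalog of cancer-annotated residues; and single-linkage
  clustering of exposed positions into surface patches with an
  interface-overlap report.
* **Synthetic generators** — seed-deterministic PDB / aligned-FASTA / TSV
  fixtures (ideal helices, planted contacts at exact distances, burial
  cages, two-chain complexes, MSAs with controlled per-column conservation,
  predictor tables with planted vote patterns) so the full pipeline is
  testable offline.

The published twelve-variant polycythemia panel, its predictor evidence
table and the COSMIC-derived cancer-position catalog ship as plain-text
fixtures and drive the worked example below.

## Worked example

```r
library(phd2screen)

rep <- run_pipeline(phd2_panel_path(), phd2_evidence_path(),
                    catalog = phd2_cancer_catalog_path())
rep
#> <report> 12 variant(s) classified
#>    Pathogenic: 3 | Likely Pathogenic: 4 | Ambiguous: 2 | Likely Neutral: 3
#>  variant                region n_deleterious n_available conservation           verdict
#>    V138A n_terminal_disordered             0           5     Variable    Likely Neutral
#>    Q157H n_terminal_disordered             0           5     Variable    Likely Neutral
#>    P165S n_terminal_disordered             0           5     Variable    Likely Neutral
#>    P200Q      oxygenase_domain             4           8    Conserved         Ambiguous
#>    N203K      oxygenase_domain             5           8    Conserved Likely Pathogenic
#>    D254H      oxygenase_domain             8           8    Conserved Likely Pathogenic
#>    K291I      oxygenase_domain             3           8     Variable Likely Pathogenic
#>    P317R      oxygenase_domain             7           8    Conserved        Pathogenic
#>    R371H      oxygenase_domain             7           8    Conserved        Pathogenic
#>    H374R      oxygenase_domain             7           8    Conserved        Pathogenic
#>    R398X      oxygenase_domain             0           0         <NA>         Ambiguous
#>    K423E       c_terminal_tail             3           5    Conserved Likely Pathogenic
```

Reading the table: `n_deleterious / n_available` is the normalized vote —
N203K's 5/8 means five of the eight tools that returned a value call the
change deleterious. P200Q lands in *Ambiguous* because its pathogenicity
tools vote deleterious while all three ΔΔG values are stabilizing (Eris
−4.46 kcal/mol trips the strong-conflict rule). D254H stops at *Likely
Pathogenic* despite an 8/8 vote because PolyPhen rates it only "Possibly
damaging". R398X (nonsense) has no predictor output and is *Ambiguous* by
the no-evidence rule; `truncation_length(parse_variant("R398X"), 426)`
reports the 29 residues lost, which removes the C-terminal tail (419–426)
carrying a putative PDZ-binding motif.

Each verdict carries its trail:

```r
rep$verdicts$P200Q
#> <verdict> Ambiguous [stability_conflict] 3 pathogenicity tools deleterious
#>           but all ddG stabilizing (min -4.46 kcal/mol)
```

Structure-level analyses run on any PDB file; synthetic fixtures make the
geometry reproducible offline:

```r
pdb <- make_structure_fixture(fixture_spec("planted-contacts", pairs = list(
  list(res1 = "CYS", res2 = "CYS", atom1 = "SG", atom2 = "SG",
       distance = 2.04, resno1 = 201, resno2 = 208))))
build_rin(read_structure(pdb))
#>   chain1 resno1 chain2 resno2            type distance
#> 1      A    201      A    208 generic-contact     2.04
#> 2      A    201      A    208       disulfide     2.04
```

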