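# paleoprot

Maximum-likelihood ancestral protein reconstruction with robustness
("AltAll") analysis, focal-branch substitution screening, and
structure-based ligand-pocket measurement — the computational core of
studies that ask how a protein's function changed along a specific branch
of its phylogeny (for example, how a hormone receptor's ligand-dependent
switch degraded into a constitutively active one with an occluded pocket).

The package is aimed at molecular-evolution researchers who have a protein
alignment, a tree with branch lengths, and optionally atomic structures,
and who want one tested toolchain for:

* **Ancestral reconstruction** — Felsenstein pruning under JTT (or any
  symmetric exchangeability table) with observed amino-acid frequencies,
  discrete-gamma rate variation and an invariant-sites class; ML fitting of
  α and p_inv; empirical-Bayes marginal posteriors at any internal node,
  addressed by its descendant leaves. Per-site posteriors `PP`, the ML
  sequence (argmax, alphabetical tie-break), the **AltAll** sequence
  (runner-up state wherever its `PP > 0.25`), and summary statistics.
* **Branch analysis** — every replacement `aNX` between two reconstructed
  ancestors, a descendant-conservation filter ("all or all but one"),
  residue numbering in a reference sequence (with `415+2`-style anchors at
  reference gaps), and percent identity under three explicit denominator
  conventions.
* **Structure analysis** — PDB input (altloc- and water-aware), Kabsch
  superposition RMSD over CA/backbone/all-common atoms, probe-occupied
  cavity volume on a grid (probe 1.4 Å, flood-filled solvent, mean ± sd
  over 10 randomized orientations), pocket-lining residues, and per-
  candidate pocket-proximity flags.
* **Synthetic data** — alignments evolved under the exact inference model
  with all ancestral states recorded, and hollow-shell toy structures with
  analytically known cavity volume (4/3·π·r³), so every stage is testable
  offline against ground truth.

The core model: a reversible generator `Q_ij = S_ij π_j` (rows summing to
zero, scaled to one expected substitution per site per unit length),
`P(t) = exp(Qt)` via the cached spectral decomposition of
`Π^{1/2} Q Π^{-1/2}`, and a `(k+1)`-class rate mixture with gamma rates
rescaled by `1/(1−p_inv)` so the mean rate is exactly 1. See
`vignettes/methods.Rmd` for the full account.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
committed synthetic dataset (16-taxon balanced tree, 2000 sites, JTT+Γ4
with α = 0.7, seed 42). Running them in order prints:

```
$ Rscript analysis/02_ancestral_reconstruction.R
Focal branch: ancestor of ABCDEFGH -> ancestor of EFGH
AncAll8: mean ML PP 0.977, 38 of 2000 sites ambiguous (runner-up PP > 0.25)
AncSub4: mean ML PP 0.990, 21 of 2000 sites ambiguous (runner-up PP > 0.25)
AncAll8: ML sequence matches truth at 97.9% of sites
AncSub4: ML sequence matches truth at 99.4% of sites
Fitted gamma shape 0.696 (true 0.7), p_inv 0.006 (true 0), logL -29092.1

$ Rscript analysis/03_branch_substitutions.R
Inferred replacements on the focal branch: 228
Retained by the all-but-one conservation filter: 167
True replacements on that branch: 230
Exact event recovery: 85.2%; column-level: 92.2%

$ Rscript analysis/04_structure_cavities.R
Open shell cavity: 270.6 +/- 0.8 A^3 (analytic 268.08, error 0.92%)
Occluded shell cavity: 18.4 A^3 (upper bound 207.4)
Pocket-lining pseudo-residues found: 1192 (decoys flagged: 0)
Candidate at wall residue 1: distance 3.59 A, proximal TRUE
Candidate at decoy residue 1226: distance 32.98 A, proximal FALSE
```

Reading these: the fitted gamma shape lands within 1% of the generating
value; the reconstructed root-adjacent ancestor matches the recorded true
sequence at 97.9% of sites, and its mean posterior (0.977) tracks that
realized accuracy — the calibration property the AltAll robustness control
relies on. On the structural side, the measured cavity of the analytic
shell is within 1% of the closed-form volume, filler atoms shrink it (an
occluded pocket), and only true wall residues — never the distant decoys —
are reported as pocket-lining or pocket-proximal.

The same machinery runs on real data by pointing a YAML config at your
alignment/tree/PDB files and calling `run_evolution_pipeline()` /
`run_structure_pipeline()`; every run writes a manifest with versions,
seeds, parameters and input checksums from which the outputs are
re-derivable.

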