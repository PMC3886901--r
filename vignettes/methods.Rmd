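---
title: "Methods: ancestral reconstruction and ligand-pocket analysis"
author: "paleoprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral reconstruction and ligand-pocket analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Nuclear receptors are allosteric switches: a hormone bound in an internal
cavity of the ligand-binding domain (LBD) stabilises the transcriptionally
active conformation. In some lineages this regulation has been lost — the
receptor is constitutively active and its ligand pocket is occluded by bulky
side chains. Dissecting how such a shift evolved combines two kinds of
inference that this package implements as one tested pipeline:

1. **Evolutionary**: reconstruct ancestral protein sequences on a phylogeny
   by maximum likelihood, quantify the reconstruction's robustness, and
   enumerate the amino-acid replacements on the branch where the function
   changed, filtered by conservation in the descendant clade.
2. **Structural**: measure the probe-occupied volume of the ligand cavity in
   atomic structures, superpose structures to compare them, identify
   pocket-lining residues, and flag which candidate replacements sit close
   to the pocket.

Because the original data (large curated alignments, crystal structures)
are external, the package also ships a first-class synthetic-data module:
alignments evolved under the exact inference model with all ancestral
states recorded, and toy structures whose cavity volume is known in closed
form. Every stage is therefore testable offline against ground truth.

## Substitution model

Sequences evolve by a reversible continuous-time Markov chain on the 20
amino acids. The generator is built from an empirical exchangeability
matrix $S$ (the Jones–Taylor–Thornton table, bundled as a plain-text data
file) and equilibrium frequencies $\pi$:

$$Q_{ij} = S_{ij}\,\pi_j \;(i \neq j), \qquad
  Q_{ii} = -\sum_{j \neq i} Q_{ij},$$

rescaled so $-\sum_i \pi_i Q_{ii} = 1$; branch lengths are then expected
substitutions per site. Frequencies may be the table's own, an explicit
vector, or observed from the alignment; observed counts get one pseudocount
per amino acid so no frequency is zero (a zero frequency would break the
reversible construction; at realistic alignment sizes the pseudocount is
negligible). Transition matrices $P(t) = e^{Qt}$ are computed through the
symmetrised generator $B = \Pi^{1/2} Q \Pi^{-1/2}$, whose eigendecomposition
is cached per model — numerically stable for reversible generators and fast
for the many branch evaluations optimisation needs.

Rate variation across sites uses the standard discrete-gamma approximation:
$k$ equal-probability categories of the mean-one gamma$(\alpha,\alpha)$
density, each represented by its conditional mean (computed in closed form
from the incomplete-gamma identity), with $k = 4$ by default — the de facto
standard and the smallest $k$ with accepted accuracy; $k$ is configurable.
An invariant-sites class of weight $p_\mathrm{inv}$ at rate 0 is mixed in
and the gamma rates are rescaled by $1/(1-p_\mathrm{inv})$, so the grand
mean rate stays exactly 1 and branch lengths keep their units.

## Likelihood, optimisation and ancestral reconstruction

The alignment likelihood is computed by Felsenstein pruning, vectorised
over compressed site patterns, with per-node rescaling and accumulated log
scalers to prevent underflow on large trees. Gaps and ambiguity codes at
leaves are missing data (all-ones conditional vectors). The peeling routine
works on the tree as an undirected graph rooted at an arbitrary vertex;
under a reversible model the total likelihood is root-invariant (tested),
and marginal posteriors at a node are obtained by peeling *toward* that
node and multiplying by $\pi$ — the empirical-Bayes marginal
reconstruction. The rate mixture enters both computations by weighting each
class's contribution; the invariant class has a closed form (a site is
compatible only if all observed leaves agree).

Free parameters ($\alpha$, $p_\mathrm{inv}$, optionally each branch length)
are fitted by coordinate-wise bounded Brent search
($\alpha \in [0.01, 100]$ on a log scale, $p_\mathrm{inv} \in [0, 0.99]$),
sweeping until the log-likelihood gain drops below $10^{-4}$. This is
derivative-free and robust at the problem sizes the package targets;
non-convergence returns the best-so-far fit with a flagged report rather
than an error.

From the per-site posterior matrix three sequences derive:

* **ML sequence** — per-site argmax; exact ties resolve to the state
  earlier in the canonical alphabetical order, so outputs are
  deterministic.
* **AltAll sequence** — the "worst plausible" ancestor: wherever the
  runner-up state's posterior exceeds a threshold (default 0.25, strict),
  it replaces the ML state. Synthesising this variant bounds the
  sensitivity of downstream conclusions to reconstruction uncertainty.
* **Summaries** — mean ML posterior and the count of ambiguous sites,
  over all columns or a subset (e.g. pocket-lining positions).

Ancestral gap states are not inferred (indel reconstruction is out of
scope); instead every column is reported with the fraction of gapped
leaves, so indel-dominated columns can be masked downstream. Internal
nodes are addressed by the sorted set of descendant leaf names, which is
stable across serialisations of the same rooted tree.

## Branch substitution analysis

Replacements between two reconstructed ancestors are enumerated per
alignment column; columns where either ancestor is gapped or ambiguous are
excluded from events and counted separately, since their history is
indel-confounded. The descendant-conservation filter retains an event when
at most `max_exceptions` (default 1 — "all or all but one") descendant
sequences carry a canonical state different from the derived state; gapped
descendants are not counted as exceptions, because a missing residue is not
evidence against conservation — the per-event tallies expose gap counts so
the stricter reading can be audited. Sites map to a reference numbering
(e.g. the human ER$\alpha$ sequence) by walking the reference row of the
alignment; columns gapped in the reference get a nearest-anchor annotation
such as `415+2` instead of a number. Pairwise identity is reported under
all three denominator conventions (both-ungapped, either-ungapped,
alignment-length) with the convention recorded in the output, because
published identity figures rarely state theirs; the pipeline default is
both-ungapped.

## Cavity volumes on a grid

The probe-occupied cavity volume follows the classic grid approach: lay a
cubic grid (default spacing $h$ = 0.5 Å, padding twice the largest inflated
radius) over the structure; mark a voxel *probe-accessible* when a probe
sphere (default radius 1.4 Å, water-sized) centred there overlaps no atom's
van der Waals sphere (Bondi-type heavy-atom radii bundled in code; an
optional united-atom inflation compensates for missing hydrogens);
flood-fill accessibility from the box boundary to identify bulk solvent;
the remaining accessible components are interior cavities. One cavity is
selected — the largest, or the one nearest a user-supplied seed point (so
"the ligand pocket" need not be the largest void) — and its volume is
reported under one of two conventions:

* **probe-center**: the accessible voxel volume itself;
* **probe-occupied** (default): the accessible region dilated by the probe
  radius and clipped by the vdW spheres — the region a water-sized probe
  can physically occupy.

The accessible region is continuous but sampled at voxel centres, so the
dilation radius carries a sub-voxel correction: interior accessible voxels
(all six neighbours accessible) dilate by probe + $h\sqrt{3}/2$ (any point
of such a voxel is an admissible probe centre), boundary ones by probe +
$h/2$ (the true accessibility boundary lies on average halfway to the first
blocked centre). The whole computation is repeated over randomized grid
orientations (default 10; uniform rotations from seeded quaternions, the
first always the input orientation) and reported as mean ± sd — the sd
quantifies grid anisotropy. Molecular volumes (e.g. of a ligand) use the
same machinery on the union of atomic spheres.

Calibration on the analytic shell fixture (below) shows the corrected
estimator is accurate to about 1% of the closed-form volume at 0.5 Å and is
essentially converged there: successive refinements 0.5 → 0.35 → 0.25 Å
move the estimate by well under 1%. One documented consequence: the
residual ~1% offset is the *fixture's* discrete-atom geometry (a probe
slips marginally past the nominal cavity radius between finite wall atoms),
not grid error, so halving the spacing does not shrink the deviation from
the smooth-sphere closed form — the acceptance suite records this honestly
rather than hiding it, and the unit suite asserts the convergence band
instead.

Pocket-lining residues are those with any heavy side-chain atom within a
cutoff of the cavity voxel centres (glycine, having none, never qualifies);
candidate substitutions are flagged pocket-proximal when their residue's
minimum heavy-atom distance to the cavity (or to supplied ligand atoms) is
at most 5 Å by default. The cutoffs are free parameters, reported in
outputs, since published pocket definitions rarely document them.

Rigid superposition pairs residues via a global affine-gap sequence
alignment of the two chains (BLOSUM62), collects CA, backbone or
all-common atoms, and solves for the optimal proper rotation by the
Kabsch/SVD method (reflections excluded; collinear or <3-pair inputs
rejected). The RMSD is cross-checked in the test suite against an
independent structural-bioinformatics implementation.

## Synthetic data: what it emulates, and what it does not

`simulate_alignment()` draws root states from $\pi$, a rate class per site,
and child states branch-by-branch from the exact finite-time transition
matrices — the same kernel the likelihood uses, which keeps
oracle comparisons clean (no Gillespie discretisation mismatch). All
internal-node sequences, per-site classes and the seed are recorded;
replaying a seed reproduces the dataset bit-for-bit.

The committed study conditions used throughout the tests and the analysis
scripts are: a 16-taxon balanced tree with exponential branch lengths of
mean 0.1 substitutions/site (seed 42), JTT, 4-category gamma with
$\alpha = 0.7$, no invariant class, 2000 sites. These are desk-scale
stand-ins for a deep-metazoan receptor alignment: ~0.1 expected
replacements per branch per site, strong-but-imperfect reconstruction
(mean posterior ≈ 0.97 here versus ≈ 0.73 in genuinely deep problems), and
a focal branch carrying a few hundred replacements. The focal branch for
branch-analysis scoring is the root-adjacent ancestor joined to its
internal child across the *longer* of its two internal branches — the
branch carrying more change, mirroring how an empirical study focuses on
the branch where the function shifted. Event recovery on short branches is
intrinsically poor (few true events, reconstruction noise dominates), and
the analysis scripts report both exact and column-level recovery to make
that visible.

What passing these tests does *not* show about real data: the simulator
draws i.i.d. sites with no indels, no alignment error, no among-site
compositional heterogeneity, and a correct model (the inference model is
the generating model). Real reconstructions face all four, so synthetic
accuracies are upper bounds, and the package's full-scale numbers on
external datasets should be treated as approximate reproductions.

`make_toy_structure()` places carbon-like pseudo-atoms (radius 1.7 Å) on a
sphere of radius $r_\mathrm{cav} + 1.7$, so the probe-occupied interior is
analytically $\tfrac{4}{3}\pi r_\mathrm{cav}^3$. Shell point density
defaults to 3 atoms/Å² — probe-tight with a wide margin (tightness is
verified at construction by the cavity engine itself, with automatic
density escalation and a loud failure) while keeping the discrete wall
within about 1% of the ideal sphere. Filler atoms dropped inside the
cavity shrink it monotonically — the fixture-level mirror of an occluded
ligand pocket — and a distant compact decoy cluster provides residues that
must never be reported as pocket-lining.

## Pipeline and reproducibility

`run_evolution_pipeline()` and `run_structure_pipeline()` orchestrate the
stages from a single YAML configuration (paths, ancestor clades, model
settings, thresholds 0.25 / 1 / 1.4 Å / 10 orientations, seeds), write all
tables in plain formats (TSV/FASTA/JSON) and a machine-readable manifest
(package version, seeds, parameters, input checksums). Outputs are
deterministic given the config and seeds; re-runs are byte-identical except
the manifest timestamp (tested). The numbered scripts under `analysis/`
run the whole study on the synthetic fixtures and narrate what they find;
there is no shell CLI wrapper — the exported functions and these scripts
are the interface.

## Known limitations

* No indel model: gap columns are reported, not reconstructed.
* No tree search or model selection: the tree and exchangeability matrix
  are inputs.
* Joint (as opposed to marginal) ancestral reconstruction is not
  implemented.
* Cavity volumes depend on convention, radius set, grid spacing and
  cavity-selection rule; published volumes computed with other tools under
  undocumented settings should be compared only approximately, and the
  package reports its own settings alongside every number.
* The branch-length optimiser is one-branch-at-a-time Brent search —
  adequate at desk scale, not tuned for hundreds of taxa.
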