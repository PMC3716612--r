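---
title: "Methods: iterative refinement and model quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative refinement and model quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`refine3d` implements an iterative protocol for protein structure
refinement — the task of nudging a predicted model closer to its native
(experimental) structure while repairing local errors such as irregular
hydrogen bonding, steric clashes and distorted bond geometry — together
with the assessment machinery used to judge whether a refinement method
actually helps: six model-quality metrics, robust Z-score normalization
into a single overall quality score, ranking against a do-nothing
control, and Wilcoxon signed-rank significance tests.

Each refinement round is a two-step process:

1. **Hydrogen-bond network optimization.** Polar hydrogens are built at
   template geometry and a discrete, clash-penalized search optimizes
   side-chain amide/imidazole flips, the histidine tautomer, and
   hydroxyl/sulfhydryl/ammonium rotor positions.  The result is the
   *extended atomic model*.
2. **All-atom energy minimization.** The extended model is minimized with
   limited-memory BFGS under a composite force field: physics-based
   bonded terms, a harmonic tether on the C-alpha and C-beta atoms, a
   knowledge-based atomic pairwise potential of mean force (PMF), and an
   explicit hydrogen-bonding potential.

The round is repeated five times, each round starting from the previous
round's minimized model, yielding five refined models in round order.
The tether keeps backbone excursions small within a round while allowing
progressive drift toward lower energy across rounds.

# The composite energy

All energies are in kcal/mol-equivalent units, coordinates in Angstrom.

**Bonded terms.**  Harmonic bonds \(E_b = \sum k_b (b - b_0)^2\) and
angles \(E_\theta = \sum k_\theta (\theta - \theta_0)^2\), plus cosine
torsions \(E_\phi = \sum k_\phi (1 + \cos(n\phi - \delta))\).  The
equilibrium values \(b_0, \theta_0\) are standard Engh–Huber-style
geometry, generated from the same internal-coordinate templates the
synthetic peptide builder uses, so an ideal template peptide scores
essentially zero bonded energy by construction.  The exact constants of
the original Java implementation this protocol derives from are not
public; this package's parameter table is its own documented stand-in
with the same term structure, shipped in a human-editable text format
(`write_ff_params()` / `read_ff_params()`).  Torsion terms are applied
where they express real preferences that the harmonic terms cannot:
peptide-bond planarity (\(n=2\), \(\delta=\pi\), \(k=10\)) and sp3
side-chain staggering (\(n=3\), \(\delta=0\), \(k=0.2\)).  Backbone
\(\phi/\psi\) preferences are deliberately left to the knowledge-based
terms.  Defaults: \(k_b = 300\) kcal/mol/Å², \(k_\theta = 80\)
kcal/mol/rad².

**Tether.**  \(E_t = k_t \sum_{\mathrm{CA,CB}} |r - r_{\mathrm{ref}}|^2\)
with \(k_t = 1\) kcal/mol/Å² by default.  Only C-alpha and C-beta atoms
are restrained; side chains and the backbone carbonyl relax freely.

**Pairwise potential of mean force.**  A quasi-chemical construction
over coarse atom types (shared backbone N/CA/C/O/CB types plus
residue-specific side-chain element classes such as `SER:O`):

\[
e(i,j,\mathrm{bin}) = -\ln
\frac{N_{\mathrm{obs}}(i,j,\mathrm{bin}) + \alpha}
     {N_{\mathrm{exp}}(i,j,\mathrm{bin}) + \alpha},
\]

where the expectation comes from the distance-only marginal (a
type-independent reference state) and \(\alpha = 1\) is a pseudocount
that keeps sparse statistics stable.  Distances are binned at 0.5 Å on
[2, 10] Å.  Values are interpolated per type pair with a single natural
cubic spline through the bin midpoints, anchored to zero at and past the
cutoff and to a repulsive value below the first bin, giving a potential
that is continuous with a continuous first derivative across all
interior bin edges and exactly zero beyond 10 Å.  Pairs within three
covalent bonds are excluded.  Neighbor search uses cubic cell lists, so
the evaluation scales linearly in atom count at fixed density.

**Hydrogen-bond potential.**  For every donor-H...acceptor triple with
H...A below 3 Å:

\[
E = -w \; e^{-(d-d_0)^2/2\sigma_d^2}
  \; \max(0, -\cos\theta_{DHA})^p
  \; \max(0, \cos(\theta_{HAB} - \theta_{\mathrm{off}}))^q,
\]

with defaults \(d_0 = 2.0\) Å, \(\sigma_d = 0.3\) Å, \(p = q = 2\),
\(\theta_{\mathrm{off}} = 120^\circ\) (the ideal approach angle at an
sp2 acceptor) and well depth \(w = 2\), optionally modulated by the
secondary-structure state of the donor residue.  The cited protocol uses
an explicit hydrogen-bonding term whose functional form is not published;
this Gaussian-distance times clamped-cosine-power form is this package's
concrete choice.  The hard 3 Å evaluation cap introduces a discontinuity
of order \(10^{-2}\) at the cap (the Gaussian is already tiny there);
the minimizer's line search tolerates it in practice.

All gradients are analytic and validated against central finite
differences (max relative error below \(10^{-4}\) at \(h = 10^{-5}\) Å;
in practice around \(10^{-9}\)).

# Secondary structure

Some energy terms can weight hydrogen bonds by secondary-structure
state, so the package assigns 3-state secondary structure internally
using the Kabsch–Sander electrostatic criterion (backbone H-bond energy
below −0.5 kcal/mol; two consecutive i→i+4 turns make helix, bridges
make strand).  A DSSP output file can be supplied instead and is used
verbatim; the internal assigner exists so the package has no mandatory
external-binary dependency.

# Minimization and iteration

L-BFGS is provided by `stats::optim(method = "L-BFGS-B")`, whose line
search satisfies the strong Wolfe conditions, with memory 10.  The
nominal step budget is 200,000 per round; "convergence to machine
precision" is operationalized as a relative energy change below
\(10^{-12}\) or a projected-gradient infinity norm below \(10^{-8}\) —
literal machine-epsilon tests are line-search-unstable.  Each round
re-assigns secondary structure, rebuilds and re-optimizes the hydrogen
network, and re-tethers to its own starting coordinates
(`tether_reference_policy = "per_round_input"`, the default).  The
alternative `"original_start"` policy restrains every round to the
original input; both are implemented because the source protocol does
not state which reference the tether uses, and `per_round_input` is the
default because it is what makes the iteration meaningful — each round
may drift a little further toward a lower minimum.

Emitted models are stripped of hydrogens for submission-format parity
(configurable), and model rank equals round order.

# Quality metrics

All metrics pair atoms by (chain, residue number, atom name) and error
out on sequence mismatches; no terminus trimming is applied.

- **RMSD** — single Kabsch least-squares superposition of paired
  C-alpha atoms, reflections excluded; no distance cutoff.
- **GDT-TS** — mean over cutoffs {1, 2, 4, 8} Å of the maximal fraction
  of C-alpha pairs within the cutoff, maximized over superpositions
  seeded from contiguous 3/5/7-residue windows (plus the global fit) and
  iteratively refit on the within-cutoff subset (≤ 20 rounds).  Reported
  on [0, 1].
- **GDC-SC** — the same machinery on one characteristic atom near the
  end of each side chain (GLY excluded), with ten thresholds
  \(c_k = 0.5k\) Å and linearly decreasing weights
  \(w_k \propto 11 - k\).  The cited side-chain score's exact thresholds
  and weights are not reproduced in the source; this scheme is the
  package's documented choice matching its description.
- **SphereGrinder** — for each residue, all reference atoms within 6 Å
  of its reference C-alpha form a sphere; the score averages the
  fractions of residues whose per-sphere all-atom RMSD (after per-sphere
  superposition) is below 2 Å and below 4 Å.
- **CAD-AA** — residue-pair contact areas computed by sampling each
  atom's solvent-extended sphere (vdW + 1.4 Å) at 256 deterministic
  Fibonacci points, assigning each point to the neighbor whose extended
  sphere it penetrates deepest; the score is one minus the bounded,
  normalized total area difference over the reference's contacting
  pairs.  Sampling rather than exact Voronoi tessellation keeps the
  implementation dependency-free; a dense-sampling oracle (10^5
  points/atom) guards its accuracy to within 2% in the tests.
- **MP-proxy** — explicitly *not* MolProbity: a clash score (severe
  overlaps per 1000 atoms), rotamer outliers (chi-1 further than 40°
  from staggered) and a coarse Ramachandran-favored fraction combined
  with the published MolProbity combination constants.  A clash-free
  helix with favored backbone and rotamers scores exactly 0.5.  It is
  labelled MP-proxy in every report.

# Normalization, ranking and significance

For each metric, the refinement delta is \(\delta_Q = Q(r) - Q(s)\)
(refined minus starting score).  Because lower RMSD and MP-proxy mean
better models, deltas of those two metrics are negated before pooling so
that positive always means improvement; the source never states how
lower-is-better metrics enter the pooled score, and without this
orientation an RMSD improvement would *lower* the overall score,
contradicting the ranking it is meant to support.  Raw deltas are
reported alongside.

Per target and metric, deltas are pooled across groups (one model per
group per target, either the first or the best submission), the
do-nothing pseudo-group **Void** (all deltas zero) is injected, and each
group gets a robust Z-score
\(Z = (\delta - \mathrm{median}) / (1.486 \cdot \mathrm{MAD})\); 1.486
scales the MAD to a normal standard deviation (verified on 10^6 draws in
the acceptance checks).  A degenerate pool (MAD = 0) yields all-zero
Z-scores rather than infinities.  The overall quality score is the
weighted Z average with GDT-TS carrying weight 5 and the other five
metrics weight 1 — half the total weight on backbone accuracy — and
groups are ranked by the sum of overall scores across targets; a group
missing a target simply lacks that term.  Group-level significance uses
the two-sided Wilcoxon signed-rank test against zero with zeros dropped
(the Pratt variant is available), an exact enumeration null for n ≤ 20
(valid under mid-ranked ties) and the tie-corrected normal approximation
above.

When a group's "best" model must be chosen without re-pooling across
groups, candidates within the group are ranked by the same weighted
average applied to their oriented deltas; ties go to the lower model
rank.

# Synthetic data

The generator builds idealized peptides from internal coordinates
(helix \(\phi/\psi = -57/-47\), strand \(-119/113\), helix–loop–helix
with an extended linker) over a 13-residue-type builder set with a
minimal 1–3-rotamer library, then perturbs them in a fixed, replayable
order: segment rigid shift, per-atom Gaussian noise, side-chain rotamer
scrambling, discrete amide/ring flips, clash injection.  Defaults
(noise SD 0.3–0.45 Å, 20–30% side-chain scrambling, occasional clash)
produce starting models whose GDT-TS/RMSD spread is in the same broad
regime as real refinement targets (roughly GDT-TS 0.55–0.95).
Assessment scenarios plant a skill gradient: each group's models move a
skill-dependent fraction of the way from the start toward the native
(plus 0.03 Å noise), and a zero-skill group reproduces the start
exactly, so ground truth for ranking is known.  Everything is
deterministic under the supplied seed.

What the generator does *not* emulate: real homology-model error
profiles (correlated, template-driven), loop modeling failures, register
shifts, or the size of real targets.  Passing the planted-gradient tests
shows the ranking machinery orders known skill correctly; it does not
certify performance on real predictions.

# Numerical choices and limitations

- Problem sizes in the test and acceptance runs (8–20-residue peptides,
  20 decoy/scenario seeds, step caps of 150–200 L-BFGS iterations) were
  chosen as the smallest sizes that still exercise every code path
  meaningfully; all are configurable upward.
- Discrete network search: clusters are solved exhaustively when they
  have at most 6 variables *and* at most 2048 joint states (three
  12-position rotors qualify; six do not), otherwise by greedy descent
  with 3 seeded random restarts.  The objective adds a clash penalty
  \(\sum \max(0, 0.8 (r_i + r_j) - d)^2\) over moved atoms so the
  search cannot manufacture clashes.  The input state is always a
  candidate, so the objective never increases.
- Missing atoms: refinement refuses models missing backbone N/CA/C;
  missing side-chain atoms are tolerated and terms referencing them are
  skipped.  HETATM records and waters are excluded by default.
- The peptide builder covers 13 residue types; unsupported types are
  substituted by alanine with a warning.  Reading, refining and scoring
  arbitrary PDB files covers all 20 standard residues.
- Angle-table fallbacks for triples outside the named tables use
  120°/109.47° by hybridization; ideal peptides therefore carry a
  residual bonded energy of order 0.01–0.05 rather than exactly zero.
- The PMF derived from a handful of idealized peptides is statistically
  thin; it provides a generic packing/repulsion signal for fixtures, not
  a production statistical potential.  Tables derived from larger
  structure sets can be dropped in via `read_pmf_table()`.
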