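---
title: "Modelling doughnut-like domain-swapped oligomers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling doughnut-like domain-swapped oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringswap)
```

## The modelling problem

Disulfide-stabilized human cystatin C forms closed, approximately flat rings of
10–12 subunits. Three experimental techniques constrain their shape: TEM gives
outer diameters of 16–24 nm and an annulus width of 5–6 nm; AFM gives heights
of 1.6–2.5 nm (its lateral distances are uncalibrated and not used); SAXS
Guinier analysis gives a radius of gyration, and parameterizing the ring as a
flattened annulus gives outer diameter 20–23 nm, width 7–8 nm and height
2.4–2.6 nm. Biochemistry (loss of papain inhibition, retained legumain
inhibition) indicates the subunits are connected by the same 1–58 domain swap
seen in the crystalline dimer.

`ringswap` reproduces the desk-side part of that modelling chain: propose
candidate C~n~ rings, measure their doughnut geometry, keep only candidates
inside the experimental intervals, rewire chains with the cyclic domain swap,
and score structures/trajectories with the standard stability metrics. The
force-field stages of the original workflow (restrained all-atom MD,
coarse-grained dynamics) are out of scope; their role here is played by
explicit, seeded synthetic trajectories with known ground truth.

## Ring construction

A candidate ring is `n` rigid copies of the subunit. The subunit is centred on
its centroid, oriented by three angles — tilt (about the local tangential
axis), spin (about the local radial axis) and twist (about the vertical axis
through the centroid; tilt/spin/twist names are conventional, and these three
axes are the independent ones a C~n~ placer needs) — translated `ringRadius` Å
from the axis, and replicated by rotations of 2π/n about z. Symmetry is exact
at build time (transforms
are composed analytically, not fitted); assemblies loaded from disk make no
axis assumption — geometry measurement recovers the axis as the
smallest-spread principal axis of the coordinates.

The original study obtained candidate geometries from a symmetry-docking
search and then screened them *manually* against the experimental dimensions.
Because the published selection criterion is purely geometric, the package
replaces the docking stage with a transparent, deterministic grid over ring
radius and orientation (`enumerateCandidates`); docking energetics are not
reimplemented. Steric plausibility is tracked by counting inter-chain CA pairs
closer than 2 Å (default); clashes flag a candidate but never remove it —
dimensional filtering is a separate, explicit step. The published grouping of
100 docking poses into five subfamilies was manual, with no reproducible rule,
and is deliberately not implemented.

## The cyclic domain swap

`applyCyclicSwap` transfers residues 1–58 of each chain to its cyclic
successor (direction is a flag; the experiment does not distinguish
handedness). The operation is a pure relabeling: the coordinate multiset is
conserved bitwise, every composite chain has exactly the monomer sequence, and
the swap's n-th power is the identity. In the original workflow the broken
58–59 junction was subsequently relaxed by restrained MD with no bonds imposed
around the junction; since MD is out of scope, the package instead *reports*
the C(58)–N(59) distance per composite chain (`junctionReport`) as an honest
strain metric (an intact peptide bond is ~1.33 Å; a freshly relabeled ring
shows tens of Å).

Crystallographically missing segments (the monomer entry lacks residues 78–79)
are rebuilt with N, CA, C, O and CB atoms. The CA path follows the straight
line between flanking anchors when that yields steps in the physical 2.8–4.2 Å
band; for short anchor separations a straight line would compress steps below
2.8 Å, so the path becomes a circular arc with ~3.8 Å steps bulging away from
the structure centroid. (A purely linear interpolation cannot satisfy the step
bound for a 2-residue gap between helix anchors ~5 Å apart; the arc keeps the
bound while passing through the same anchors.)

## Geometry, units, and the "inner diameter" ambiguity

Internally everything is Å; ring dimensions are reported in nm through one
conversion boundary. The experimental tables use "inner diameter" for the
distance between the cavity edge and the ring's outer edge — an annulus
*width* — while common usage means the cavity diameter. The package never uses
the phrase: `RingGeometry` carries `cavityDiameter` (2 × minimal radial
distance of heavy atoms) and `ringWidth` = (outer − cavity)/2 separately.
Hydrogens are excluded from all dimension measurements (the experimental
dimensions exclude the hydration shell; crystal coordinates have no protons).
Default constraint intervals: TEM outer 16–24 nm and width 5–6 nm, AFM height
1.6–2.5 nm, SAXS outer 20–23 nm, width 7–8 nm, height 2.4–2.6 nm; rows are
selectable, bounds inclusive, and selected rows are intersected (asking for
TEM ∩ SAXS width errors, because 5–6 and 7–8 nm are disjoint — the two
techniques genuinely disagree on this number).

The mass-weighted coordinate R~g~ uses standard atomic masses (a uniform-mass
switch serves bead models). For a uniform annular cylinder the closed form is
R~g~² = (R~in~² + R~out~²)/2 + h²/12, which the tests verify against ≥10⁶-point
Monte-Carlo volume integration to 0.5% including the hoop (R~in~ = R~out~,
h = 0) and disc (R~in~ = 0) limits. For the doughnut defined by the SAXS
dimensions (R~out~ 10.75, R~in~ 3.25, h 2.5 nm) this gives 7.97 nm. That value
is not reconcilable with the measured Guinier R~g~ of 5.28 nm under this shape
model; the original analysis used an external "universal R~g~ calculator"
whose parameterization is not public, so neither number is treated as ground
truth for the other — the package reports both and leaves the discrepancy
visible.

## SAXS: Debye curves and Guinier fitting

`debyeIntensity` evaluates I(s) = ΣᵢΣⱼ fᵢfⱼ sinc(s·rᵢⱼ) over a bead model
(sinc gets a series branch below 10⁻⁸ to avoid 0/0), with s = 4π sin θ/λ in
nm⁻¹. `guinierFit` regresses ln I on s² and reports R~g~ = √(−3·slope), with
the window chosen iteratively: starting from the points whose intensity is
still within the Guinier-model decay at s·R~g~ = 1.3 (a noise-robust seed),
the ceiling is reset to 1.3/R~g~ and the fit repeated to a fixed point (≤20
iterations; an oscillating window is reported with `converged = FALSE`, not an
error). Weights are (I/σ)² when uncertainties are present, otherwise the fit
is unweighted — whether the original fit was σ-weighted is unstated, so the
conventional default is documented rather than asserted. At R~g~ = 5.28 nm the
ceiling is 1.3/5.28 ≈ 0.246 nm⁻¹, matching the upper end of the fit range used
in the original analysis (printed as 0.247 nm⁻¹).

One numerical caveat: for an exact homogeneous-sphere curve the Guinier model
itself is biased at s·R~g~ = 1.3 (the fitted R~g~ comes out ~1.8% above
√(3/5)·R, independent of weighting or grid density). The sphere oracle test
therefore fits a conservative window (s·R~g~ ≤ 0.8, bias ~0.7%), while the
1.3 rule is validated on exact Guinier-model curves where it is bias-free.

## Stability metrics

*Kabsch superposition* is the closed-form SVD solution restricted to proper
rotations (determinant correction); tests compare it against an independent
rotation-space search (coarse rotation-vector grid plus coordinate-descent
refinement). *RMSD series* superpose each frame onto a reference over a
selection (CA by default). *TM-score* uses d₀ = 1.24(L−15)^⅓ − 1.8 with L the
reference length, maximized by the conventional heuristic (seed fragments of
lengths L, L/2, L/4 at multiple offsets; include residues within a cutoff
starting at 8 Å and halving to d₀; re-superpose to a fixed point; keep the
best). Note that the score-optimal superposition is not the RMSD-optimal one:
on a configuration where every residue is displaced by exactly d₀ and the
least-squares superposition is the identity, the plug-in score is exactly 0.5,
but maximizing over superpositions legitimately yields slightly more (~0.57) by
sacrificing a few residues. `tmScore(..., optimize = FALSE)` exposes the
plug-in score at the Kabsch superposition for exactly this kind of analysis.

*Hydrogen-bond occupancy* counts frames where the donor–acceptor heavy-atom
distance is ≤ 3.5 Å and the donor–H–acceptor angle ≥ 120° (both configurable;
the thresholds used by the original trajectory analysis are unstated, so these
common MD-analysis defaults are documented, not asserted as theirs). Amide
hydrogens absent from the coordinates are constructed at 1.01 Å along the
bisector-opposed direction from N, per frame.

*Secondary structure* uses Kabsch–Sander bonds,
E = 0.084·332·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol with a bond at
E < −0.5, and DSSP-style patterns: consecutive 4-turns → α-helix (3- and
5-turn analogues give 3₁₀/π, collapsed into H), parallel/antiparallel bridge
patterns → E, isolated turns → T, else C. The original study used the STRIDE
server, whose empirical torsion-propensity terms are not fully re-derivable;
DSSP-style assignment agrees with STRIDE on ~95% of residues, which is why
composition comparisons carry a ±3 percentage-point tolerance. Residues with
incomplete backbones are labelled C and counted.

## Synthetic data: what it emulates, and what it does not

All fixtures are pure functions of their parameters and a seed; a root seed
fans out to per-generator streams via `generatorSeed(root, name)` =
(root·10007 + Σ utf8(name)) mod (2³¹ − 1), so adding a fixture never perturbs
an existing one. Every generator stores its ground truth in the annotations.

The **toy monomer** is built from ideal internal coordinates (N–CA 1.458,
CA–C 1.525, C–N 1.329 Å; angles 111.0/117.2/121.7°; NeRF chain construction):
an α-helix block (φ, ψ = −57, −47) packed above a five-strand antiparallel
sheet (φ, ψ = −139, 135) assembled from hairpins, plus designed β-turn-like
motifs (five residues at φ, ψ = −65, −50, carrying one isolated i→i+4 bond
each — torsions chosen so the 3-turn bonds are clearly absent and the label is
a robust T), interpolated loops, and extended termini. Strand registration
(spacing 4.2 Å, alternate-strand offset 2.75 Å along the strand axis, flip
about z) was frozen from a one-off scan maximizing Kabsch–Sander bonds between
adjacent ideal strands; the register only closes for even strand lengths,
which the layouts respect. The default 120-residue layout is flat (z extent
~2.3 nm) and elongated (x extent ~5.3 nm) like a cystatin-type subunit, so
rings built from it have realistic doughnut dimensions, and its designed
composition mirrors the monomer crystal structure (~17% helix, ~45% sheet,
~27% coil). Its R~g~ (~1.7 nm) reflects that elongation. A small coordinate
jitter (σ = 0.01 Å) makes seeds distinguishable without perturbing any
hydrogen bond.

Because the reference crystal structures cannot be redistributed with the
package, `makeSyntheticCystatinMonomer` and `makeSyntheticCystatinDimer` are
offered as *clearly synthetic* stand-ins whose designed composition follows
the published secondary-structure table (dimer: ~18% helix, ~36% sheet per
chain, four strands). Regression tests against the published composition
therefore validate that the assignment machinery recovers a designed
composition from raw coordinates — they are not a re-measurement of the
crystal structures themselves. Likewise the synthetic trajectories (rigid
motion + Gaussian noise + scheduled hydrogen-bond geometry) validate the
metric implementations; they say nothing about the dynamics of real oligomers,
and the published trajectory-scale observables (RMSD drifts, TM-scores at
specific temperatures, occupancy percentages) are not reproduced here because
they require the original multi-microsecond trajectories.

Design-truth agreement is asserted on segment interiors (residues more than
one position from a designed-segment boundary, ≥90%): assignment schemes
lose 1–2 residues at every element boundary by construction (a 4-turn pattern
cannot mark the first and last helix residue), so boundary residues are where
any two schemes disagree.

## Numerical and interface choices

- Alternate locations: altloc 'A' or blank kept, others discarded.
- Author residue numbering is never re-indexed, so the literature's residue
  references (58/59 junction, 47–69 disulfide, 78–79 gap) stay literal.
- `buildRing` chain ids are A, B, C, … in angular order; rings above 62 chains
  are rejected (PDB chain-id alphabet).
- The cavity diameter of a bead model is measured from the sampled centroid;
  with N beads its sampling error (~R~g~/√N per axis) dominates the bead-grid
  resolution, hence the looser tolerance on that one dimension in tests.
- Degenerate inputs: a single point has all-zero ring geometry; empty
  coordinate sets, non-positive masses, gaps at chain termini, single-chain
  swaps, and negative s values are explicit errors.
- Problem sizes used in the validation suite: 120-residue subunits, rings of
  10–12 subunits (~7,200 atoms), 50-frame trajectories, 10⁵–10⁶-point
  Monte-Carlo integrations, 100-replicate noise ensembles — sizes at which
  every property under test is already stable.

## Known limitations

- No energetics anywhere: candidate generation is geometric, the swap is a
  relabeling, and junction strain is reported, not relaxed.
- The Guinier window rule assumes a monotone low-angle decay; curves whose
  window oscillates are flagged rather than resolved.
- The secondary-structure assigner implements the hydrogen-bond patterns only;
  STRIDE's torsion terms and DSSP's full ladder/sheet bookkeeping (bulges,
  ladder merging) are simplified to the 4-state collapse used downstream.
- The parametric placer explores rigid-body placements of a rigid subunit; it
  cannot represent the subunit deformations that relaxation would introduce.
- PDB is the only coordinate format (via bio3d); mmCIF and compressed
  trajectory formats are out of scope.
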