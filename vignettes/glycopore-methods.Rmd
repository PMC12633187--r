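---
title: "Methods: geometric gating analyses for pentameric channel trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric gating analyses for pentameric channel trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

`glycopore` analyses molecular dynamics trajectories of pentameric
ligand-gated ion channels — in particular GABA-A receptor assemblies in
which high-mannose N-glycans sit inside the extracellular vestibule,
facing the pore. The package asks one scientific question in several
geometric forms: *how does adding or repositioning a pore-facing glycan
change the subunit interfaces, the extracellular domain (ECD), and the
transmembrane gates?* All analyses are purely geometric; no energies,
force fields or kinetics are computed.

A *system* is one assembly variant (e.g. a control with two pore-facing
glycans versus a variant carrying a third). Each system is observed
through several independent *replicas* (trajectories). Replicas — not
frames — are the statistical unit for means, SEMs and t-tests, because
frames within a run are autocorrelated; frames are the unit only for the
permeable/non-permeable chi-squared classification, where each frame is
a categorical observation.

Coordinates are in Angstrom throughout and the pore axis is +z. No
periodic-boundary unwrapping is performed; the synthetic fixtures carry
no box. Residue numbering is taken verbatim from the topology file —
the literature mixes construct and mature numbering for the glycan
sequon (N123 vs N138 in the same receptor), so anchor residues are
always configuration inputs, never hard-coded.

## Contact analyses

**Salt bridges.** A salt bridge is present in a frame when the acid
side-chain terminal carbon (Asp CG, Glu CD) lies strictly within 4.0 A
of the base terminal atom (Arg CZ, Lys NZ). "Terminal atom" is a role,
not a PDB name; the mapping is configurable. Histidine is not in the
base set. Each acid–base residue pair counts at most once per frame.

**Hydrogen bonds.** Donor and acceptor must be polar (N, O, S, F), the
donor–acceptor distance at most 3.5 A, and the D–H···A arrangement
within 20 degrees of linearity. The angle criterion is deliberately the
deviation-from-linearity convention (the VMD semantics): an absolute
D–H–A angle below 20 degrees would be geometrically impossible for a
bonded hydrogen. Hydrogens attach to donors through explicit bonds when
the topology has them, otherwise by a 1.25 A nearest-heavy-atom rule.
Because a residue pair may form several donor/acceptor triplets, both a
triplet-level and a residue-pair-level occupancy (pair counted once per
frame if any triplet qualifies) are available; the pair level is the
default reporting unit.

**Occupancy and the comparison filter.** Occupancy is the fraction of
frames a contact is present, computed per replica; the cross-replica
SEM is the sample SD over replicas divided by sqrt(n). Alongside raw
occupancies the frame-wise distance series is z-scored within each
system (pooling frames of all replicas) and summarised per replica.
Two systems are compared pair-by-pair, with pairs missing from one
system entering at occupancy zero — zeros are data. A pair enters the
reported comparison only when the absolute occupancy difference
*strictly exceeds* 0.10. Exact fractions k/n whose binary double lands
one ulp above 0.10 would otherwise flip the strict boundary, so the
filter tests `|delta| - 0.10 > 1e-9`; the guard is far below any
meaningful occupancy resolution and keeps the boundary semantics exact
for planted integer frame counts.

## ECD geometry

**Hull expansion.** Per frame, each subunit ECD's mass-weighted centre
of mass is projected on the xy plane and the area of the convex hull of
the five points is recorded (grDevices::chull + the shoelace formula).
Splayed subunits give a larger area. With fewer than three distinct
points the area is zero, with a warning. One phrasing ambiguity is
worth flagging: expansion results of this kind are sometimes quoted as
a "convex volume" with area units; this package computes the 2-D xy
area and nothing else.

**Loop RMSD.** Internal-loop flexibility (defaults per subunit role:
alpha 130–143, beta 124–137, gamma 154–167) is the backbone RMSD
against the first frame. The superposition policy is open in the
underlying protocols; the package's choice is to fit each frame on the
whole-subunit backbone and then measure the loop without further
fitting, which isolates internal loop motion from rigid subunit drift.
The fit selection is an explicit argument, so the alternatives (no fit;
fit on the loop itself) are one call away.

**RMSF.** RMSF_i = sqrt(mean_t |r_i(t) − <r_i>|^2) after superposing
all frames on the time-averaged structure (one refinement pass: fit to
frame 1, average, re-fit to the average — sufficient at these scales).
The fit selection again matters: fitting on a *stable core* (here the
static scaffold backbone) measures fluctuation against a rigid
reference and makes planted amplitudes exactly recoverable
(RMSF = sigma * sqrt(3) for isotropic Gaussian displacement of width
sigma per axis); fitting on all atoms absorbs a fraction ~1/N of any
single atom's motion into the frame. Stable-core fitting is standard
practice and is what the shipped analyses use. Two-system comparisons
use a Welch t-test on replica-mean RMSF.

**Glycan tracking.** Each glycan is followed through its anchor
asparagine C-alpha and the terminal sugar's ring O5 (configurable);
the orientation vector, the 2-D distribution of terminal positions,
and the glycan RMSF over ring atoms summarise where the glycan sits
and how stiff it is.

## Pore geometry and hydration

**Pore radius.** The radius at height z is the largest sphere centred
in that plane, near the axis, touching no atom's vdW sphere:
r(z) = max_c min_a (|c − a| − vdw_a). The profiler reimplements the
HOLE geometry with a deterministic coarse-to-fine grid search (0.25 A
coarse pass over a ±4 A square, local refinement of the best three
candidates down to 0.01 A steps, compiled clearance kernel) instead of
the original's simulated-annealing walk; the test suite enforces
agreement with an exhaustive fine-grid brute force to within 0.05 A on
randomised ring and funnel fixtures. Radii are clamped to
[0, end_radius] with end_radius = 25 A; planes with no nearby atoms
report the end radius (an open mouth). vdW radii come from a fixed
Bondi-like element table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 A),
configurable; solvent and hydrogens are excluded from the profiling
atom set.

**Gates.** Three gate regions are profiled: the activation gate (AG,
9' position of the pore-lining TM2 helix), the second hydrophobic
constriction (2', the alpha1 V257 level), and the desensitisation gate
(DG, −2'). The reference point is the COM of the gate residues'
C-alpha atoms. The per-frame gate radius is the *minimum* radius inside
a slab of ±2 A about the gate COM z (slab definition and the
minimum-over-slab choice are package decisions; the alternative —
radius at the exact COM plane — is a parameter). Closure probability is
the fraction of frames with radius ≤ 1.25 A, a representative water
radius; a frame at exactly the threshold is closed/non-permeable.

**Water occupancy.** Waters are located by their oxygen. A water counts
when it lies in the square 5×5 A column around the axis
(|x−cx| ≤ 2.5 and |y−cy| ≤ 2.5 — a square, following the area
phrasing, not a circle) and falls into a half-open 2 A z-bin
[lower, upper) anchored at the reference z. Bin totals equal the
in-column count every frame by construction, and the tests assert it.

**Water wires.** A frame sustains a wire when in-column water oxygens
form a chain with consecutive O–O distances ≤ 3.5 A connecting the
lower to the upper face of the gate region (the ±2 A slab extended by
2 A per side, i.e. gate z ± 4 A); a water reaches a face when its axial
distance to it is within the O–O cutoff. The wire definition is a
package decision (the underlying protocols leave it implicit) and the
cutoff is a parameter.

**Permeability test.** Frames are classified permeable (radius > 1.25
A) or non-permeable per system; the systems × {permeable,
non-permeable} table gets a Pearson chi-squared (no continuity
correction, k−1 df). The accompanying sensitivity test recomputes the
statistic over thresholds 1.0–1.5 A in 0.05 A steps — an
interpretation of the briefly-mentioned "sensitivity test" as a
threshold sweep. Expected cell counts below 5 trigger a warning
recommending an exact test. Whether the chi-squared should compare
frame classifications of two systems (the default here) or pooled
counts across replicas is left open upstream; both inputs can be fed
to `permeability_test()` since it takes plain radius vectors.

## Dynamical network analysis

Nodes are protein C-alpha atoms and glycan ring O5 atoms. Two nodes are
adjacent when any heavy-atom pair of their residues sits within 4.5 A
in at least 75% of frames — the established dynamical-network
convention, adopted because the upstream description names the step but
not the criterion; both numbers are parameters. Edges between
sequence-adjacent residues of the same chain are removed to suppress
trivial backbone correlation. The correlation is the normalised
covariance of 3-D displacement vectors,
C_ij = <dr_i · dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), after superposition
to the mean structure (stable-core fit recommended, as above); this
linear estimator is the main interpretive assumption — generalised
(mutual-information) correlations are out of scope. Edge weights are
w = −ln|C|, so strong correlation *or* anticorrelation shortens paths.
Edges with C = 0 are dropped (infinite weight).

Suboptimal paths between a source and sink are enumerated *exactly*:
depth-first search over simple paths, pruned with the admissible bound
"weight so far + shortest remaining distance", returning every path
within a tolerance of the optimum (default 10% of the optimal weight).
At the package's graph scales (tens of nodes) exact enumeration is
cheap and sidesteps the approximation behaviour of k-shortest-path
heuristics. Betweenness is standard weighted shortest-path betweenness
(igraph), ties split fractionally, normalised by the (n−1)(n−2)/2 node
pairs a vertex can mediate. A node is a conserved hub when it appears
in the path ensembles of *strictly more than* 75% of replicas,
endpoints excluded; path-edge correlation summaries (mean |C| and the
fraction of edges at |C| ≥ 0.5) quantify whether extracted paths ride
on real correlated motion. Per-node visit frequency within one run's
suboptimal ensemble and recurrence across runs are both reported, as
the two readings of "frequently visited" differ.

## The synthetic generator

Real trajectories at the microsecond scale are neither shippable nor
re-simulatable, so every stage is validated on synthetic pentamer
trajectories with *planted, exactly known* ground truth. The template
is a geometric toy: five chains with C5 symmetry; an ECD scaffold ring
of backbone beads whose per-chain COMs sit exactly on a pentagon
(closed-form hull area); acid/base residue pairs whose terminal atoms
sit at a near distance (< 4 A) in exactly round(occupancy × n_frames)
seeded frames and a far distance otherwise; Ser–Thr donor/acceptor
pairs likewise, with the hydrogen kept on the donor–acceptor line;
three gate rings of pore-lining atoms whose inscribed radius follows a
per-frame schedule *exactly* (ring radius = schedule + vdW), each
surrounded by a wall ring 3 A outside that stands in for the helix
bundle — without it the planar search would escape the thin toy ring
outward; a TIP3P-like water column with planted per-bin counts and a
schedulable water wire whose central link parks outside the column in
non-wire frames; glycan pseudo-chains of C1/O5 sugar beads that sway
rigidly with Gaussian amplitude (expected RMSF = sigma·sqrt(3)); and
free node residues carrying block-correlated displacements
a_i(t) = sqrt(rho)·g(t) + sqrt(1−rho)·e_i(t) along a fixed random
direction, whose population correlation is exactly rho.

What the fixtures deliberately do *not* emulate: forces and dynamics
(frames are temporally uncorrelated — occupancy and every statistic
used here are frame-count properties), solvent realism, side-chain
chemistry beyond the named terminal atoms, and periodic boundaries.
Passing tests therefore demonstrate that the *measurement machinery* is
correct and exactly calibrated, not that any biological conclusion
transfers; on real data the same code runs with real topologies and
the configuration supplies the selections. Planted bin counts must be
zero inside the wire stripe (z in [−4, 4] in-column) when a wire is
scheduled, or the plants would bridge the wire; the spec constructor
enforces this.

All randomness flows from one integer seed; regeneration is
bit-identical, and changing the seed changes frame memberships but
never the planted targets (they are constructed, not sampled).

## The shipped demo study

`run_demo_study()` builds a control assembly (two pore-facing glycans)
and a perturbed assembly (a third glycan) and runs the full pipeline.
The planted effect sizes follow the magnitudes reported for
glycosylated GABA-A receptor simulations, so the demo exercises the
pipeline at realistic signal strength: activation-gate mean radius 1.38
vs 1.19 A via two-level schedules, closure probability 30.2% vs 59.8%
at 1.25 A, water-wire persistence 43% vs 11%, a +21.66 A^2 hull
expansion, glycan sway giving RMSF 6.59 vs 4.14 A, six salt bridges and
four hydrogen bonds with shifts straddling the 10% filter, and a
seven-node allosteric chain at pairwise correlation 0.718 from an ECD
"binding site" node to the activation gate. The study size is 500
frames × 4 replicas per system, chosen so every planted fraction is an
integer frame count (0.302 × 500 = 151) and four replicas support
SEMs and conservation scoring; the test suite exercises the same demo
at 100 × 2. The chi-squared value scales with frame count and is
reported at the demo's own n, not any external value.

## Numerical choices and degenerate inputs

- Strict-boundary conventions are frozen in tests: salt bridge `< 4.0`,
  H-bond `<= 3.5` and `<= 20` degrees, permeability "closed" at
  `<= 1.25`, persistence `>= 0.75`, inclusion filter and conservation
  strictly `>`.
- Half-open z-bins assign an oxygen on an edge to the upper bin.
- The pore search is confined to a ±4 A square about the reference
  axis (±2 A for gate traces, where the reference tracks the gate COM);
  radii are clamped to [0, end_radius].
- Zero-variance network nodes get zero off-diagonal correlation with a
  warning rather than NaN.
- Degenerate variance in the replica-mean Welch test (all replicas
  identical) short-circuits to an exact-separation report instead of a
  t statistic.
- Empty selections, atom-count mismatches, missing backbone atoms in a
  loop, and windowless COM displacement calls are hard errors: silent
  empties corrupt occupancy denominators.

## Known limitations

Geometric criteria only (no energetic H-bond scoring, no cation–pi
interactions); linear correlations only; 2-D hull area only; no
conductance or PMF estimation; XTC input is not supported (PDB and DCD
are); and the synthetic fixtures, by design, cannot validate behaviour
that only force-field physics produces.
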