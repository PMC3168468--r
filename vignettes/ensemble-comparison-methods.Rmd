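---
title: "Comparative analysis of conformational ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of conformational ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembledyn)
```

## Scope and rationale

`ensembledyn` compares equilibrium conformational ensembles of homologous
proteins — typically a cold-adapted enzyme, a warm-adapted homolog, and
engineered mutants of the former — residue by residue through a structural
correspondence. The comparison rests on five observables that together
characterise how mutations redistribute stabilising interactions and
collective motions:

1. **Surrounding hydrophobicity (Hp)** — the local hydrophobic environment
   of each residue;
2. **Hydrogen-bond persistence** — geometric H-bond detection and the
   fraction of donors/acceptors engaged;
3. **Essential dynamics** — PCA of Cα fluctuations, per-residue rmsf in
   the essential subspace, anisotropic U-tensors, and sampling-quality
   indices;
4. **Cross-correlation networks** — significant long-range coupled
   motions, filtered and differenced across systems;
5. **Salt-bridge networks** — ion-pair persistence with a
   classifier-derived cutoff, spatial-proximity clusters, cross-system
   conservation groups, and correlation of acquired bridges with
   experimental phenotypes.

The package does not run molecular dynamics, compute DSSP assignments or
structural alignments, or estimate interaction free energies: ensembles,
per-frame secondary-structure labels, and residue correspondences are
inputs.

## The data model

Every analysis consumes an `ensemble`: an ordered array of frames with a
per-atom table and one Cα pointer per residue, in nm and ps. Multi-model
PDB files are read and written through bio3d (Å converted on I/O, so
round-trip precision is the PDB's 10⁻³ Å). Independent replica
simulations of one system are concatenated with
`join_macrotrajectory()`, discarding a per-replica equilibration prefix;
all persistences are fractions of the joined macro-trajectory's frames,
with equal frame weighting throughout.

Superposition (`superpose()`) least-squares-fits every frame to the
iteratively refined mean structure (Kabsch fit on a selection, default all
Cα, iterated until the mean moves < 10⁻⁶ nm). A collinear selection
leaves the rotation undetermined and is a hard error. The representative
conformation of an ensemble is the sampled frame with least main-chain
(N, Cα, C, O; Cα-only as a logged fallback) rmsd from the coordinate
mean — the mean itself is unphysical and never reported as a structure.

## Surrounding hydrophobicity

For residue *i* in one frame,

$$\mathrm{Hp}(i) = \sum_{j \ne i} H(r_d - r_{ij})\, h_j,$$

with \(r_{ij}\) the Cα–Cα distance, \(r_d = 0.8\) nm, \(H\) the Heaviside
step with \(H(0) = 1\) (the boundary counts as inside), and \(h_j\) the
hydrophobicity index of residue *j* in kcal/mol from thermodynamic
transfer experiments. The packaged default scale is the Jones (1975)
transfer free-energy scale; the scale is an editable TSV and every report
records its provenance, because absolute Hp values depend on the scale
while cross-system comparisons do not. The residue's own index is
excluded by default ("surrounding" residues); a flag re-includes it for
sensitivity checks. The ensemble value is the per-frame mean;
`on = "mean"` instead evaluates Hp once on the mean structure, offered
because frame-averaging and structure-of-mean differ slightly for mobile
regions. Profiles are smoothed with a centred 5-residue window (ends
truncated), and `hp_histogram()` tallies residues per Hp range with
half-open `[low, high)` bins.

## Hydrogen bonds

A bond exists in a frame iff the donor–acceptor distance is ≤ 0.35 nm and
the angular criterion holds for at least one hydrogen covalently attached
to the donor (same residue, within 0.115 nm in the first frame). The
default angular convention measures the angle at the donor between the
D→H and D→A vectors, cutoff 30° — the common MD-package convention for
that cutoff value; a deviation-from-linearity criterion at the hydrogen
vertex is available behind `vertex = "hydrogen"`. Donor/acceptor
membership follows standard amino-acid chemistry (backbone N–H donor and
carbonyl O acceptor, canonical side-chain groups) and ships as an
editable TSV; proline's backbone N is never a donor. Structures without
explicit hydrogens are rejected rather than silently downgraded to a
distance-only criterion, since the two criteria disagree precisely for
the bent contacts the angle filter exists to remove. The normalized
ensemble fraction counts, per frame, the distinct donor and acceptor
atoms participating in at least one bond over the total number of donors
plus acceptors (atom-participation counting; event counting would weight
multi-bonded atoms differently).

## Essential dynamics

The 3N×3N covariance of Cα positional fluctuations about the ensemble
mean is diagonalised (mass-unweighted, 1/n denominator so per-residue
tensor traces equal mean squared fluctuations exactly). The essential
subspace is the span of the leading eigenvectors; its dimension k is the
smallest reaching 70% cumulative variance by default — in well-sampled
protein ensembles this is typically of the order of ten eigenvectors —
with a fixed-k override for cross-system comparability, since
k-by-variance can select different k per system. Eigenvector signs are
fixed by making the largest-magnitude component positive, so reports are
reproducible across platforms.

Per-residue rmsf is computed on subspace-reconstructed coordinates
(frames rebuilt from their first-k projections) rather than in
eigenvector coordinates: this matches the notion of projecting the
trajectory onto the essential subspace and yields per-residue values that
reduce exactly to the ordinary rmsf at k = 3N. Anisotropic U-tensors are
the 3×3 covariances of the same reconstructed fluctuations; the ellipsoid
scale for a probability level p follows the χ²(3 df) quantile convention
(recorded as `sqrt(qchisq(p, 3))`, default p = 0.1).

Sampling quality is monitored with the cosine content of the leading
principal projections (computed with trapezoidal quadrature, so an exact
half-period cosine scores 1; values near 1 flag diffusion-like,
unconverged sampling) and the RMSIP over the first 10 eigenvectors
between two subspaces. rmsf convergence uses sliding windows of 1, 2, 5,
10, 15 and 20 ns moving by 500 ps, averaging the per-window profiles per
length; window lengths exceeding the trajectory are skipped with a
warning rather than an error so short test trajectories remain usable.

## Cross-correlation networks

Within non-overlapping windows (1 ns default; 2 and 3 ns serve as
consistency checks) the normalised covariance
\(C(i,j) = c(i,j)/\sqrt{c(i,i)c(j,j)}\) of Cα fluctuation vectors about
the window mean is computed, and the per-window matrices are averaged
elementwise; thresholds are applied to the averaged matrix, with
per-window matrices retained for inspection. Fluctuations are taken
about each window's own mean, which already removes inter-window drift.
An optional per-window rigid-body re-fit (`refit = TRUE`) is provided
for trajectories with substantial rotational drift, but it is off by
default: least-squares fitting spreads a spurious anticorrelation of
order 1/N over all residue pairs, a bias comparable to the recovery
tolerances of interest at small N, whereas the global fit-to-mean
superposition plus window-mean centring leaves planted correlations
unbiased.

Networks keep pairs with |C| > 0.4 and sequence separation |i−j| > 12
(both strict), the separation cutoff excluding within-helix and
sequence-neighbour correlations. On the 1 ns scale essentially only
positive correlations exceed 0.4, but the filter uses |C| as defined.
Pairs inside the same annotated helix, or both within an annotated
barrel-strand set, can additionally be masked via `ss_pair_mask()`; the
mask is explicit configuration, not an inference, because the membership
of those classes is a per-protein annotation choice. Zero-variance
residues in a window yield masked entries excluded from the average with
a message. `network_diff()` maps edges through the residue
correspondence and reports shared and private edges; edges touching
gapped residues go to a separate unmappable set, never silently dropped.

## Salt bridges

Oppositely charged side-chain groups (default Asp OD1/OD2 and Glu
OE1/OE2 negative, Lys NZ and Arg NE/NH1/NH2 positive; His excluded by
default because its charge is protonation-dependent; termini optional)
are in contact when the minimum inter-atom distance across the two
groups is < 0.4 nm (0.45 and 0.5 nm as sensitivity settings).
Persistence is the contact fraction over the macro-trajectory;
per-replica persistences can be inspected by running detection per part
before joining.

The persistence cutoff separating structural bridges ("signal", > 30%)
from transient encounters ("noise", < 10%) is selected by training a
maximum-margin linear SVM and a 4-nearest-neighbour classifier on the
two classes of the observed 1-D persistence distribution and locating
each classifier's decision boundary inside the gap; the selected cutoff
is their common boundary, or the midpoint with the disagreement width
reported when they differ. k-NN ties are broken toward the noise class —
the conservative direction, admitting fewer bridges. The 4-NN classifier
is implemented in the package because its tie-break must be
deterministic. If either training class is empty the procedure aborts
and instructs use of a fixed cutoff (default 24%, i.e. bridges present
in at least 24% of frames; 20% as a sensitivity setting).

Residues involved in retained bridges form an undirected graph with arcs
for bridged pairs and for sequence neighbours at |i−j| < 5 (i.e. ≤ 4 —
stated explicitly because the off-by-one changes clusters); connected
components are the spatial-proximity clusters, ordered by smallest
member. Nodes are residues, not charged groups, so a residue bridging
two partners joins them into one cluster. Conservation groups across
systems (after mapping to the cold reference numbering) are: I = present
in all systems; IV = present in the warm reference and at least one
mutant but not the cold wild-type (mesophilic-like acquisitions); II/III
= present in exactly one wild-type with no corresponding residues in the
other; all else unclassified. `phenotype_correlation()` reports the
Pearson coefficient of a per-mutant feature — canonically the count of
group-IV bridges acquired — against phenotype columns such as Tm and
kcat/Km, requiring at least 3 mutants and flagging zero-variance
features as undefined.

## Synthetic ensembles as ground truth

Because archived trajectories are rarely available and real ones have no
known truth, the generators plant the quantities the analyses estimate:

- `gen_gaussian_ensemble()` samples a Cα bead chain from
  \(\Sigma = V\Lambda V^{\top} + \sigma^2 I\) and returns the analytic
  correlation matrix and eigensystem, so covariance, correlation, rmsf
  and subspace recovery can be asserted against exact values.
- `gen_contact_series()` builds spatially isolated GLU/LYS pseudo-pairs
  whose charged atoms toggle between a formed (0.30 nm) and broken
  (0.80 nm) distance by a per-frame Bernoulli draw with known p.
- `rpersistence_mixture()` draws persistences from a two-component Beta
  mixture with modes near 0.05 and 0.6 and no mass in (0.10, 0.30),
  emulating the empirically bimodal signal/noise structure of ion-pair
  persistence distributions.
- `gen_homolog_pair()` relates two bead systems by an indel-containing
  correspondence with shared planted modes on mapped positions.
- `gen_two_system_fixture()` combines these into a reference/variant
  pair whose only differences are one gained bridge and one extra
  correlated pair.

Same seed means bit-identical output. These ensembles are Gaussian and
memoryless: they have no autocorrelation in time, no anharmonicity, no
side-chain packing, and no coupling between the contact series and the
bead dynamics. Passing recovery tests therefore demonstrates numerical
correctness of the estimators and filters — not that real trajectories
are converged or that the geometric criteria capture chemistry; on real
data the sampling-quality indices and sensitivity cutoffs exist
precisely because those assumptions fail gradually.

Default problem sizes used by the test-suite and the acceptance script —
50-residue Hp configurations, 5,000-frame correlation recovery,
10,000-frame eigenvalue recovery, 2,000-frame persistence estimates, 100
seeded cutoff-selection mixtures, and a 40-residue two-system pipeline
fixture at 1,000 frames — were chosen so that sampling error sits well
inside the assertion tolerances at desk scale.

## Numerical choices and degenerate inputs

- Covariance uses the 1/n denominator; eigenvalues are clipped at 0;
  the eigenvalue sum reproduces the trace to ~10⁻¹⁵ relative.
- A rigid (zero-variance) ensemble is flagged degenerate: no k is
  selected and downstream projection refuses it explicitly.
- Ensembles not flagged as superposed are checked for net rigid drift
  (centroid standard deviation > 10⁻³ nm is a hard error) before
  covariance analysis.
- Persistence filtering keeps `persistence >= cutoff` ("at least"), so a
  planted 0.25 passes and 0.23 fails at the 24% default.
- Half-open histogram bins `[low, high)`; `findInterval` semantics.
- Modal secondary-structure ties are broken by a fixed priority order
  (H, G, I, E, B, T, S, C, -) and flagged.
- Report TSVs carry a comment header with package version, seed and all
  parameters, and contain nothing time- or locale-dependent, so reruns
  are byte-identical.

## Known limitations

- Hp, correlation and ED operate on Cα only, by design; all-atom
  variants are out of scope.
- Salt-bridge strength is not estimated — persistence is a geometric
  occupancy, blind to desolvation penalties and charge networks'
  energetics.
- The conservation-group rules assume one cold reference, one warm
  reference and mutants of the cold system; other topologies fall into
  "unclassified" rather than being guessed.
- The H-bond detector requires explicit hydrogens; ensembles from
  united-atom force fields must be protonated upstream.
- PDSSP consumes external label tables; no secondary structure is
  computed internally.
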