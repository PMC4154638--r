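---
title: "Mapping long-range communication in conformational ensembles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping long-range communication in conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnpaths)
```

# The model

`psnpaths` treats a protein conformational ensemble as evidence for two
complementary residue–residue relations, and looks for long-range
communication where both hold along a chain.

## The contact layer: interaction-strength networks

Two residues interact non-covalently when their side chains touch. Per
frame, for every residue pair $(i, j)$ with $|i - j| \ge 2$, we count the
number of distinct side-chain heavy-atom pairs within a distance cutoff
(default **0.45 nm**), $n_{ij}$, and convert it into a percent-scaled
interaction strength

$$I_{ij} = 100 \cdot \frac{n_{ij}}{\sqrt{N_i N_j}},$$

where $N_i$ is a normalization value for the residue type of $i$ —
bulky aromatic side chains make many more atomic contacts than alanine,
and dividing by $\sqrt{N_i N_j}$ makes strengths comparable across types.
When no externally calibrated table is given, `self_normalization()`
derives $N$ from the ensemble itself as the per-type maximum of the mean
total contacts a residue makes, floored at 1; users with a calibrated
per-type table can inject it through `normalization_table()`. The factor
of 100 keeps cutoffs on the conventional 0–40 scale.

A protein structure network (PSN) at cutoff $I_{min}$ joins residues with
$I_{ij} > I_{min}$ (strict inequality). Its connected components are the
clusters; zero-degree nodes are orphans; nodes of degree $\ge 4$ are
hubs. Scanning $I_{min}$ from 0 to 40 in steps of 0.2 and recording the
largest-cluster size produces a non-increasing profile whose main
transition defines the critical cutoff $I_{crit}$: weak, promiscuous
contacts dissolve there while the stiff interaction core survives.

Per-frame networks are aggregated into a **consensus network**: an edge is
kept when its strength exceeds $I_{min}$ in at least a fraction (default
**0.5**) of the frames. This persistence filter removes transient
contacts that exist in individual snapshots but not in the ensemble.

## The dynamics layer: linear mutual information

Coupled motions are quantified per residue pair from C$\alpha$
displacement vectors. Within non-overlapping windows of
`window_frames` frames, coordinates are least-squares superposed onto the
window-mean structure (two fitting passes) to remove rigid-body motion,
and the Gaussian (linear) mutual information is computed from the
$3\times3$ marginal and $6\times6$ joint displacement covariances,

$$\mathrm{MI} = \tfrac12\left(\ln\det C_i + \ln\det C_j - \ln\det C_{ij}\right),
\qquad r = \sqrt{1 - e^{-2\,\mathrm{MI}/3}} \in [0, 1].$$

$r$ is a generalized correlation coefficient: 0 for uncorrelated, 1 for
fully correlated motions, and — unlike a Pearson correlation of
projections — invariant to the relative orientation of the two residues'
fluctuations (the package asserts this numerically to $10^{-6}$ under
global rotations). For isotropic, equal-variance displacements with
per-axis correlation $\rho$, $r = |\rho|$ exactly, which is the closed
form the synthetic validation relies on. The window matrices are averaged
element-wise into the working correlation matrix; a significance cutoff
(default **0.5**, inclusive) marks pairs with meaningful coupling.

Replicate agreement is measured by the Frobenius norm of the difference of
two matrices of order $m$, $F = \sqrt{\sum_{ij} (a_{ij}-b_{ij})^2}$.
Replicates of one system are judged consistent when all their pairwise
norms are smaller than every norm against a control matrix from a run
that does not preserve the native correlation pattern (in the synthetic
setting, a shuffled covariance specification; for real data, an unfolding
simulation), with half-versus-half norms of single replicates as the
within-trajectory baseline.

## Communication paths

On the consensus network all edges have unit length, and shortest paths
(fewest intermediate nodes) are computed with Floyd–Warshall; ties are
broken toward the lexicographically smallest node sequence so results are
reproducible, with bounded enumeration of all co-shortest paths available
on demand. For a set of target residues, every other residue contributes
its best path into the set, filtered by the cascade:

1. **correlation filter** — at least one intermediate node has $r \ge 0.5$
   with the path's first or last residue;
2. **occurrence** — the fraction of per-window consensus networks
   containing every edge of the path is at least **0.15**;
3. **length** — the path spans more than three nodes (endpoints included).

Retained paths are partitioned into long-range ($\ge 8$ nodes) and
shorter classes, compared across conditions by exact node sequence, and
joined into a **meta-graph** whose edge weight is the fraction of retained
paths containing that connection. Node participation counts in the
meta-graph rank mediator residues; deleting the top mediator from the
network and recomputing distances is the in-silico analogue of a
communication-breaking point mutation.

# The synthetic generator

No public trajectory accompanies the analyses this package is built for,
so validation rests on synthetic ensembles with exact ground truth:

* `make_reference_polymer()` places residues on a smooth curve at 1.0 nm
  C$\alpha$ spacing, each with 1–5 pseudo side-chain heavy atoms according
  to its residue type (glycine gets none, exercising the C$\alpha$
  fallback of the selection policy). The deliberately generous spacing
  guarantees a contact-free baseline: every contact present afterwards
  was planted.
* `sample_gaussian_ensemble()` draws per-residue displacement vectors
  from a multivariate normal with block-constant per-axis correlation
  $\rho$ (independent axes, default per-axis variance 0.0025 nm², i.e.
  0.05 nm fluctuations) and moves each residue rigidly, so planted
  side-chain geometry survives sampling.
* `plant_contact_chain()` relocates the side-chain atoms of the chain
  residues, in exactly $\lceil \text{persistence} \cdot n_{frames} \rceil$
  frames, onto a dedicated contact line 2 nm away from the polymer: tight
  clusters 0.34 nm apart, so consecutive chain residues form contacts
  (every atom pair within 0.45 nm) while chain-skipping pairs stay beyond
  0.6 nm. Successive chains are placed on parallel lines so multiple
  planted paths never collide. Residues outside the chain are never
  touched.

What this emulates: known pairwise correlations for estimator validation,
and persistent non-covalent contact chains with controllable per-frame
persistence for network and path validation. What it does not emulate:
realistic protein geometry, internal side-chain dynamics, anisotropic or
correlated-across-axes fluctuations, solvent effects, and the broad
spectrum of weak transient contacts real proteins show. Passing tests
therefore demonstrate correctness of the machinery under controlled
conditions, not the biological validity of any particular cutoff on real
trajectories.

Because the synthetic baseline is contact-free, self-normalized strengths
of planted edges sit near 100 — far above the 0–40 window in which real
proteins show their cluster transition. End-to-end synthetic runs
therefore set the cutoff explicitly (`i_min = 5`, safely below any
planted strength) rather than relying on scan-transition detection, which
is validated separately on two-scale networks built for that purpose.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `distance_cutoff` | 0.45 nm | atom-pair contact distance |
| `seq_exclusion` | 2 | minimum sequence separation of counted pairs |
| `imin_range`, `imin_step` | 0–40, 0.2 | strength-cutoff scan grid |
| `persistence_threshold` | 0.5 | consensus edge persistence |
| `lmi_window_frames` | ensemble metadata | frames per correlation window |
| `lmi_cutoff` | 0.5 | correlation significance (inclusive) |
| `min_occurrence` | 0.15 | path occurrence probability floor |
| `min_node_count` | 4 | paths must span more than three nodes |
| `long_range_nodes` | 8 | long-range class, endpoints included |
| `hub_min_degree` | 4 | hub definition (more than three edges) |

Windows are counted in frames, not physical time: an ensemble carries a
`frames_per_window` field standing in for a fixed-length time window
(conventionally 5 ns), since synthetic frames have no timestep.

# Numerical and design choices

* **Contact atoms.** Side-chain heavy atoms (all non-hydrogens outside
  `N, CA, C, O, OXT`) by default — communication paths are conceived as
  chains of side-chain contacts — with glycine represented by its
  C$\alpha$. Hydrogens are flagged on reading and excluded from counting.
  Both choices are policy arguments, not hard-coded.
* **Distinct pairs.** $n_{ij}$ counts atom *pairs*, not atoms: one atom
  may appear in several pairs, each pair counted once.
* **Strict edge rule and boundaries.** Edges require $I_{ij} > I_{min}$
  strictly. Consequently an edge whose strength coincides exactly with a
  scan grid point dies at that grid point, and the detected transition
  then equals the edge strength itself; validations with planted integer
  strengths scan on a grid that does not contain them (step 0.3), which
  real-valued strengths from actual ensembles never require. The
  significance cutoff on correlations is *inclusive* ($r \ge 0.5$), the
  persistence threshold likewise.
* **Largest cluster of an edgeless graph is 0**, not 1, so scan profiles
  terminate at zero; this affects only the tail of the profile.
* **$I_{crit}$ detection** operationalizes "main transition" as the
  largest single-step drop of the profile, reported at the first grid
  point of the new plateau, ties broken toward the smaller cutoff. A
  3-point smoothed variant (`method = "smoothed"`) is available for drops
  split across grid points. A flat profile raises a no-transition error
  rather than fabricating a cutoff.
* **Hub threshold.** Conventions in the literature of this method vary
  between "more than three" and "more than four" edges; the default is
  degree $\ge 4$, with the stricter variant one argument away.
* **Covariance regularization.** $10^{-8}$ nm² is added to covariance
  diagonals before determinant evaluation, so planted rigid blocks (or
  frozen residues) do not produce singular matrices; genuinely
  non-positive joint determinants fall back to $r = 0$ with a warning.
* **Superposition reference** is the window mean (two passes) by default;
  first-frame and no-superposition variants are provided. For ensembles
  in which a large fraction of residues moves as one correlated block,
  the rigid-body fit absorbs part of that collective motion and biases
  $r$ downward — validation fixtures therefore keep planted blocks a
  small fraction of the chain, mirroring the situation in real proteins
  where collective drift is genuinely indistinguishable from rigid-body
  motion.
* **Occurrence denominator.** The probability of occurrence is computed
  over per-window consensus networks, reusing the correlation windowing;
  per-replicate occurrence is available by passing one consensus network
  per replicate instead.
* **Direct edges** (source–target pairs with no intermediate) cannot
  satisfy the correlation filter literally and are short-range by
  construction; they are excluded from the ranked path list and reported
  separately in the `direct_edges` attribute.
* **Target sets** are handled per target residue with de-duplication:
  each source keeps its shortest, then highest-occurrence, path into the
  set.
* **Numbering.** Residues are indexed contiguously from 1 internally
  (the R convention); the author/PDB numbering of the input is carried
  alongside for reporting.
* **Determinism.** Every stochastic generator takes an explicit seed and
  restores the caller's RNG state; identical configurations produce
  byte-identical run artifacts (the GML creator stamp is normalized for
  this reason).

# Validation scales

The shipped test-suite and the acceptance script validate on sizes chosen
to exercise every code path while completing in minutes: exhaustive graph
oracles on all labelled graphs up to 5 nodes plus 100 random graphs up to
50 nodes; LMI recovery on 100-residue ensembles of 5000 frames (planted
$\rho \in \{0, 0.3, 0.6, 0.9\}$, recovered within $\pm 0.05$); path
recovery on 24-residue ensembles of 200 frames in four analysis windows;
replicate consistency on three 30-residue replicates of 600 frames
against a shuffled-covariance control. The estimator-recovery tolerance
of 0.05 reflects the combined effect of sampling noise at 5000 frames,
the Gaussian-MI estimator's small-sample bias, and the superposition
effect discussed above.

# Known limitations

* Only protein chains enter the network: nucleic acids, ligands and
  solvent are dropped on reading (with a warning), so in a
  protein–DNA complex the network describes the protein's internal
  communication, not protein–DNA edges.
* The linear (Gaussian) MI estimator captures linear coupling only;
  nonlinear estimators (e.g. k-nearest-neighbour MI) and full correlation
  analysis are out of scope.
* Degree is the only centrality measure computed; the method ranks
  mediators by path participation, not betweenness.
* The self-derived normalization makes strengths comparable within one
  system; cross-system comparisons should use one shared table.
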