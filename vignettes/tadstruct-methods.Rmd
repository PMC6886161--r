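---
title: "Models and methods behind tadstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tadstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadstruct)
```

## The problem

Hi-C experiments count physical contacts between pairs of fixed-size genomic
bins ("beads"). Within a topologically associating domain (TAD) these counts
are dense; across TADs they are sparse. `tadstruct` turns a single
chromosome's or TAD's contact matrix into a 3D bead-chain model by metric
multidimensional scaling (MDS), and then quantifies the model's shape with
structural metrics that can be weighted by genetic and epigenetic features.

## From contacts to target distances

Bead pairs split into two sets: $C_1 = \{(i,j): c_{ij} \neq 0\}$ and
$C_2 = \{(i,j): c_{ij} = 0\}$. Pairs in $C_1$ receive a target distance by
the decreasing power law

$$\delta_{ij} = \beta \left(1/c_{ij}\right)^{\alpha},$$

with $\alpha = 1/3$ and $\beta = 1$ by default. $\alpha = 1/3$ reflects the
volume-vs-contact-frequency scaling argument common in chromatin
reconstruction; $\beta$ only sets the overall scale of the model, which is
why truth-recovery comparisons allow a similarity (scaled) superposition.
Pairs in $C_2$ get no target distance; masks carry definedness, never
sentinel values.

## The three objective functions

Writing $d_{ij}$ for the model distance, the package minimizes one of
(sums over unordered pairs $i < j$):

1. **Relative stress on observed pairs** (`eq2`):
   $\sum_{C_1} (d_{ij}-\delta_{ij})^2/\delta_{ij}^2$.
2. **Stress plus repulsion** (`eq3`):
   $\sum_{C_1} (d_{ij}-\delta_{ij})^2/\delta_{ij} - \gamma \sum_{C_2} d_{ij}^2$
   with $\gamma = 0.01$. Note the first-power denominator on the $C_1$ term:
   this objective is *not* objective 1 plus a penalty. The repulsion term is
   unbounded below for any bead with no $C_1$ edge, so such inputs are
   rejected with a pointer to `largest_connected_component()`.
3. **Targeted placement of zero-contact pairs** (`eq4-shortest`,
   `eq4-max`):
   $\sum_{C_1} (d_{ij}-\delta_{ij})^2/\delta_{ij}^2 +
   \sum_{C_2} (d_{ij}-R_{ij})^2/R_{ij}^2$, where $R$ is either the
   shortest-path distance between $i$ and $j$ through the graph whose edges
   are $C_1$ pairs weighted by $\delta$ (per-pair $R_{ij}$), or the single
   maximum target distance over $C_1$ (scalar $R$). The shortest-path matrix
   is computed once per contact matrix — it depends only on $\delta$, not on
   the evolving coordinates. For a $C_1$ pair the shortest path may undercut
   the direct edge; only $C_2$ entries of the matrix are consumed.

The choice between the two $R$ schemes is a modelling statement about
missing data: shortest-path $R$ assumes unobserved pairs are roughly as
close as the contact graph allows, maximum-distance $R$ assumes they are far
apart. On dropout fixtures the reconstructed median $C_2$ distance under
`eq4-max` is at least that under `eq4-shortest`, which the acceptance
checks assert.

## Optimization

All objectives are smooth away from coincident beads, with analytic
gradients of the form $\nabla_i f = \sum_j K_{ij}(x_i - x_j)$ for per-pair
coefficients $K_{ij}$; the gradients are verified against central finite
differences for all four variants in the test suite. Minimization uses
L-BFGS-B (`stats::optim`) with iteration cap 3000 and projected-gradient
tolerance $10^{-7}$ per start.

Starts: the first is a classical (Torgerson) MDS embedding of the target
distances, with $C_2$ entries completed by graph shortest paths — random
cube initializations alone proved unreliable at $n = 50$ (runs stall in
local minima an order of magnitude above the global basin), while the
Torgerson start lands in the recovery basin essentially always. The
remaining starts (5 total by default) draw coordinates uniformly from a
cube whose side is the mean target distance, under a PRNG fully determined
by the configured seed; the start with the lowest final objective wins.
Every reconstruction is therefore bit-reproducible given its seed.

Two degenerate situations are handled explicitly: exactly coincident beads
in an active pair get a deterministic symmetric jitter of
$10^{-9}\times$ the initialization scale before differentiation (logged);
and a restart whose objective goes non-finite is discarded with a message
rather than poisoning the result.

**Chirality.** Pairwise distances are invariant under reflection, so a
reconstruction with a perfect objective may still be the mirror image of
the underlying truth. Superposition itself (`kabsch_superpose`) excludes
reflections — proper rotations only, enforced by flipping the smallest
singular value's sign — so recovery against a known ground truth is
assessed as the better of the structure and its `mirror_structure()`.

## Structural metrics

**Radius of gyration.** $R_g = (\sum_i m_i \lVert x_i - R_C\rVert^2 / M)^{1/2}$
about the mass-weighted center $R_C$. The masses encode features:
`mass_unit` (all 1), `mass_TSS` (1 + TSS count), `mass_or` (2 if any of
TSS/H3K4me3/RNA polII present, else 1), `mass_and` (1 + total of the three
counts). $M$ defaults to $\sum_i m_i$, the physically standard choice; the
`length_normalized` flag instead divides the total mass by the number of
beads, because "total mass normalized by TAD length" admits either reading
— both are exposed and the default is stated rather than silently chosen.
Length is measured in beads, not base pairs, where the flag applies.

**Folding degree.** Every three consecutive beads span a plane and
consecutive planes meet at a dihedral angle, computed as the unsigned angle
in $[0, \pi]$ between plane normals (chirality discarded — the matrix
diagonal needs a magnitude; an all-planar zigzag chain gives $\pi$). The
third iterated line graph $L^3$ of the bead chain is a path on $n-3$ nodes,
one per dihedral. The metric is the normalized Estrada index of
$S = A(L^3) + \mathrm{diag}(\varphi)$: $\frac{1}{m}\sum_j e^{\lambda_j}$
over the eigenvalues of $S$. The exact matrix composition (edge weights on
$L^3$, diagonal units) is not uniquely fixed by the Estrada-index
literature this follows; the composition above is this package's reading,
and the unnormalized sum $\sum_j e^{\lambda_j}$ is attached as an attribute
so either convention is available. Three consecutive collinear beads (cross
product below $10^{-12}$) are a hard error, not a silent zero angle.

**Exponent parameter.** The 2D (matrix-level) metric: mean contact
$P(s)$ at each genomic separation $s$ — zero counts included, a zero is
data — then a least-squares fit of $\log_{10} P(s)$ on $\log_{10} s$ over
all separations with $P(s) > 0$ (`max_s` can truncate the range). The
returned value is the negated slope, positive for decaying matrices. At
least 3 usable separations are required.

## TAD-level analyses

Per-TAD feature enrichment is either a midpoint-based peak count or the
mean of $\log_2$ signal values over overlapping intervals, both divided by
TAD length in base pairs. Non-positive signal values are excluded from the
log with a counted warning; a TAD with no overlapping signal yields a
missing value, not zero. Metric–feature association uses plain Pearson
correlation with the two-sided $t$-distribution p-value; no multiplicity
correction is applied at this level (a Benjamini–Hochberg adjustment is a
one-liner away via `p.adjust` on the output).

Chromatin-state fold enrichment of state $s$ in TAD $t$ is the coverage
fraction of $s$ within $t$ divided by the coverage fraction of $s$ in the
union of all segmentation intervals supplied. TAD–TAD affinity is the
absolute Pearson correlation of fold-enrichment profiles. Clustering is
Ng–Jordan–Weiss spectral clustering: symmetric degree normalization,
top-$k$ eigenvectors, row normalization, then seeded k-means. The k-means
restarts use k-means++ seeding: with $k$ in the tens, uniform random
restarts routinely merge one pair of clusters and split another even on a
cleanly separated embedding, and no practical restart count fixes that
reliably. Dense affinities are used directly (no k-NN sparsification).

Inter-TAD observed/expected contacts use $E_{ij} = R_i R_j N_{inter}$ with
$N_{inter}$ the total inter-TAD count and $R_i$ the fraction of inter-TAD
contacts involving TAD $i$. Each contact is associated with *both* of its
TADs, so $\sum_i R_i = 2$; the wording of the source formula does not fix
this convention, and this choice is the one under which two TADs in
isolation give $O/E = 1$ exactly. The two-TAD and uniform three-TAD cases
($O/E = 3/4$) are asserted in the tests.

## The synthetic generator

Real mESC Hi-C/ChIP-seq inputs are deliberately not bundled; the generator
produces ground-truth fixtures in their place:

- **Structures**: regular helices (closed-form geometry, equal dihedrals)
  and seeded fixed-step random walks (collinear triples resampled away).
- **Contacts**: the exact inverse of the conversion law,
  $c_{ij} = (\beta/d_{ij})^{1/\alpha}$, so structure → contacts → target
  distances is an identity without noise — the backbone of every recovery
  test. Realism knobs: multiplicative lognormal noise (Hi-C counts are
  positive and heteroscedastic) and symmetric pair dropout (default study
  fixture: 20% dropout at 40 beads) creating a non-empty $C_2$.
- **Feature tracks**: Poisson point events per bead and lognormal signal
  tracks.
- **Planted state profiles**: `k_blocks` center vectors with within-block
  Gaussian noise (sd 0.05) over 14 states, mirroring a 14-state
  segmentation; centers are rejection-sampled to pairwise
  $|\mathrm{cor}| < 0.4$ because a planted partition is only a meaningful
  clustering benchmark if its blocks are identifiable under the
  correlation-based affinity — with unconstrained random centers in 14
  dimensions, chance near-collinear center pairs collapse blocks.

What the generator does *not* emulate: excluded volume, loop extrusion,
coverage biases (fixtures are already balanced unless you apply
`ice_normalize` to deliberately biased input), distance-dependent noise
correlation, and translocation-like structural variants. Passing recovery
tests on these fixtures therefore demonstrates correctness of the
optimization and metric machinery, not biological accuracy of any
particular reconstruction from noisy experimental data.

## Numerical choices

- Contact matrices must be symmetric to $10^{-9}$ absolute after read-time
  repair; readers repair only relative asymmetry up to $10^{-6}$ (averaging
  $M$ with $M^\top$) and refuse worse, naming the worst cell.
- ICE-style balancing: divide by marginals until the coefficient of
  variation of non-zero-row marginals drops below $10^{-5}$ (default), cap
  200 sweeps, all-zero rows untouched and excluded, final scale fixed at
  unit mean marginal. Non-convergence is a message, not an error.
- Peaks/TSS spanning bin boundaries are counted once, in the bin containing
  their midpoint; sum/mean/any aggregation modes use full overlap. BED
  input is 0-based half-open; strand is ignored everywhere.
- Disconnected contact graphs are an error for shortest-path $R$ (and the
  repulsive objective), with `largest_connected_component()` as the
  documented escape hatch — never silently patched.
- All stochastic code paths (restarts, synthetic draws, k-means) consume an
  explicit integer seed; derived seeds stay below $2^{31}$.

## Problem sizes

The test and acceptance fixtures use 50-bead noiseless helices for
recovery, 40 beads with 20% dropout for the zero-contact-pair comparisons,
5-bead instances for gradient checks, chains up to $n = 12$ for the
eigenvalue oracle, 40-bead matrices for noisy exponent recovery, and 200
profiles for the 20-cluster benchmark — sizes chosen so each property is
exercised at a scale where an independent oracle (exhaustive path
enumeration, determinant root-finding, grid-search superposition) is still
exact, while full runs stay comfortably interactive on a laptop.

## Limitations

Single chromosome or TAD at a time (no genome-wide multi-chromosome
matrices); text formats only (no `.cool`/`.hic`); population-average
reconstruction (one consensus structure, no ensemble or single-cell
modelling); $\alpha$ is fixed rather than fitted; and the Estrada-matrix
composition is one defensible reading of the folding-degree literature, as
noted above.
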