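---
title: "Elastic-network mode analysis and perturbation mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network mode analysis and perturbation mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmspm)
```

## The model

A protein or protein complex is reduced to one node per residue, placed at
its Cα atom. Every pair of nodes whose reference distance $d_{ij}^0$ is
strictly below a cutoff $R_c$ is joined by a harmonic spring, giving the
anisotropic elastic-network Hamiltonian

$$H \;=\; \tfrac{1}{2}\sum_{(i,j):\,d_{ij}^0 < R_c} \gamma\,
\bigl(d_{ij} - d_{ij}^0\bigr)^2 ,$$

where $\gamma$ is a single global spring constant that only sets the energy
scale. `build_hessian()` assembles the exact second-derivative matrix of
this energy at the reference structure: each contact contributes
$-\gamma\,\hat e_{ij}\hat e_{ij}^{\mathsf T}$ to its off-diagonal $3\times3$
block, with $\hat e_{ij}$ the unit vector along the reference separation,
and diagonal blocks accumulate minus the row sums, so every block row sums
to zero and the energy is invariant under rigid translation. Normal modes
are the eigenpairs of this $3N\times3N$ matrix under unit masses
(`compute_modes()`); a connected, generically coordinated network has
exactly six zero eigenvalues (rigid translations and rotations). Mode
numbering is 1-based over the full ascending spectrum *including* the zero
modes, so the first internal mode of a connected assembly is mode 7.

Under-coordinated geometries deserve a warning here: a straight bead chain
is *floppy* in a distance-only network — bending costs no pairwise distance
change — and carries additional exact zero modes (mechanisms).
`compute_modes()` flags any spectrum with more than six zeros, and the
pipeline refuses to analyze such a network, distinguishing true
disconnection (it lists component sizes) from mechanisms.

## Measured quantities

**Overlap.** Given two conformations of the same node set, the transition
vector $\Delta\mathbf r$ is the per-node coordinate difference after the
end conformation has been rigid-body superposed (Kabsch) onto the start
(`transition_vector()`, `align = TRUE` by default — without alignment,
arbitrary rigid offsets between deposited structures leak into
$\Delta\mathbf r$ and inflate the apparent participation of the rigid-body
modes). The overlap of mode $M$ is the normalized inner product

$$I_M \;=\; \frac{\bigl|\mathbf q^M \cdot \Delta\mathbf r\bigr|}
{\lVert\mathbf q^M\rVert\,\lVert\Delta\mathbf r\rVert} \in [0,1].$$

The absolute value is deliberate: an eigenvector's sign is arbitrary, and
only $|I_M|$ is meaningful; the signed projection is retained internally
(it is what makes $\sum_M I_M^2 = 1$ over the complete basis an exact
Parseval identity, which the test suite asserts). Modes with
$I_M \ge 0.35$ (configurable) form the *dominant set*, reported in
descending overlap.

**Covariance.** Residue cross-correlations over a mode subset $S$ are

$$C_{ij} \;=\; \frac{\sum_{M\in S} \mathbf q_i^M\!\cdot\mathbf q_j^M / \omega_M}
{\sqrt{\sum_{M\in S} |\mathbf q_i^M|^2/\omega_M}\,
 \sqrt{\sum_{M\in S} |\mathbf q_j^M|^2/\omega_M}} \in [-1, 1],$$

with $+1$ concerted and $-1$ opposed motion. The weight $\omega_M$ is taken
as the Hessian *eigenvalue* $\lambda_M$ (the thermal-covariance convention:
summed over all internal modes this reproduces the normalized per-node-pair
block traces of the Hessian pseudo-inverse, which is the oracle the tests
compare against). Whether the frequency $\sqrt{\lambda_M}$ was intended
instead is ambiguous in this corner of the literature, so `covariance()`
exposes a `weighting` switch (`"eigenvalue"`, `"frequency"`, `"none"`); for
a single mode all three give identical maps, so per-mode figures are
unaffected by the choice.

**Displacement.** The relative displacement of node $i$ in mode $M$ is
$\delta q_i^M = \sqrt{(q_{ix}^M)^2 + (q_{iy}^M)^2 + (q_{iz}^M)^2}$; for a
normalized mode $\sum_i (\delta q_i^M)^2 = 1$. Profiles for a mode *set*
are the plain arithmetic sum of per-mode profiles (not an RMS), matching
the "sum of the individual fluctuations" convention used when painting
mobility onto structures.

**Structural perturbation method.** A mutation at node $i$ is modeled as
stiffening every spring incident to $i$ by $\delta\gamma$. The response of
mode $M$ is the first-order eigenvalue shift, the quadratic form of the
mode over the perturbation Hessian:

$$\delta\omega_i^M \;=\; \delta\gamma \sum_{j:\,d_{ij}^0<R_c}
\bigl[\hat e_{ij}\cdot(\mathbf q_i^M - \mathbf q_j^M)\bigr]^2 \;\ge\; 0 .$$

This is exactly linear in $\delta\gamma$, so hot-spot *rankings* are
independent of the perturbation magnitude; the default
$\delta\gamma = 0.01\,\gamma$ merely keeps first-order perturbation theory
accurate when validating against full rediagonalization (the suite demands
agreement within 1% at $\delta\gamma = 10^{-4}\gamma$ for every node of a
30-node toy). Hot spots for a mode are the top fraction (default 2%) of
nodes by response, with the count taken as the *ceiling* of
$\text{fraction}\times N$ — 2% of 1853 nodes keeps 38 — and ties broken
deterministically by ascending node index. Because some published counts
are quoted as an absolute number across differently sized models,
`select_hotspots()` also accepts an absolute `count`. A useful identity
(tested): summing responses over all nodes counts each contact at both
endpoints, so $\sum_i \delta\omega_i^M = 2\,\delta\gamma\,\lambda_M/\gamma$
for a unit-normalized mode.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `rc` | 9 | Å | contact cutoff; chosen by maximizing the Pearson correlation of mode B-factors with experimental B-factors (`calibrate_cutoff()`) |
| `gamma` | 1 | energy/Å² | global spring constant; rescales the spectrum, cancels in overlap, covariance and rankings |
| `overlap_threshold` | 0.35 | — | dominant-mode cutoff on $I_M$ |
| `hotspot_fraction` | 0.02 | — | fraction of nodes kept per mode (ceiling) |
| `delta_gamma` | 0.01 | fraction of γ | perturbation magnitude; rankings invariant |
| `tol_zero` | 1e-8 | relative | eigenvalue threshold for zero modes |

Contacts use the strict inequality $d < R_c$; a pair at exactly the cutoff
is excluded (measure zero in practice, but documented). Coordinates are Å
throughout; PDB output is fixed-column with occupancy 1.00, and per-node
scalars written to the B-factor column are min–max rescaled to
$[0, 99.99]$ to fit the field.

## Synthetic fixtures: what they emulate, and what they do not

The generators exist so every stage is testable without downloading any
structure. Domains are jittered FCC-like compact clusters — for an elastic
network only the contact topology matters, so no attempt is made at
realistic backbone geometry, secondary structure or sequence (residues are
poly-alanine). All generators are deterministic given their seed, and the
jitter is uniform on $[-j, +j]$ per coordinate so distance guarantees are
exact bounds rather than probabilistic ones.

**Hinged two-domain pair** (`make_hinge_dimer()`). Emulates an open→closed
transition with a known displacement field: the closed conformation is the
open one with the moving domain rigidly rotated about the hinge axis, so
the ground truth is exact and identically zero on the static side. The
hinge is built as a *revolute joint*: each domain carries a 5-node pillar
parallel to the rotation axis at 0.8 Å radius, and the two pillars
interdigitate. Contacts within this tall, narrow column are almost
unstrained by rotation about the axis (moment arm = pillar radius) but
strongly strained by rocking or torsion (moment arm = column height), which
makes the in-plane hinge rotation the softest internal motion by
construction. A literal two-point hinge will not do: if the domains touch
only the two hinge nodes, relative rotation about the line through them
changes *no* distance at all and appears as a seventh exact zero mode. The
static domain carries ten times the moving domain's nodes, so the soft
mode's counter-rotation (which splits inversely with domain inertia)
concentrates on the moving domain — the lever-arm construction behind the
3:1 displacement contrast the tests assert.

**Dimer with 0/1/2 cochaperones**
(`make_symmetric_dimer_with_cochaperones()`). Emulates a two-fold-symmetric
chaperone homodimer: protomer B is protomer A rotated 180° about the dimer
axis, exactly, so mirror-symmetry assertions hold to floating-point
precision rather than statistically. The protomers join across the same
revolute-column interface, making the open/close counter-rotation the
softest interface motion; the recorded `closing_delta` (a ±12° counter-
rotation) is zero on cochaperone nodes, since a conformational change of
the dimer does not define displacements for a bound partner. One
cochaperone cluster docks broadly onto a protomer flank; the symmetric 1:1
complex is produced by the same least-RMSD overlay
(`assemble_symmetric_complex()`) used for real structures, which for exact
protomer copies reproduces the two-fold symmetry exactly (re-superposition
RMSD 0).

What the fixtures do *not* emulate — and hence what passing tests do not
show about real data: protomers here are internally rigid blobs, so all
soft motion is inter-body. One consequence is worth spelling out: with one
cochaperone bound, the softest mode (the closing counter-rotation) and the
whole-spectrum thermal fluctuations both show the bound protomer suppressed
relative to the free one (about 1.7-fold and 2.5-fold respectively in the
standard fixture), but the dominant set also contains a stiffer mode in
which only the bound-side body rotates — a mode family that real,
internally flexible protomers fragment and damp. The suite therefore
asserts suppression for the leading dominant mode and for B-factors, not
summed over every mode above threshold. Real structures also have
heterogeneous contact density, loops and disorder, which affect cutoff
calibration and mode localization in ways uniform synthetic blobs cannot.

## Numerical choices

- Dense symmetric eigensolver (LAPACK via `eigen(symmetric = TRUE)`) over
  the full spectrum; appropriate up to a few thousand nodes, which covers
  the 2458-node symmetric complex. Partial/sparse solvers are out of scope.
- Deterministic eigenvector signs (largest-magnitude component positive) so
  covariance signs and CSV outputs are identical across runs; re-running an
  identical pipeline configuration reproduces outputs byte for byte.
- `tol_zero` is relative to the largest eigenvalue; an all-zero Hessian
  (no contacts) is treated as all zero modes.
- Kabsch superposition corrects reflections by flipping the smallest
  singular direction, so returned rotations are always proper; collinear
  or <3-point correspondences are rejected (the rotation would be
  underdetermined).
- Node identity is `(chain, residue number)`; insertion codes are rejected
  rather than silently renumbered. Equal-length structures correspond
  positionally by default; anything else needs an explicit mapping.
- A transition of numerically zero length (< 1e-10 Å) is an error, not a
  degenerate profile.

## Problem sizes

The test suite runs on toys between 2 and 340 nodes (full eigensystems up
to ~1000 dimensions) plus a contact/assembly check at the published sizes
(1853 and 2458 nodes, no eigendecomposition). The acceptance script
additionally diagonalizes the full 1853-node asymmetric complex
(5559-dimensional Hessian) to compute hot spots and fluctuation ratios at
the published scale; that is the largest routine computation in the
package and completes in minutes on one CPU.

## Known limitations

- Single global spring constant: no distance-weighted or sequence-dependent
  stiffness, no Gaussian (isotropic scalar) network variant.
- Unit masses; mode frequencies are reported as Hessian eigenvalues, not
  physical frequencies.
- The comparison runner (`run_reference_comparison()`) reproduces published
  dominant-mode indices and overlaps only when the user supplies prepared
  full-length structures; homology completion and docking of missing
  regions are out of scope, and reported overlap values for real chaperone
  complexes are sensitive to how missing loops were modeled.
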