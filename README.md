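# enmspm

Coarse-grained normal-mode analysis of chaperone complexes — and of protein
assemblies in general — with the three observables that turn a mode spectrum
into a mechanistic story: how well each mode explains an observed
conformational transition, which residues move together, and which residues
wire the allosteric signal.

The package is aimed at structural biologists and biophysicists studying
large conformational cycles (the Hsp90 open→closed transition and its
modulation by a bound Hsp70 is the motivating system) where all-atom
simulation is impractical but an elastic network captures the collective,
low-frequency motions.

## The model

Each residue is a node at its Cα position. Nodes within a cutoff
R<sub>c</sub> (default 9 Å, selected by B-factor calibration) are joined by
harmonic springs with one global spring constant γ:

&nbsp;&nbsp;&nbsp;&nbsp;H = ½ Σ<sub>(i,j): d⁰<sub>ij</sub> &lt; R<sub>c</sub></sub> γ (d<sub>ij</sub> − d⁰<sub>ij</sub>)²

Diagonalizing the 3N×3N Hessian of H gives eigenvectors **q**<sup>M</sup>
and eigenvalues λ<sub>M</sub>; a connected assembly has six zero modes
(rigid motions), so the first internal mode is mode 7. On top of the
spectrum the package computes:

- **Overlap** I<sub>M</sub> = |**q**<sup>M</sup>·Δ**r**| / (‖**q**<sup>M</sup>‖‖Δ**r**‖)
  of each mode with a transition field Δ**r** taken between two superposed
  conformations; modes with I<sub>M</sub> ≥ 0.35 are *dominant*.
- **Covariance** C<sub>ij</sub> ∈ [−1, 1], the normalized correlation of
  per-residue displacement directions within a mode (or a 1/λ-weighted mode
  set): +1 concerted, −1 opposed.
- **Displacement** δq<sub>i</sub><sup>M</sup> = |**q**<sub>i</sub><sup>M</sup>|,
  the per-residue mobility in a mode, summed over mode sets for mapping
  onto structures.
- **Structural perturbation method (SPM)**
  δω<sub>i</sub><sup>M</sup> = δγ Σ<sub>j</sub> [ê<sub>ij</sub>·(**q**<sub>i</sub><sup>M</sup> − **q**<sub>j</sub><sup>M</sup>)]²,
  the mode-frequency response to stiffening the springs of residue i; the
  top 2% of residues per mode are its allosteric *hot spots*.

Structure I/O (CA-only PDB), Kabsch superposition, symmetric-complex
assembly by least-RMSD overlay, cutoff calibration, deterministic synthetic
fixtures with known ground-truth dynamics, and a config-driven pipeline
(`run_analysis()`) writing a complete CSV/PDB/JSON report bundle are all
included.

## Worked example

A hinged two-domain toy whose closed conformation is the open one with the
small domain rotated 15° about the hinge — so the true answer is known:

```r
library(enmspm)

pair <- make_hinge_dimer(seed = 1)
pair
#> toy_pair: hinged two-domain toy, 120 deg -> 105 deg closure (340 nodes, seed 1)

cfg <- analysis_config(pair$open, pair$closed, outdir = "hinge-run")
report <- run_analysis(cfg)
report
#> analysis_report:
#>   dominant modes:
#>     mode 7  overlap 0.919
#>   artifacts: 9 files in hinge-run

segment_summary(report$covariances[[1]], pair$open$segments)
#>   segment_i segment_j       mean
#> 1    static    static  0.0979518
#> 2    moving    static -0.2804256
#> ...
#> 5    moving    moving  0.8163690
```

Read: the very first internal mode (mode 7) explains 92% of the open→closed
transition — hinge motions are low-frequency modes. The covariance block
means show the moving domain internally concerted (+0.82) and anticorrelated
with the static domain (−0.28), the signature of a hinge. The report
directory also contains the per-mode displacement profiles, the SPM hot-spot
lists (`hotspots_mode7.txt`, as `chain:resnum`), a displacement-annotated
PDB for molecular viewers, and a JSON metadata record that echoes the exact
configuration.

For real data, replace the toy with two prepared PDB files of matched
residue content (`read_structure()`), and use `run_reference_comparison()` to
tabulate computed dominant modes against externally reported values. An
asymmetric complex can be expanded to its symmetric 1:1 counterpart with
`assemble_symmetric_complex()`, which overlays the ligand-bound protomer
onto the free one and carries the ligand along.

A thin command-line wrapper with `synth`, `run` and `calibrate-cutoff`
subcommands is installed at `inst/cli/enmspm.R`.

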