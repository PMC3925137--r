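---
title: "Fibril mechanics from thermal fluctuation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibril mechanics from thermal fluctuation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmech)
```

## The problem

Amyloid fibrils are filamentous protein aggregates built from stacked
cross-beta layers: beta strands run perpendicular to the fibril axis, layers
repeat every ~4.8 Å with a small twist, and two beta-sheets pack against each
other through a dry "steric zipper" interface. The packing pattern of that
interface — whether the two sheets are co- or anti-aligned, whether hydrogen
bonding within a sheet is parallel or anti-parallel, and whether the zipper
packs identical or distinct sheet faces — defines eight polymorph classes
(`enumerate_zipper_classes()`), and the polymorph controls the fibril's
mechanics.

`fibrilmech` implements the fluctuation route to those mechanics: given an
equilibrium trajectory of a fibril (from molecular dynamics, or from this
package's own synthetic generator), it extracts the vibrational spectrum by
quasi-harmonic analysis, identifies which spectral modes are bending,
torsion, or stretching by comparing them with continuum beam mode shapes,
and inverts the matched frequencies into bending rigidity, persistence
length, torsional and axial stiffness.

## Quasi-harmonic analysis

For C-alpha coordinates $\mathbf r$ sampled over frames, the fluctuation
(covariance) matrix is

$$\mathbf Q = \langle (\mathbf r - \langle \mathbf r\rangle) \otimes
(\mathbf r - \langle \mathbf r\rangle) \rangle ,$$

a $3N \times 3N$ matrix in Å². Frames are first iteratively superposed onto
the mean structure (Kabsch least squares), otherwise rigid diffusion swamps
the internal modes; `align = FALSE` is retained for experiments on raw
covariances, and a fixed external reference can be supplied when strict
frame-to-frame comparability matters. The spectral decomposition
$\mathbf Q \mathbf v_j = \xi_j \mathbf v_j$ orders eigenvalues descending.
Treating each principal mode as an effective harmonic oscillator of mass
$M_C$ gives the stiffness matrix
$\mathbf K = k_B T \sum_j \xi_j^{-1} \mathbf v_j \mathbf v_j^{\mathsf T}$
(over internal modes) and per-mode natural frequencies

$$\omega_j = \sqrt{\frac{k_B T}{M_C\,\xi_j}} .$$

Six eigenvalues of a superposed trajectory are numerically zero — the
rigid-body translations and rotations — and are excluded from all internal
sums (`n_rigid = 6` by default). The per-mode fluctuation contribution is
the variance fraction $\alpha_k = \xi_k / \sum_j \xi_j$, which equals
$\mathrm{RMSF}(k)^2 / \mathrm{RMSF}^2$ with
$\mathrm{RMSF}^2 = \sum_j \xi_j / N$; a ratio-of-RMSF (non-squared) variant
is available behind `alpha_variant = "rmsf_fraction"` because the
dimensionless contribution can be defined either way and the variance
fraction is the one that sums to exactly 1.

**Choice of $M_C$.** The site mass is a convention, not a measurement: it
scales all frequencies by $M_C^{-1/2}$ and all inverted rigidities by
$M_C^{-1}$ jointly with the mass per length, so the *pipeline* keeps a
single `calpha_mass` knob used consistently for frequencies, mass per unit
length, and rotary inertia. The default 12.011 Da (a carbon atom) is the
C-alpha-coordinate convention; for coarse bead models supply the bead mass.

## Continuum beam layer

A free-free Euler-Bernoulli beam (both ends unconstrained — the only
boundary condition consistent with six rigid-body zero modes of a fibril
fluctuating in solvent) has bending mode shapes

$$\varphi_n(x) = (\cosh\beta_n x + \cos\beta_n x) -
\sigma_n(\sinh\beta_n x + \sin\beta_n x),$$

with $\lambda_n = \beta_n L$ the roots of $\cos\lambda\cosh\lambda = 1$
($\lambda_1 = 4.7300407\ldots$) and
$\sigma_n = (\cosh\lambda_n - \cos\lambda_n)/(\sinh\lambda_n - \sin\lambda_n)$.
Torsion and stretching of the free-free rod share the shape family
$\cos(n\pi x/L)$. The frequency relations, and the inversions this package
reports, are

| family  | frequency | inversion |
|---------|-----------|-----------|
| bending | $\omega_n = \lambda_n^2\sqrt{E_BI/(\mu L^4)}$ | $E_BI = \omega^2\mu L^4/\lambda_n^4$ |
| torsion | $\omega_n = (n\pi/L)\sqrt{G_TJ/\iota}$ | $G_TJ = \iota(\omega L/n\pi)^2$ |
| axial   | $\omega_n = (n\pi/L)\sqrt{E_XA/\mu}$ | $E_XA = \mu(\omega L/n\pi)^2$ |

where $\mu$ is mass per unit length and $\iota$ the rotary inertia per unit
length (equal to $\rho J$ for a homogeneous section, in which case the
torsional modulus reduces to the textbook $G_T = \rho(\omega L/n\pi)^2$ and
$J$ cancels). Rigidities ($E_BI$, $G_TJ$, $E_XA$) are the assumption-free
primary outputs; moduli in Pa require a cross-section model and are reported
only when one is configured. The persistence length is
$l_p = E_BI/(k_BT)$.

**Cross-section models.** Nothing in a fluctuation trajectory fixes $A$,
$I$ or $J$; they are geometric conventions needed only for GPa conversion.
The `envelope` model takes per-station convex hulls of the atom centers,
inflated by an effective atomic radius (default 3 Å), and integrates the
offset polygons exactly; `fixed` accepts user-supplied section values.
$\mu$, $L$ and $\iota$ are always measured directly from the mass
distribution.

**Mode classification.** Each eigenvector is decomposed per axial station
into collective displacements along the two principal transverse directions,
the axial direction, and a least-squares twist about the axis. Squared
overlaps with the analytic shape bases (projected into the rigid-free
complement, since discretely sampled continuum shapes retain a little rigid
content) assign the family and order; the bending plane whose order-1 mode
fluctuates more is labelled *soft*. Modes with best overlap below 0.5 are
`mixed`; eigenvalues below $10^{-6}\xi_1$ are `rigid`. Inversion pairs each
family's lowest-order classified mode with its quasi-harmonic frequency.

## The synthetic generator

The package is validated against trajectories whose mechanics are known
exactly. `beam_spec()` fixes the study conditions; the defaults describe a
12 nm filament of 20 axial stations — roughly the ~4.8 Å-rise layer stack of
a short fibril coarse-grained to one station per pair of strands — with two
1100 Da tracer beads per station (about the mass of a 10-residue strand)
offset ±5 Å perpendicular to the axis, mirroring the two sheets of a
cross-beta layer. Pure-centerline models cannot express torsion; the tracer
pair makes twist observable from coordinates alone. Default rigidities are
$E_BI_z = 1\times10^{-28}$ and $E_BI_y = 2\times10^{-28}$ N m² (the scale
reported for short amyloid fibrils, and anisotropic so the two bending
families separate), $G_TJ = 2\times10^{-28}$ N m² and
$E_XA = 2\times10^{-9}$ N (giving shear/axial moduli of a few tenths of GPa
for a nm² section), at 300 K, with frame metadata of 6 ps.

Each frame superposes the analytic free-free modes (default: first three
orders per family) with amplitudes drawn independently per frame from the
equipartition distribution $q_n \sim \mathcal N(0,\,k_BT/(m_n\omega_n^2))$,
where the modal mass $m_n$ is the discrete quadrature
$\sum_i m_i \varphi_n(x_i)^2$ over the beads. Two numerical choices matter:

* **Discrete orthogonality.** Continuum shapes evaluated at a finite set of
  stations are only approximately orthogonal (and carry a little rigid
  content). The displacement patterns are therefore projected out of the
  exact discrete rigid-body space and Gram-Schmidt orthogonalized in order
  of ascending frequency — the discrete normal modes of a discrete system
  *are* orthogonal, and this keeps generator and analyzer consistent;
  low-order shapes remain analytic while high orders absorb the small
  corrections.
* **Local thermal jitter.** A small isotropic per-coordinate Gaussian
  (default 0.1 Å RMS at 300 K, scaled by $\sqrt{T/300\,\mathrm K}$) stands
  in for the unresolved local disorder of real data, making the fluctuation
  spectrum full-rank as observed covariances are — without it every
  direction outside the injected modes would be exactly zero and the
  rigid-mode count would be meaningless. Its magnitude sits far above the
  rigid-mode threshold ($10^{-6}\xi_1 \approx 6\times10^{-4}$ Å² at the
  defaults) and at or below 1% of the smallest injected-mode eigenvalue, so
  it biases no recovered rigidity by more than ~1%.

Amplitudes are drawn as one block (modes fastest, frames outermost), then
the jitter block, then any rigid-motion block, so a fixed seed fixes the
trajectory bit-for-bit.

What the generator does *not* emulate: anharmonicity, solvent memory and
hydrodynamics, sequence-specific packing, shear-deformable (Timoshenko)
corrections that matter for short stubby fibrils, and conformational
transitions. Passing the recovery tests therefore demonstrates that the
analysis chain is a correct inverse of the harmonic beam model at realistic
noise — not that any particular real fibril is harmonic.

## The zipper builder

`build_zipper_fibril()` produces idealized cross-beta geometry for any of
the eight classes: extended strands with 3.4 Å C-alpha spacing, 4.8 Å rise,
configurable per-layer twist (a positive twist is a right-handed helix and
reads back as a positive IUPAC inter-layer dihedral), 10 Å sheet separation,
anti-aligned classes reversing the second sheet, anti-parallel classes
alternating strand direction layer-to-layer, hetero classes shifting the
second sheet by half a residue. With `include_backbone_atoms = TRUE` each
residue carries N, H, CA, C, O placed so that the stack forms clean
axis-parallel N-H···O=C hydrogen bonds, as in cross-beta architecture. It is
an idealization for testing metrics, not a model of any deposited structure.

## Conformational metrics

* **RMSD / RMSF** — Kabsch superposition; RMSF from the retained spectrum.
* **Inter-layer dihedral** — IUPAC dihedral of (axis tip j, centroid j,
  centroid j+1, axis tip j+1), the per-layer twist; `strands_per_pitch()`
  converts its mean into strands per full helical turn
  (10° and 2 strands/layer give 72).
* **Bending angle** — deviation from straight of the two end-centroid
  vectors about the mid-layer centroid (a three-point definition; the hinge
  layer is configurable).
* **Order parameter** — population variance (rad²) of the layer dihedrals
  about their circular mean; values above 0.07 flag a disordered fibril.
  The variance form is the simplest dimensionless disorder measure
  consistent with that threshold; a circular-SD variant is available
  (`op_variant`).
* **Hydrogen bonds** — geometric criterion D···A ≤ 3.5 Å and
  D-H···A ≥ 150° (a common convention; there is no universal one), with a
  distance-only 3.2 Å fallback and warning when hydrogens are absent;
  reported per residue with mean and fluctuation.
* **SASA / nonpolar solvation** — Shrake-Rupley with a deterministic
  golden-spiral mesh (960 points, 1.4 Å water probe by default) and
  $\Delta G_{np} = \gamma\,\mathrm{SASA} + \beta$ with
  $\gamma = 0.00542$ kcal/(mol Å²), $\beta = 0.92$ kcal/mol. Electrostatic
  (Poisson-Boltzmann) solvation and molecular-mechanics energies are out of
  scope.

## A worked example

```{r example}
spec <- beam_spec()           # the documented defaults above
traj <- sample_beam_trajectory(spec, n_frames = 2000, seed = 1)
report <- run_analysis(list(calpha_mass = spec$mass_per_bead_Da,
                            discard_fraction = 0), trajectory = traj)
report$mechanics[, c("family", "order", "nu_THz", "rigidity")]
```

The recovered rigidities sit within a few percent of the declared
$10^{-28}/2\times10^{-28}$ N m² at 5000 frames (the problem size used by the
package's own validation suite, which runs in well under a minute); at the
2000 frames above the statistical error is correspondingly larger.

## Problem sizes, tolerances, defaults

* Validation runs use 20 stations (40 beads), 5000 frames, fixed seeds:
  large enough that the variance-of-variance error per mode is ~2%, small
  enough to keep the whole suite fast. Equipartition is checked at
  10⁴ frames against a 5% band.
* Analysis defaults mirror common practice for equilibrium trajectories:
  discard the first half (`discard_fraction = 0.5`), 6 ps frame metadata,
  `n_rigid = 6`, alignment on.
* Eigen-decomposition is a dense symmetric solve; a deterministic sign
  convention (largest-magnitude component positive) makes outputs
  reproducible. Fancier reduced-order eigensolvers are a performance
  optimization only and are deliberately not implemented.
* Degenerate sections ($I_y = I_z$) make the soft/stiff split arbitrary;
  the classifier then labels by eigenvalue order, which is the only
  observable distinction.

## Known limitations

* Euler-Bernoulli bending neglects shear; for fibrils only a few diameters
  long the inverted bending modulus absorbs the shear compliance and reads
  low. A Timoshenko correction is a documented non-goal.
* The quasi-harmonic frequency scale is set by the site-mass convention
  (see above); rigidity ratios between polymorphs are insensitive to it,
  absolute values inherit it.
* The H-bond criterion and the bending-angle hinge are conventions;
  both are configurable and logged in the run report.
* PDB files carry no masses; the pipeline substitutes `calpha_mass`
  uniformly.
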