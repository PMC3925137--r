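# fibrilmech

Mechanical properties of amyloid fibrils from thermal fluctuation
trajectories.

Amyloid fibrils — stacked cross-β layers of β-strands packed through a dry
steric-zipper interface — behave at the 10 nm scale like elastic beams, and
their stiffness is encoded in the polymorph (which of the eight possible
zipper packings the fibril adopts). This package extracts that mechanics
from an equilibrium trajectory, with no pulling or indentation: for
scientists analyzing coarse (Cα-level) molecular-dynamics trajectories of
fibrils or other filaments, and for method developers who need a fully
controlled synthetic benchmark.

The chain is:

1. **Quasi-harmonic analysis.** The Cα fluctuation matrix
   Q = ⟨(r − ⟨r⟩) ⊗ (r − ⟨r⟩)⟩ over superposed frames is spectrally
   decomposed; each principal mode of variance ξⱼ is an effective harmonic
   oscillator with natural frequency ωⱼ = √(k_BT/(M_C ξⱼ)), and
   K = k_BT Σ ξⱼ⁻¹ vⱼvⱼᵀ is the effective stiffness matrix. Six near-zero
   modes (rigid-body space) are excluded; αₖ = ξₖ/Σξ measures each mode's
   share of the thermal fluctuation.
2. **Mode classification.** Modes are decomposed per axial station into
   transverse / axial / twist channels and matched by overlap against the
   free-free Euler-Bernoulli shapes φₙ(x) = (cosh βₙx + cos βₙx) −
   σₙ(sinh βₙx + sin βₙx) (bending, with cos λ cosh λ = 1 roots) and
   cos(nπx/L) (torsion, stretching).
3. **Inversion.** Matched frequencies give rigidities:
   E_B·I = ω²μL⁴/λₙ⁴ per bending plane, G_T·J = ι(ωL/nπ)²,
   E_X·A = μ(ωL/nπ)², and the persistence length l_p = E_B·I/(k_BT).
   Moduli (Pa) follow when a cross-section model is configured.

Also included: RMSD/RMSF, inter-layer twist dihedrals and strands-per-pitch,
bending angle, a twist-disorder order parameter (variance of layer dihedrals,
rad²; > 0.07 flags disorder), geometric backbone H-bond detection,
Shrake-Rupley SASA and the nonpolar solvation energy
ΔG_np = γ·SASA + β; an idealized builder for the eight steric-zipper
polymorph classes; and a synthetic generator of thermally fluctuating
free-free beams with exactly known mechanics (equipartition-sampled analytic
modes plus a small local-disorder jitter), which is the package's validation
surface.

## Worked example

```r
library(fibrilmech)

spec <- beam_spec()    # 12 nm beam, 20 layers x 2 tracers, EI = 1 / 2 x 1e-28 N m^2
traj <- sample_beam_trajectory(spec, n_frames = 5000, seed = 1)
report <- run_analysis(list(calpha_mass = spec$mass_per_bead_Da,
                            discard_fraction = 0), trajectory = traj)
print(report)
#> Fibril fluctuation analysis report
#>   5000 frames x 40 C-alpha sites (config 0020d8a4)
#>   RMSF = 5.128 A over retained modes
#>   mechanics (lowest-order mode per family):
#>       family mode order  nu_THz rigidity  modulus persistence_length_m
#> 1  soft-bend    1     1 0.00318 1.00e-28 2.39e+09             2.42e-08
#> 2 stiff-bend    2     1 0.00445 1.97e-28 3.11e+08                   NA
#> 3    torsion    5     1 0.01488 1.94e-28 2.87e+08                   NA
#> 4      axial    7     1 0.02350 1.94e-09 1.38e+09                   NA
```

Reading the output: the two lowest non-rigid modes are the order-1 bending
modes of the two principal planes (the fibril bends before it twists or
stretches); their frequencies, ~0.003 THz here, invert to bending rigidities
of 1.00×10⁻²⁸ and 1.97×10⁻²⁸ N m² — the generator's declared 1×10⁻²⁸ and
2×10⁻²⁸ recovered to within a few percent — and a persistence length of
24 nm for this deliberately soft 12 nm beam. Torsion and stretching appear
at higher frequency (modes 5 and 7), as they do for real fibrils.

A thin CLI wrapper ships in `inst/scripts/fibrilmech`
(`build` / `simulate` / `convert` / `run`).

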