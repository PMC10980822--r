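# memwrap

Membrane biophysics of lipid-binding-mediated, clathrin-independent
endocytosis: what does it take for a multivalent globular particle — a
virus-like ~40 nm shell studded with ligands — to deform a membrane and get
wrapped? `memwrap` implements the adhesion-energy model of this process as
a tested, reusable pipeline for biophysicists and quantitative cell
biologists:

* **Affinity → adhesion energy.** Multivalent binding of a particle
  (scaffold radius *R*<sub>p</sub> = 15 nm, 180 sites) to lipid-anchored
  receptors produces an effective adhesion potential
  *V*(*l*) = −*U* exp[−(*l* − *l*₀)²/(2σ²)] with preferred separation
  *l*₀ = 8 nm and spread σ = 1 nm derived from the receptor–ligand
  geometry, and depth *U* = (*k*<sub>B</sub>*T*/*A*) ln([R]/ξ*K*<sub>D</sub>)
  set by the receptor affinity (*A* = 4π*r*²/180 ≈ 37 nm² with wrap radius
  *r* = *R*<sub>p</sub> + *l*₀ = 23 nm).
* **Wrapping threshold.** Wrapping beats the Helfrich bending cost above
  *U*<sub>t</sub> = 2κ/*r*²; at κ = 20 *k*<sub>B</sub>*T* and
  [R]/ξ = 16,300 nM the threshold affinity is
  *K*<sub>D</sub>* ≈ 1000 nM.
* **Shape mechanics.** Discretized axisymmetric membrane profiles with
  validated bending/adhesion energy functionals (sphere = 8πκ, cylinder =
  πκ*L*/*R*, catenoid ≈ 0).
* **Constrained minimization.** Minimum-energy shapes for single-particle
  wrapping and for joint wrapping in periodic membrane tubules
  (augmented-Lagrangian solver with analytic gradients, 5 nm neck
  constraint), giving the per-particle energy gain of tubulation.
* **Threshold inference.** A maximum-likelihood two-plateau change-point
  estimator for yes/no membrane-deformation tables across an affinity
  panel.
* **Colocalization.** Object-based overlap quantification for two-channel
  z-stacks (Otsu segmentation, overlap pixels / particle pixels,
  slice → cell → replicate aggregation).
* **Synthetic data.** Seeded generators for affinity panels, binary
  outcome tables and two-channel spot images with ground truth, so the
  whole pipeline is testable without any download.

## Worked example

```r
library(memwrap)

# Where does a 600 nM receptor sit relative to the wrapping threshold?
binding_condition(KD = 600)
#> Binding condition
#>   KD      : 600 nM (rho = 16300 nM)
#>   U       : 0.08941 kBT/nm^2
#>   U_t     : 0.07561 kBT/nm^2 (kappa = 20 kBT, r = 23 nm)
#>   KD*     : 998.6 nM
#>   regime  : wrapped (U > U_t)
```

600 nM is just above threshold (*U* > *U*<sub>t</sub>): membrane
deformation is favorable. Simulating a deformation assay over the default
7-condition panel (36 pM – 23 mM) and inferring the threshold:

```r
tab <- simulate_outcomes(gen_affinity_panel(), outcome_truth(), seed = 1)
estimate_threshold(tab)
#> Deformation threshold: KD_hat = 1510 nM (gap 600 - 3800 nM)
#>   plateaus: p_high = 0.904, p_low = 0.100; logLik = -13.181
```

The estimator localizes the yes/no transition to the 600–3800 nM gap —
the conditions flanking the theoretical *K*<sub>D</sub>* ≈ 1000 nM. The
tubulation energetics at a wrapped affinity:

```r
gain <- tubule_gain(binding_condition(600), n_segments = 200, seed = 1)
as.numeric(gain)  # ~36 kBT: joint wrapping in a tubule is clearly favorable
```

And the imaging arm, on synthetic ground truth:

```r
st <- gen_coloc_stack(image_truth(overlap = 0.5), seed = 1)
attr(coloc_stack(st$particle, st$organelle), "aggregate")
#> [1] 0.4921855   # programmed overlap 0.5 recovered within 0.01
```

See `vignette("wrapping-energetics")` for the model, discretization,
solver and design choices.

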