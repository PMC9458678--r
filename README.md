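# saxsens: SAXS-restrained conformational ensemble reweighting

Flexible multidomain proteins — for example the catalytic RBR module of the
E3 ubiquitin ligase HOIP, three zinc-binding subdomains (RING1, IBR,
RING2) joined by two flexible linkers — do not adopt a single structure in
solution. A small-angle X-ray scattering (SAXS) curve measured on such a
protein is an ensemble average, and a crystal conformation often fits it
poorly. `saxsens` implements the a-posteriori reweighting workflow that
reconciles a conformational ensemble (e.g. from molecular dynamics) with a
measured SAXS curve, in two complementary flavours:

* **Maximum parsimony (BSS-SAXS).** Conformers are clustered twice — first
  density-based (HDBSCAN\*) on pairwise C-alpha distance features, then
  Ward-linkage on their scattering profiles under the error-weighted
  dissimilarity chi²(i,j) = Σ\_q [(I_i − I_j)/σ]² — to yield a small
  *basis set* K of conformationally unique, experimentally distinguishable
  states. Weights over the basis follow the Bayesian posterior
  P(w | data) ∝ exp(−chi²(w)) with
  chi²(w) = Σ\_q [(I_exp − c·Σ\_k w_k I_k)/σ]², the scale c profiled by its
  closed form, sampled by Metropolis Monte Carlo on the simplex
  (51,000 steps, 1,000 burn-in).
* **Maximum entropy.** All conformers keep a weight; the negative
  log-posterior L(w) = θ·S_KL(w‖w⁰) + chi²(w)/2, with
  S_KL = Σ\_k w_k ln(w_k/w⁰_k), is minimised over the simplex at each θ of
  a scan, and the confidence parameter θ is chosen at the elbow of the
  (S_KL, chi²_red) L-curve. Conformers with weights more than one standard
  deviation above the mean are reported as significantly up-weighted.

Around this core the package provides a Debye-equation forward model
(unit / residue-bead / Cromer–Mann atomic form factors), primary SAXS
analysis (iterative Guinier fitting, dimensionless Kratky transform with
the globular x²·exp(−x²/3) and Gaussian-coil references, model-based P(r)
with Dmax), coordinate handling (multi-model PDB and XYZ, domain
definitions, composite-model assembly by Kabsch superposition and
grafting), weighted free-energy surfaces over interdomain collective
variables with difference landscapes and block-averaging errors, and a
synthetic multidomain generator with known ground-truth weights so the
whole pipeline is testable end to end.

Everything is tidyverse-flavoured: conformers and ensembles are atom
tibbles, curves are `(q, I, sigma)` tibbles, fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Recover a known two-state mixture (70% compact, 30% extended, 1% noise)
with both inference tracks:

```r
library(saxsens)

rec <- two_state_recovery(0.7, noise_fraction = 0.01, seed = 1)
rec$posterior
#> MaxPars posterior: K = 2, 50000 samples (35% acceptance)
#>   mean weights: 0.708 0.292
rec$lcurve
#> MaxEnt L-curve: 13 theta values, selected theta = 0.04642 (chi2_red = 1.258)
sprintf("MaxPars: %.3f  MaxEnt: %.3f", rec$p_maxpars, rec$p_maxent)
#> "MaxPars: 0.708  MaxEnt: 0.708"
```

Both tracks recover the true compact fraction 0.7 within 0.01. Primary
analysis of a single extended toy conformer:

```r
toy  <- generate_toy_ensemble(1, seed = 1, hinge = 180)   # fully extended
conf <- ensemble_frames(toy$ensemble)[[1]]
curve <- debye_curve(conf, seq(0.002, 0.25, length.out = 120))
guinier_fit(curve, qrg_limit = 1.0)
#> Guinier fit: Rg = 42.466 +/- 0.143 A, I(0) = 1.388e+05 (11 pts, qRg_max = 0.97)
pr_from_model(conf)
#> P(r): 133 bins of 1.00 A, Dmax = 132.77 A, Rg(P(r)) = 43.83 A
```

The P(r)-based radius of gyration equals the geometric one (43.83 Å)
exactly; the Guinier estimate sits ~3% below it, the expected bias of the
Guinier approximation for strongly elongated particles. A full pipeline run
over an ensemble file goes through `reweight_run()` (or the thin CLI
wrapper in `inst/cli/saxsens.R`), which writes per-frame weights,
diagnostics and the resolved configuration to an output directory.

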