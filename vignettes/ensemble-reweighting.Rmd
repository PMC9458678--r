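---
title: "Methods: SAXS-restrained ensemble reweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS-restrained ensemble reweighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsens)
```

## The problem and the model

A SAXS measurement on a flexible multidomain protein observes the
population-weighted average of the scattering of all conformations in
solution,
$$I_\mathrm{obs}(q) \approx c \sum_k w_k I_k(q),$$
where $I_k(q)$ is the orientation-averaged intensity of conformer $k$,
$w_k \ge 0$, $\sum_k w_k = 1$ and $c$ is an unknown multiplicative scale
(detector calibration, concentration, contrast). Given a candidate
ensemble — typically frames of an unbiased molecular-dynamics simulation —
the reweighting task is to infer $w$ such that the average matches the
measured curve within its errors $\sigma(q)$, without overfitting.
`saxsens` implements the two standard, philosophically opposite answers:

* **Maximum parsimony** compresses the ensemble to the smallest set of
  conformationally unique and experimentally distinguishable states (the
  *basis set*) and treats their weights as parameters of a Bayesian model
  with likelihood $\exp(-\chi^2(w))$,
  $\chi^2(w) = \sum_q [(I_\mathrm{exp} - c\,I_\mathrm{comp}(w,q)) /
  \sigma]^2$, and a uniform simplex prior. The scale is profiled at every
  evaluation by its weighted-least-squares closed form
  $c = [\sum I_\mathrm{exp} I_\mathrm{comp}/\sigma^2]
       [\sum I_\mathrm{comp}^2/\sigma^2]^{-1}$.
  The posterior is mapped by Metropolis Monte Carlo on the simplex and
  summarised by the columnwise mean and standard deviation.
* **Maximum entropy** keeps every conformer and minimises
  $L(w) = \theta\, S_{KL}(w \,\|\, w^0) + \chi^2(w)/2$ with
  $S_{KL} = \sum_k w_k \ln(w_k/w^0_k)$ relative to reference weights
  $w^0$ (uniform for an unbiased trajectory). The confidence parameter
  $\theta$ trades fit quality against perturbation of the reference and is
  selected at the maximum-curvature elbow of the $(S_{KL}, \chi^2_{red})$
  L-curve in log–log coordinates. Any constant factor in the $\chi^2$
  convention only rescales $\theta$, so the $1/2$ here is a convention,
  not a substantive choice.

## Forward model

Theoretical curves come from the exact Debye double sum
$I(q) = \sum_i \sum_j f_i(q) f_j(q)\, \mathrm{sinc}(q r_{ij})$ with the
$q r = 0$ limit taken as 1, so $I(0) = (\sum_i f_i(0))^2$ exactly. Three
form-factor models are available: *unit* (toy beads, every forward value
has an analytic oracle), *residue* (one bead per residue weighted by its
electron count) and *atomic* (four-Gaussian Cromer–Mann factors). There is
no hydration-shell term: the package's forward model is deliberately
parameter-free, and the contrast difference a hydration layer would
contribute at low q is absorbed into the fitted scale $c$. Absolute
$\chi^2$ values against curves fitted with shell-model programs are
therefore not comparable bit for bit; relative comparisons across
conformers, which drive all inference here, are unaffected.

## Primary analysis

The Guinier fit regresses $\ln I$ on $q^2$ (weights $(I/\sigma)^2$ from
error propagation), starting from the 20 lowest usable points and growing
or shrinking the window until $q_{max} R_g \le 1.3$ (configurable; the
conventional validity limit). The first non-positive intensity truncates
the usable range; an exactly flat curve yields $R_g = 0$, and a rising
low-q slope is an error rather than a silent $R_g = 0$. The dimensionless
Kratky transform $(qR_g)^2 I/I(0)$ against $qR_g$ is reported with the
globular reference $x^2 e^{-x^2/3}$ (peak at $(\sqrt3, 3/e)$) and the
Gaussian-coil reference $2/x^2 [e^{-x^2} + x^2 - 1]$. The pair-distance
distribution is computed from coordinates (a $f_i(0)f_j(0)$-weighted
histogram of pairwise distances, area-normalised, 1 Å bins by default) —
not by indirect Fourier transform of the data, which needs a
regularisation apparatus out of scope here. Its radius of gyration uses
the total-weight normalisation
$R_g^2 = \sum_{i<j} w_i w_j r_{ij}^2 / (\sum_i w_i)^2$, which coincides
with the geometric $R_g$ for any number of scatterers, including the
two-point case where the off-diagonal-only convention would be $\sqrt2$
too large.

## Two-step clustering and its parameters

Structural clustering runs the HDBSCAN\* algorithm (implemented in full:
mutual-reachability distances, minimum spanning tree, condensed tree,
excess-of-mass selection) on per-frame vectors of pairwise C-alpha
distances over the three core domains. These features are invariant under
rigid-body motion, so no trajectory alignment is needed. The minimum
cluster size is 5 frames (protocol default); frames in low-density regions
get label −1 and are discarded. Cluster representatives minimise the
summed pairwise feature-RMSD score $\sum_i R_{ij}$, ties broken to the
lowest frame index. The monotone relation between RMSD and summed squared
differences means either reading of the score selects the same member;
RMSD proper is implemented.

Profile clustering compares representative curves with the per-point
normalised $\chi^2(i,j)/N_q$ after scaling each profile to unit intensity
at the lowest q (and the errors by the profiles' common forward
intensity), agglomerates with Ward's linkage and cuts the tree at 0.15.
The normalisation behind the 0.15 threshold is not uniquely determined by
the protocol it follows; threshold, normalisation and linkage are all
arguments. Per cluster, the profile nearest the cluster mean becomes the
basis member — a deterministic, oracle-checkable choice.

## Samplers and optimisers

The Metropolis proposal transfers $\delta \sim U(-s, s)$ between two
uniformly chosen weight components; it is symmetric, keeps the simplex sum
exactly, and rejects moves leaving $[0,1]$. The half-width $s$ is tuned
during burn-in towards 25–45% acceptance (factor 0.8/1.25 every 100
steps, clamped to $[10^{-4}, 1]$) and then frozen so the post-burn-in
chain is a proper Metropolis chain. Defaults are 51,000 steps with 1,000
burn-in; the seed is an argument and is recorded in the result.

The MaxEnt objective is minimised by BFGS in log-weight coordinates with
the softmax back-transform and the analytic gradient
$\nabla_g L = w \circ (v - \langle w, v\rangle)$,
$v = \theta(\ln(w/w^0)+1) + c^2 Bw - cA$ (checked against finite
differences in the tests). The scale $c$ is profiled inside the objective
by its closed form — by the envelope theorem the gradient is unchanged at
the profiled $c$ — and outer rounds (10 by default) re-estimate and
confirm it; convergence is a relative $L$ change below $10^{-10}$. Two
numerical safeguards matter: the first quasi-Newton step is damped to
O(1) in log-weight units (an undamped step of size $\|\nabla\|$ can jump
to a simplex vertex, a spurious stationary point of the softmax
parameterisation), and a vertex-escape restart pulls back halfway to the
reference if a vertex is reached anyway. The $\theta$ scan (default 13
log-spaced points, $10^{-2}$–$10^6$) runs from the largest $\theta$
downwards, warm-starting each solve, which also makes the monotone
regularisation path ($S_{KL}$ down, $\chi^2$ up with $\theta$) a cheap
invariant to assert.

Significant conformers are those with $w_k$ above the mean plus one
*population* standard deviation, with strict inequality — uniform weights
therefore select none.

## Landscapes and errors

Free-energy surfaces are weighted 2-D histograms over the two interdomain
center-of-mass distances, converted by $F = -k_BT \ln(h/h_{max})$ so the
most populated bin sits at zero; empty bins are masked (NA), never zero.
Default binning is 40×40 over the observed range padded 2%; units are
$k_BT$ (dimensionless) by default or kcal/mol at the stated temperature
(300 K, the usual simulation temperature). Difference landscapes subtract
surfaces bin by bin where both are occupied. Statistical errors of
time-series observables use block averaging over doubling block sizes,
reporting the maximum blocked standard error among sizes retaining at
least 8 blocks — a conservative, deterministic plateau rule.

## The synthetic generator

`generate_toy_ensemble()` emulates the architecture the pipeline targets:
three rigid bead domains (53/46/203 beads, matching the residue counts of
an RBR module with its C-terminal extension; radii $3.15\,n^{1/3}$ Å,
protein-like packing) joined by two straight bead linkers (44 and 27
beads), with one hinge angle at the central domain and one twist dihedral
per frame. Arm extensions (22 and 31 Å beyond touching spheres) were set
once so that the fully folded hinge gives an overall $R_g$ near 26 Å and
the fully extended one near 44 Å — the compact↔extended continuum of an
RBR-scale protein, with extended interdomain distances near the
crystallographic extended conformation. Bead templates are fixed per seed,
so all frames share one topology, and output is byte-reproducible given
the seed. Synthetic observations add independent Gaussian noise with
$\sigma(q) = \nu [I(q) + 0.005\,I(q_{min})]$ at noise fraction $\nu$; the
floor keeps $\sigma$ positive in the weak high-q tail. At $\nu = 0$ the
curve is the exact mixture and $\sigma$ is a tiny sentinel so downstream
fits remain defined.

What the toys do *not* emulate: atomic detail and side chains, excluded
volume and hydration contrast, force-field-specific conformational
statistics, inter-frame correlation of a real trajectory, and q-dependent
error structure of a real detector. Passing the recovery suites therefore
demonstrates correctness of the estimators under a known truth, not
end-to-end accuracy on experimental data.

## Problem sizes used in the checks

The validation suites run at deliberately modest sizes: 50-bead conformers
against the direct $O(N^2)$ Debye sum, a 4,000-bead uniform ball for the
closed-form $P(r)$ radius, 50,000-step Metropolis chains against 1-D grid
quadrature, 20 random two-state toys for the $\theta \to 0$ oracle, a
20-seed replication of the two-state recovery, and a 50-conformer
sparse-truth maximum-entropy benchmark (150 q-points, 1% noise).

## Known limitations

* Per-conformer weight recovery by maximum entropy is limited by profile
  degeneracy: conformers adjacent on the hinge continuum have SAXS curves
  indistinguishable within 1% noise, so the KL-regularised solution
  spreads each true state's weight over its neighbours. The recovered
  weights locate the correct regions of the landscape (and the elbow
  $\chi^2_{red}$ is statistically consistent), but the per-conformer
  Pearson correlation with a sparse truth saturates below the 0.9 mark —
  the acceptance suite documents this at its fixed seed, and the
  acceptance script reports the computed correlation. Identifying
  *distinguishable* states before weighting them is precisely the job of
  the maximum-parsimony basis-set construction.
* Density-based structural clustering presumes trajectory-dense sampling;
  on a small set of independently drawn conformers every frame is its own
  state and the profile-clustering step alone defines the basis.
* The forward model omits the hydration shell; absolute $\chi^2$ against
  shell-model programs differ systematically (the scale absorbs most of
  the discrepancy at low q).
* Composite-model assembly grafts rigid fragments; it does not rebuild
  missing loops, so metrics that require a closed loop are computed from
  the superposed fragments.
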