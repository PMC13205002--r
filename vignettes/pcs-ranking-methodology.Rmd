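---
title: "Modeling and scoring electrotactile electrode configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and scoring electrotactile electrode configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsrank)
```

## The problem

Fingertip electrotactile interfaces deliver spatial touch cues through small
disc-electrode arrays, but the electrode geometry that gives one user crisp,
well-localized sensations can feel blurry or uncomfortable to another.
Finding the right diameter--spacing combination by exhaustive psychophysical
testing of a 36-candidate grid takes on the order of two hours per person.
`pcsrank` implements a subject-informed screening pipeline: from four easily
measured descriptors (sex, age, height, weight) it simulates the electric
field and afferent-fiber response for every candidate geometry, condenses
each simulation into the Perceived Correctness Score (PCS), learns a
regressor from PCS-labeled simulations, and ranks the candidates so that
only a short Top-k list needs behavioral verification.

## Candidate space

Candidates are 3 x 2 arrays of circular electrodes with diameter $D \in
\{2.0, \dots, 4.5\}$ mm and edge-to-edge gap $Q \in \{0.5, \dots, 3.0\}$ mm
at 0.5 mm steps --- 36 configurations labeled `DxQy`. Centres sit on a
uniform grid with pitch $D + Q$ in both axes (the source text does not state
whether row and column pitches differ; a uniform pitch is the simplest
reading consistent with the array drawings). The array's coverage area is
taken as the bounding rectangle $(2D + Q)(3D + 2Q)$, which reproduces both
published endpoints (0.315 and 2.34 cm$^2$) exactly. Enumeration order is
fixed (D-major) so that ranking ties always break identically.

## Tissue model

The fingertip is a planar four-layer slab: stratum corneum, viable
epidermis, dermis, subcutaneous tissue, with fixed thicknesses 0.029, 0.089,
1.380 and 3.500 mm. Each layer's conductivity follows a Cole-Cole
dispersion,

$$\sigma_c(f) = \frac{\sigma_\infty}{1 + (j\omega\tau)^{1-\alpha}} +
\sigma_0,$$

implemented exactly in this printed form. Note the naming tension: in this
form $\sigma_\infty$ enters the *low*-frequency limit
($\sigma_c(0) = \sigma_\infty + \sigma_0$) and the conductivity decreases
with frequency toward $\sigma_0$. We keep the formula as printed rather than
"fixing" it, since all downstream quantities are internally consistent.
Baseline parameter values per layer are not published for this model; the
defaults in `inst/extdata/default_config.yaml` are representative low-kHz
skin-layer values from the dielectric-dispersion literature (a highly
resistive stratum corneum around $2\times10^{-4}$ S/m, epidermis/dermis
around 0.2--0.3 S/m, subcutaneous fat around 0.03 S/m). They are data, not
code, and can be replaced wholesale through the run configuration.

The quasi-static solve uses a single effective frequency
$f_{\mathrm{eff}} = 1/(2 \times \text{phase width}) = 5$ kHz for the 100 us
biphasic phases --- the dominant spectral content of a rectangular phase ---
and the *real part* of $\sigma_c$ (conduction current dominates in the
quasi-static regime). Relative permittivity is carried in the layer type but
unused by the default conduction-only solver.

**Personalization.** How descriptors map to tissue parameters is not
identified by any published equation, so the package uses a deliberately
simple, monotone, clamped multiplicative factor

$$g = \mathrm{clamp}\!\left(1 + a_1\tfrac{\mathrm{bmi}-22}{22} +
a_2\tfrac{\mathrm{age}-25}{25} + a_3(\mathrm{sex}-0.5),\; 0.5,\; 1.5\right)$$

applied to every layer's $\sigma_\infty$ and $\sigma_0$ (defaults $a_1 =
0.15$, $a_2 = -0.05$, $a_3 = 0.05$). Geometry is never personalized; the
published model also holds thicknesses fixed. The factor is smooth and
testable, and because it scales all layers equally, it leaves
scale-invariant quantities (the focusing ratio, the descriptor-balance
term) untouched while shifting field magnitudes and the membrane-potential
peak --- which is exactly the kind of inter-individual variation the
recommender is meant to absorb.

## Field solver

The potential obeys $\nabla\!\cdot\!\sigma\nabla\Phi = 0$ on a voxelized
slab, discretized with a cell-centred finite-volume scheme and
harmonic-mean face conductances; vertical cell edges are aligned to the
layer interfaces so no cell straddles two tissues. Current enters as a
uniform Neumann flux over the active disc footprint and leaves through the
grounded bottom face (Dirichlet $\Phi = 0$), a monopolar-with-distant-return
abstraction; a run-configuration switch instead designates one array disc
as the return. The geometry is a rectangular slab rather than a curved 3-D
finger: layering and electrode geometry, which drive the score, are
preserved at desk scale.

The linear system is symmetric positive definite and is solved with a
sparse Cholesky factorization (exact to machine precision and
deterministic); the relative residual is still computed and stored in every
`potential_field`, and the discrete formulation conserves current through
every horizontal cut by construction. The field is the central-difference
negative gradient, and three magnitude summaries are taken over the region
below the stratum corneum (where the innervated layers lie, and where
contact-edge cells cannot dominate the maximum): $E_{\max}$, the
volume-weighted mean $E_{\mathrm{avg}}$, and the volume integral
$E_{\mathrm{int}} = \sum |E|\,\mathrm{d}V$. Which electrode(s) were driven
and at what amplitude during the published feature-extraction runs is not
stated; the package drives a single central electrode at 2 mA (within the
0--10 mA device range) by default, both configurable.

Default resolution is 0.7 mm laterally with (2, 2, 6, 7) vertical cells per
layer (~20k unknowns, about a second per solve). Doubling the lateral
resolution moves the three field features by a few percent on reference
cases without reordering configurations; the default is chosen so a full
5-subject x 36-configuration training build completes in a few minutes.

## Neural response

A-beta afferents are modeled SENN-style as chains of nodes of Ranvier
coupled by axial conductances. The governing equation is the *passive*
linear cable

$$\frac{dV_n}{dt} = \frac{1}{C_m}\left[G_a\,\Delta^2(V + V_e)_n -
G_m V_n\right],$$

where $\Delta^2$ is the axial second difference with sealed ends and the
extracellular potentials $V_{e,n}(t) = \Phi(x_n)\,i(t)/I_{\mathrm{solve}}$
(quasi-static separability) enter through their second difference --- the
activating function. The published equations are passive even though the
surrounding text speaks of action potentials; we implement the printed
model literally and define *activation* as the absolute membrane potential
$v_{\mathrm{rest}} + V_n$ crossing $V_{\mathrm{th}} = -55$ mV from
$v_{\mathrm{rest}} = -70$ mV. Spike shape is never needed: the score only
consumes the peak $V_{\mathrm{peak}}$ and its time $T_{\mathrm{peak}}$.

Cable constants come from classical SENN values recorded in the default
configuration: 9 um fiber diameter, internode spacing 100 x diameter
(0.9 mm), axoplasm resistivity 110 ohm cm, nodal capacitance 2 uF/cm$^2$,
nodal conductance 30.4 mS/cm$^2$, nodal gap 2.5 um; hence
$G_a = \pi d^2 / (4\rho_i L)$ and nodal area $\pi d \times$ gap. One fiber
is placed mid-dermis (0.8 mm) under the array centroid along the
3-electrode axis, with 21 nodes; the published model does not quantify
fiber count or placement. Integration is classical fixed-step RK4 ---
explicit and deterministic --- with the stability precondition
$dt \le 0.1\,C_m/(G_m + 2G_a)$ enforced; trajectories on small cables match
a dense adaptive ODE reference to $10^{-6}$ relative.

Under these constants and a 2 mA drive, peak depolarizations are large and
the logistic activation weight saturates near 1 for most configurations;
ranking is then driven mainly by the focusing and balance factors. This is
a faithful consequence of the printed passive model, not a tuning choice,
and is worth knowing when interpreting component values.

## The score

$$\mathrm{PCS} = w_{\mathrm{neuro}} \times u_{\mathrm{pattern}} \times
\ln(1 + E_{\mathrm{focus}})$$

with $E_{\mathrm{focus}} = E_{\max}/(E_{\mathrm{avg}} + 10^{-9})$,
$w_{\mathrm{neuro}} = 1/(1 + e^{-(V_{\mathrm{peak}} - V_{\mathrm{th}})k})$
($k = 0.05$ mV$^{-1}$), and $u_{\mathrm{pattern}} = 1/(1 + C)$ where $C$ is
the $n = 3$ population coefficient of variation of $(|E_{\max}|,
|E_{\mathrm{avg}}|, |E_{\mathrm{int}}|)$. Three reading decisions, all
ranking-neutral or explicitly prescribed: the logarithm is natural (any
base rescales scores monotonically); $C$ mixes quantities with different
units and is computed literally on raw SI magnitudes as prescribed, with an
off-by-default pre-normalization switch; and all-zero descriptors define
$C = 0$ (the composite is zero anyway through $E_{\mathrm{focus}}$).

## Recommender

Each subject--configuration pair yields one training sample with the fixed
9-component feature vector $(E_{\max}, E_{\mathrm{int}}, E_{\mathrm{avg}},
V_{\mathrm{peak}}, T_{\mathrm{peak}}, \mathrm{Height}, \mathrm{Weight},
\mathrm{Age}, \mathrm{sex})$ and the computed PCS as label: 5 training
subjects x 36 configurations = 180 samples. Ten candidates are compared by
seeded shuffled 5-fold cross-validated MAE: linear regression; KNN with
$k = 1, 3, 5, 7$; random forests with 100, 300, 500 trees; gradient
boosting with (100 rounds, learning rate 0.1, depth 3) or (200, 0.05, 4).
Features are standardized inside each training fold for LR and KNN only;
tree models see raw features. Whether the published folds were grouped by
subject is unstated; the default is a plain shuffle, with a
group-by-subject mode available for leakage-sensitivity checks. The final
model is trained on all samples with squared-error loss. For a new subject
the pipeline always *regenerates* simulation features (descriptors alone
are not enough input to the regressor), predicts PCS for all 36 candidates
and returns the full descending ranking with Top-1/Top-5 sets, ties broken
by enumeration order.

## Synthetic psychophysics

Human verification data are external to this package, so the generator
emulates the experiment's statistical structure: 5-alternative pattern
recognition (chance 0.2), 15 trials per configuration (5 patterns x 3
repeats), per-configuration success probability

$$p = \mathrm{clip}\!\left(0.2 + 0.8\,
\mathrm{logistic}(\beta_0 + \beta_1 z),\; 0.2,\; 0.95\right)$$

with $z$ the standardized PCS, and binomially drawn correct counts. The
defaults were fixed once: $\beta_0 = 0.3$ puts the group mean accuracy near
the observed overall level (about two-thirds correct), $\beta_1 = 1$ plants
a clear positive PCS--accuracy link, and the 0.95 cap reflects that ceiling
performance (15/15 throughout) was not observed. Cohort descriptors are
drawn uniformly from the study population's ranges (age 22--27 y, height
165--180 cm, weight 50--82 kg, sex Bernoulli(0.5)). What the generator does
*not* model: per-pattern confusion structure, adaptation, fatigue, or
contact-impedance drift. Passing end-to-end tests therefore demonstrates
that the pipeline recovers a planted monotone PCS--accuracy link under
binomial trial noise --- not that PCS predicts human perception; that claim
can only be tested against the deposited behavioral dataset, which the
evaluation module ingests directly (trial-level or aggregate CSV).

## Evaluation

Against behavioral records the package reports: the Pearson correlation
(with its t-transform p-value, reported but never used as a gate) between
mean predicted PCS and mean accuracy across the 36 configurations;
per-subject rank of the measured-best configuration, with Top-1/Top-5
rates; threshold pruning that excludes configurations with group mean
accuracy < 61.5% *and* maximum per-subject accuracy < 80%; and the
configuration-time saving $100(1 - t_{\mathrm{rec}}/t_{\mathrm{exh}})$,
rounded half-up to one decimal for presentation (raw values retained).
Per-configuration accuracy is the unweighted mean over subjects.

## Numerical and degenerate-input conventions

Zero injected current returns an identically zero potential and zero field
features, and PCS is zero exactly when $E_{\mathrm{focus}} = 0$. Activation
uses the $\ge$ convention at threshold. Interpolated potentials are
trilinear on cell centres and nodal-exact. The cable integrator refuses
steps above the stability margin and fails loudly on divergence instead of
returning artifacts. All randomness (fold shuffles, tree fits, cohort
sampling, binomial draws) flows from explicit integer seeds; reruns with
identical configuration and seed are bit-identical.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the default solver grid
(0.7 mm lateral, 17 vertical cells) for the 5-subject training build and
the 6-subject verification cohort, a coarser grid (1.4 mm) for structural
pipeline tests, and 20 seeded replicates for the planted-link recovery
check. These sizes were chosen as the package's own desk-scale reference
configuration; larger grids refine the field features without reordering
the candidate rankings in our convergence checks.

## Known limitations

The slab geometry ignores finger curvature and the true 3-D current return
path; the passive cable cannot produce refractory or strength--duration
phenomena; the descriptor-to-conductivity mapping is a modeling convention,
not an identified physiological relation; and the activation weight
saturates under the default drive, concentrating discrimination in the
field-derived factors. All four are consequences of staying faithful to the
published model description at desk scale.
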