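---
title: "Quantifying kinase allostery from multi-state chemical shifts and calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kinase allostery from multi-state chemical shifts and calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## The scientific problem

Protein kinase A's catalytic subunit is a K-type cooperative enzyme: binding
of nucleotide at the active-site cleft raises the affinity of the
substrate-binding groove for pseudo-substrate, and this positive cooperativity
is transmitted through an internal network of allosterically coupled residues.
Pathogenic variants — including the oncogenic chimera in which a heat-shock
protein J-domain replaces part of the N-terminal helix — can leave structure
and turnover essentially intact while degrading this internal communication
and, with it, the binding cooperativity.

`allokin` implements the analyses needed to measure both sides of that
statement from solution data:

* **thermodynamics** — the cooperativity constant
  $\sigma = K_d^{\text{apo}} / K_d^{\text{nucleotide}}$ from isothermal
  titration calorimetry, with the titration curves fit to the analytic 1:1
  (Wiseman) isotherm;
* **structure-wide coupling** — chemical-shift covariance analysis (CHESCA)
  across a series of ligation states, at residue and community resolution;
* **conformational equilibrium** — PCA-based placement of each ligation state
  on a one-dimensional open↔closed coordinate (CONCISE), mapped to percent
  closed and a free-energy scale;
* **kinetics** — Michaelis–Menten fits with propagated catalytic-efficiency
  errors, to verify that turnover is only marginally affected.

A synthetic-data generator with full ground truth stands in for the NMR/ITC
measurements, so every stage is validated end to end without external data.

## The models

### Chemical-shift perturbation

Amide shift changes between two states are combined as
$\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (0.154\,\Delta\delta_N)^2}$,
the standard weighting that equalizes the dispersions of the two nuclei.
Residues above the profile mean plus one standard deviation are flagged as
responders; the multiplier is exposed (`sd_multiplier`) because the
literature convention — SD about the mean, which we adopt — is not unique.

### CHESCA

For each residue observed in all four ligation states (apo, ADP-bound,
ATPγN-bound, ternary with the pseudo-substrate peptide), the per-state
$(\delta_H, 0.154\,\delta_N)$ points are mean-centered and projected onto
their first singular vector, giving a one-dimensional trace per residue. A
residue enters the analysis only if, for at least one pair of states and one
dimension, its shift change exceeds the mean of its two linewidths
($\Delta\delta_{x,y} > \tfrac12\Delta\nu_{xA,yA} + \tfrac12\Delta\nu_{xB,yB}$):
motion within the linewidth is not a resolvable response. The matrix of
absolute Pearson correlations between traces, thresholded at $|R| \ge 0.98$,
maps the allosteric network; per-residue correlation scores divide each
residue's partner count by a fixed denominator (the 350 residues of the
kinase, configurable) so scores are comparable between constructs.
Agglomerative clustering on $1 - |R|$ extracts coherent networks.

Whether correlations should be computed on ¹H-only, ¹⁵N-only or combined
traces is a genuinely open choice; we default to the single SVD-projected
trace because it makes $|R|$ well defined per residue pair and uses both
dimensions, and expose `combine = "H"`/`"N"` for the per-nucleus variants.

Community-level CHESCA aggregates the same matrix over predefined
structural/functional communities at a lower cutoff
($R_{\text{cutoff}} = 0.8$):
$R_{X,Y} = \#\{(i \in X, j \in Y): R_{ij} > R_{\text{cutoff}}\} / (n_X n_Y)$.
The published formula addresses cross terms; on the diagonal we count
unordered distinct pairs and normalize by $n_X(n_X-1)/2$ so that a fully
self-coupled community also scores 1. Communities left without scored
residues are reported as undefined (`NA`), never as 0 — absence of evidence
is not absent coupling.

### CONCISE

Each residue's four state points are projected onto their first principal
direction; residues whose first-to-second singular-value ratio falls below 3
(configurable) are excluded as non-linear responders. Retained traces are
standardized per residue so every residue votes with equal weight, flipped to
agree with the consensus direction (two passes: a provisional first-vs-last
orientation, then re-orientation against the consensus mean trace), and the
global sign is fixed by placing the apo state at the minimum. The pooled
scores of each state are summarized by their maximum-likelihood Gaussian
(sample mean and SD); the mean is the state's position ⟨PC⟩ on the
equilibrium coordinate, and the SD measures how coordinated the response is
(broader densities = less coordinated). Standardizing before pooling is our
choice — the pooling rule is not fixed by the method's description — and it
reproduces the expected qualitative layout (apo ≈ −1.2, binary ≈ 0,
ternary ≈ +1.2 on our synthetic data).

Positions are mapped to percent closed by linear interpolation between an
open reference (0%) and a closed reference (100%), and to free energy by the
affine map anchored at 0 kcal/mol (0% closed) and −15 kcal/mol (100%
closed). The −15 anchor is the summed wild-type binding free energy of the
two steps: $RT\ln K_d$ at 300 K gives −5.60 kcal/mol for nucleotide binding
(83 µM) and −9.33 kcal/mol for pseudo-substrate binding to the binary
complex (0.16 µM), hence ≈ −14.9 kcal/mol for the apo → ternary transition;
we therefore read the anchor in kcal/mol. Uncertainties propagate from the
Gaussian SDs. Values outside [0, 100]% are reported and flagged rather than
clipped.

### ITC and cooperativity

Per-injection normalized heats follow the analytic derivative of the 1:1
isotherm,

$$\frac{d[MX]}{d[X_{tot}]} = \Delta H^\circ V_0\left[\frac12 +
\frac{1 - \frac{1-r}{2} - R_m/2}
{\sqrt{R_m^2 - 2R_m(1-r) + (1+r)^2}}\right],$$

with $R_m$ the molar ratio and $r = K_d/[M]_{tot}$, implemented exactly in
this printed form. Its limits behave as required at the tight-binding start
(bracket → 1 at $R_m = 0$, $r = 0$) and at saturation (→ 0 as
$R_m \to \infty$); in the weak-binding limit $r \to \infty$ the bracket tends
to 1, i.e. a flat featureless isotherm. $(K_d, \Delta H^\circ)$ are fit by
Levenberg–Marquardt least squares with stoichiometry fixed at 1:1; several
$K_d$ starting values are tried and the best residual kept, which makes the
noiseless simulate→fit round trip exact to solver tolerance for $K_d$ from
0.1 to 500 µM at a 100 µM cell. $\Delta G = RT \ln K_d$ (R = 1.9872×10⁻³
kcal mol⁻¹ K⁻¹, T = 300 K), $T\Delta S = \Delta H - \Delta G$, and
$\sigma = K_d^{\text{apo}}/K_d^{\text{nucleotide}}$. Fold labels round half
away from zero, which reproduces every printed fold (2, 4, 7, 13) from the
measured dissociation constants.

### Kinetics

Initial velocities are fit unweighted to $v = V_{max}S/(K_M+S)$ (no published
weighting scheme; a `weights` argument is exposed), $k_{cat} = V_{max}/[E]$
requires the enzyme concentration as user input, and the relative error of
$k_{cat}/K_M$ is the quadrature sum of the component relative errors.

## The synthetic generator

The generator emulates fast-exchange titration behavior: networked residue
$i$ in state $s$ resonates at
$\delta_i(s) = \delta_i^0 + a_i\lambda_s + \varepsilon$, a linear response
along a latent closure coordinate $\lambda$ with residue-specific amplitude
$a_i$ and Gaussian measurement noise. Defaults define the study conditions
and are not tuned per analysis:

| parameter | default | why |
|---|---|---|
| states $\lambda$ | apo 0, ADP 0.45, ATPγN 0.55, ternary 1 | binary complexes sit near the middle of the equilibrium, ⟨PC⟩ ≈ 0 |
| residues | 100 | desk-scale stand-in for the ~340 assigned amides |
| networked fraction | 0.6 (contrast: 0.3) | dense wild-type-like vs sparse chimera-like network |
| response scales | 0.15 ppm ¹H, 0.8 ppm ¹⁵N | typical amide CSP magnitudes for a domain-closure transition |
| noise SD | 0.005 ppm ¹H, 0.025 ppm ¹⁵N | well-resolved TROSY peak positions |
| linewidths | 0.03 ppm ¹H, 0.15 ppm ¹⁵N | carried on every peak; drive the inclusion filter |
| non-networked motion | 2% of the response scale | non-responding residues move well within their linewidths |

Before noise, networked residues are pairwise perfectly collinear
(|Pearson| = 1), so ground-truth recovery is exact at zero noise; the filter
then retains exactly the networked set and every qualifying pair lies within
it. Non-networked residues receive independent per-state displacements rather
than zero motion so the filter is meaningfully exercised. A single seed
governs all draws, making outputs byte-stable.

What the generator does **not** emulate: peak overlap and assignment
ambiguity, chemical-exchange broadening, non-linear (multi-pathway) responses,
state-dependent linewidths, and correlated noise between the two dimensions.
Passing tests therefore demonstrate that the analysis chain recovers the
structure it assumes, not that real spectra satisfy those assumptions.

## Numerical choices and edge cases

* Zero-variance traces make Pearson undefined: those residues are dropped
  with a warning, never scored as 0.
* Perfectly collinear trajectories have $s_2 = 0$; linearity is reported as
  `Inf` and the residue admitted.
* Duplicate (residue, state) records, non-finite shifts and non-positive
  linewidths are integrity errors at construction time, so downstream code
  can assume a valid table.
* The isotherm fitter warns when the molar-ratio grid does not bracket the
  equivalence point and degrades gracefully (ΔH → 0, $K_d$ = NA) on all-zero
  heats; the Michaelis–Menten fitter warns when $K_M$ is driven to the zero
  boundary by saturated-only data.
* All tie-breaking (state order, residue order) follows the declared state
  order and ascending residue id; shuffling input rows changes nothing.

## Problem sizes

The bundled analyses and tests run on 20–100-residue tables, 4 states,
25-injection titrations and 6-point velocity series, with 20-seed repetition
for the stochastic recovery studies; a full run of the workflow under
`analysis/` completes in seconds.

## Known limitations

Correlations are computed on 1-D projected traces; genuinely 2-D responses
(curved trajectories) are excluded rather than modelled. The community score
treats all qualifying pairs equally regardless of |R| margin above the
cutoff. The ITC module fits normalized heats only — baseline correction,
dilution-heat subtraction and competitive or multi-site models are out of
scope. ⟨PC⟩ values from real deposited shift tables depend on peak-list
completeness and are not expected to match synthetic-data values numerically.
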