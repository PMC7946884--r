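# allokin

Chemical-shift covariance and conformational-equilibrium analysis of kinase
allostery.

## The problem

The catalytic subunit of protein kinase A is a positively cooperative (K-type)
enzyme: nucleotide binding raises the affinity for pseudo-substrate, a
property carried by an internal network of allosterically coupled residues.
Disease variants — such as the oncogenic chimera in which a J-domain is fused
to the catalytic core — can preserve structure and turnover while degrading
this network and its binding cooperativity. Quantifying that degradation
requires connecting three kinds of solution measurements:

* **ITC**: the cooperativity constant σ = K<sub>d</sub><sup>apo</sup> /
  K<sub>d</sub><sup>nucleotide</sup>, with each K<sub>d</sub> from a Wiseman
  (1:1) isotherm fit of the titration heats

  dQ/dX<sub>tot</sub> = ΔH°V₀ · [ ½ + (1 − (1−r)/2 − R<sub>m</sub>/2) /
  √(R<sub>m</sub>² − 2R<sub>m</sub>(1−r) + (1+r)²) ],
  r = K<sub>d</sub>/[M]<sub>tot</sub>

* **CHESCA**: the |Pearson| ≥ 0.98 correlation matrix of per-residue,
  SVD-projected shift trajectories across four ligation states (apo, ADP,
  ATPγN, ATPγN/PKI), after a linewidth-based responsiveness filter
  (Δδ<sub>x,y</sub> > ½Δν<sub>xA,yA</sub> + ½Δν<sub>xB,yB</sub>), plus
  per-residue correlation scores and community-level scores
  R<sub>X,Y</sub> = #(R<sub>ij</sub> > 0.8)/(n<sub>X</sub>·n<sub>Y</sub>)

* **CONCISE**: per-residue PCA placing each state at a position ⟨PC⟩ on the
  open↔closed coordinate, with per-state Gaussian densities, percent-closed
  interpolation and the affine free-energy map anchored at 0 kcal/mol (0%
  closed, apo) and −15 kcal/mol (100% closed, ternary)

plus Michaelis–Menten fits (k<sub>cat</sub>/K<sub>M</sub> with quadrature
error propagation) to confirm turnover is only marginally altered. A
ground-truth synthetic generator — networked residues moving linearly along a
latent closure coordinate, non-networked residues moving incoherently within
their linewidths — makes every stage testable without external data.

The package is aimed at structural biologists and biophysicists analyzing
multi-state NMR titration series and calorimetric binding data for allosteric
proteins.

## Worked example

```r
library(allokin)

# cooperativity from the measured dissociation constants (uM)
sigma_wt      <- cooperativity_sigma(17, 0.16)  # wild-type
sigma_chimera <- cooperativity_sigma(9, 1.1)    # J-domain chimera
sigma_wt
#> sigma = 106.2 (Kd apo 17 / Kd nucleotide 0.16 uM): 106-fold
sigma_chimera
#> sigma = 8.182 (Kd apo 9 / Kd nucleotide 1.1 uM): 8-fold
fold_change(sigma_wt$sigma, sigma_chimera$sigma)$fold
#> [1] 13

# simulate and re-fit a titration at the chimera's nucleotide Kd
iso <- generate_itc_isotherm(kd = 19, dH = -11, n_inject = 25, cell_conc = 100)
fit_isotherm(iso)
#> Wiseman fit: Kd = 19 uM, dH = -11 kcal/mol (residual 0)

# conformational equilibrium on synthetic four-state data
d   <- generate_shift_dataset(synthetic_shift_config(seed = 1))
res <- concise_scores(d$shifts)
res
#> CONCISE result: 72 residues, states apo -> ADP -> ATPgN -> ATPgN-PKI
#>       apo       ADP     ATPgN ATPgN-PKI
#>    -1.180     0.022     0.114     1.044
round(concise_free_energy(res)$ddg, 2)
#> [1]   0.00  -8.11  -8.73 -15.00
```

The σ values say nucleotide binding sharpens pseudo-substrate affinity
106-fold in the wild-type but only 8-fold in the chimera — a 13-fold loss of
binding cooperativity. The isotherm round trip recovers the generating
K<sub>d</sub> exactly. The CONCISE positions place apo at the open end,
the two binary complexes near the middle and the ternary complex at the
closed end of the equilibrium, and the free-energy column interpolates
between the 0 and −15 kcal/mol anchors accordingly.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # dense- and sparse-network datasets, ITC, kinetics
Rscript analysis/02_csp.R            # perturbation maps apo -> ternary
Rscript analysis/03_chesca.R         # correlation matrices, scores, communities, clusters
Rscript analysis/04_concise.R        # <PC>, densities, percent closed, ddG
Rscript analysis/05_cooperativity.R  # isotherm fits, sigma, fold changes, MM fit
```

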