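# fractIPR

Quantitative characterization of tissue texture in brightfield
transmission microscopy images, for researchers comparing structurally
"ordered" versus "disordered" cohorts (e.g. control versus disease
sections).  In thin stained sections the transmitted intensity tracks
local mass density and refractive index, `I(x,y) ∝ ρ(x,y) ∝ n(x,y)`, so
image texture statistics act as proxies for nanoscale structural
disorder.  The package computes four complementary families of such
statistics and ships a synthetic-image module with analytically known
ground truth so every estimator can be validated end to end.

## What it computes

* **Sub-box fractal dimension maps** — each standardized 512×512 image
  is binarized at a fraction of the dynamic range and cut into 32×32
  sub-boxes (16×16 = 256 per image); in each, the box-counting dimension
  `Df = ln N(ε) / ln(1/ε)` is fitted over dyadic scales ε ∈ {2,4,8,16}.
  Length-scale and threshold sweeps trace how group contrast depends on
  those choices (`fractal_map()`, `sweep_length_scale()`,
  `sweep_threshold()`).
* **Dimension transforms and distribution shape** — `ln Df` and the
  functional transform `Dtf = Df / (Dfmax − Df)` (with `Dfmax` the
  maximum dimension over the pooled image set), which stretches the
  right tail where dense, irregular texture lives; 70-bin histograms
  with polynomial smoothing and Gaussian fits summarize distribution
  shape (`functional_transform()`, `gaussian_fit()`).
* **Chhabra–Jensen multifractal spectra** — the singularity spectrum
  `f(α)` estimated directly from q-weighted box measures
  `μᵢ(q,ε) = Pᵢ^q / Σⱼ Pⱼ^q` via regressions over scale, no Legendre
  transform; spectrum width, peak and asymmetry quantify heterogeneity
  (`mf_spectrum()`, `spectrum_metrics()`).
* **Inverse participation ratio (IPR)** — each block becomes a 2-D
  tight-binding lattice `H = Σ εᵢ|i⟩⟨i| + t Σ⟨ij⟩(|i⟩⟨j| + |j⟩⟨i|)` with
  on-site energies `εᵢ = (I − I₀)/I₀`; after full diagonalization the
  mean `Σψ⁴` over all eigenfunctions (area-normalized so an extended
  state scores 1) measures how strongly intensity disorder localizes
  light.  Mean IPR grows with the structural disorder product
  `⟨dn⟩·lc` (`ipr_map()`, `group_ipr_stats()`).
* **Synthetic ground truth and reporting** — Sierpinski carpets and
  Vicsek crosses (exact dimensions), randomized multiplicative cascades
  (closed-form `τ(q) = −log₂ Σ pᵢ^q`), correlated Gaussian disorder
  fields (exact `dn`, `lc`), two-cohort study simulation, and
  control-versus-disease comparison tables (`make_cohorts()`,
  `compare_groups()`, `run_full_analysis()`).

## Worked example

A miniature simulated study (3 + 3 images at side 128 so it runs in
under a minute; defaults are 10 + 10 at side 512):

```r
library(fractIPR)

cfg <- run_config(n_per_group = 3, side = 128, seed = 42,
                  mfa_scales = c(4, 8, 16, 32))
bundle <- run_full_analysis(cfg)
print(bundle)
```

```
Group comparison (pooled sub-box values):
 metric control_mean disease_mean mean_difference mean_pct_difference
     Df       1.7737       1.8396         0.06589               3.715
   lnDf       0.5681       0.6067         0.03869               6.810
  lnDtf       2.4177       3.1640         0.74629              30.867
 control_std disease_std std_difference std_pct_difference
      0.1697     0.13347       -0.03621             -21.34
      0.1022     0.07556       -0.02660             -26.04
      1.0018     2.05637        1.05453             105.26

Multifractal width: control 0.0720, disease 0.2855

IPR group statistics:
   group  mean     std n_blocks
 control 2.847 0.03823       48
 disease 3.149 0.06731       48
```

Reading the output: the disease cohort (generated with stronger
intensity fluctuations, longer disorder correlation and more
heterogeneous cascade weights) shows a higher mean sub-box dimension,
and the percentage mean difference grows along the transform chain
`Df < lnDf < lnDtf` (3.7 % → 6.8 % → 30.9 %) — the functional transform
amplifies contrast near the maximum dimension.  Its multifractal
spectrum is about four times wider (0.29 vs 0.07), and its mean block
IPR is higher (3.15 vs 2.85) with roughly double the spread: light
localizes more strongly on the more disordered optical lattice.

Estimators can also be checked against exact fractals directly:

```r
sc <- sierpinski_carpet(5)                    # 243 x 243, dimension ln8/ln3
fit_dimension(box_count(sc, 3^(1:4)))
#> [1] 1.892789
```

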