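---
title: "Multiparametric texture metrics for tissue images: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric texture metrics for tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractIPR)
```

## The measurement model

In brightfield transmission microscopy of thin stained sections, the
recorded intensity at a pixel tracks how much light the tissue column
under it absorbed and refracted.  Both effects grow with local mass
density, which in turn sets the local refractive index.  To first order,

$$ I(x, y) \;\propto\; \rho(x, y) \;\propto\; n(x, y), $$

so the intensity raster is a noisy proxy for the spatial organization of
tissue mass.  Everything this package computes is a statistic of that
proxy: no segmentation, no stain model, no biological annotation.  Four
families of statistics are implemented because they are sensitive to
different aspects of disorganization.

### Box-counting fractal dimension maps

A standardized image (grayscale, bilinearly resized to $512 \times 512$)
is binarized at a fixed fraction of the dynamic range and cut into
$32 \times 32$ sub-boxes, 256 per image.  In each sub-box we cover the
foreground with grids of cell size $\varepsilon \in \{2, 4, 8, 16\}$ and
count occupied cells $N(\varepsilon)$; the ordinary least-squares slope
of $\ln N(\varepsilon)$ on $\ln (1/\varepsilon)$ is the box-counting
dimension

$$ D_f = \frac{\ln N(\varepsilon)}{\ln(1/\varepsilon)}, $$

clipped to $[0, 2]$ against floating-point noise.  The full-block scale
($\varepsilon = 32$, where $N \equiv 1$) carries no information and is
excluded from the fit.  A filled block gives exactly 2, a single pixel
exactly 0, and a level-5 Sierpinski carpet recovers
$\ln 8 / \ln 3 \approx 1.8928$ exactly at ternary scales.

Two conventions deserve a sentence each:

* **Foreground is the dark phase** (intensity strictly below
  `threshold_fraction * 255`), because optically dense, mass-rich tissue
  absorbs and appears dark in transmission.  `invert = TRUE` flips this
  for stains or modalities with the opposite polarity.
* **Degenerate blocks** (empty, or occupied at fewer than two scales)
  yield `NA`, and `NA`s are excluded from every mean and standard
  deviation.  Scoring them 0 would drag group means toward 0 in sparse
  images, which is a bias, not a measurement.

`sweep_length_scale()` and `sweep_threshold()` re-run the map across
block sides (32 ... 512) and threshold fractions, pooling all defined
sub-box values per group.  Pooling (rather than averaging per-image
means first) weights every sub-box equally; a per-image pathway is a
one-line change on the pooled vectors and both give the same group
ordering on the shipped synthetic cohorts.

### Transforms of the dimension and distribution shape

Group contrast in $D_f$ is often small because most tissue blocks sit in
a narrow band below the maximum recorded dimension
$D_f^{\max}$ (computed over the *pooled* analyzed set, both groups).
Two monotone transforms sharpen it:

$$ \ln D_f, \qquad
   D_{tf} = \frac{D_f}{D_f^{\max} - D_f}, \qquad \ln D_{tf}. $$

The functional transform diverges as $D_f \to D_f^{\max}$, so the block
that attains the maximum is kept finite by a guard,
$D_{tf} = D_f / (D_f^{\max} + \epsilon - D_f)$ with $\epsilon = 10^{-6}$
by default.  Because the transform is strictly increasing, sub-box rank
order is untouched; only spacing near the top is stretched.  For
dimensions in $(1, e)$ with the disease group sitting higher, the
percentage mean differences are automatically ordered
$D_f < \ln D_f < \ln D_{tf}$ -- the package's cohort tests verify this
ordering on simulated data rather than assuming it.

Distributions are summarized as 70-bin equal-width histograms,
optionally smoothed by a degree-8 least-squares polynomial (degree 8 is
a display choice: high enough for multi-lobed shapes on 70 bins, low
enough not to oscillate; it is a parameter, not a claim), and fitted
with a Gaussian by Levenberg-Marquardt nonlinear least squares started
at the histogram moments.  The reported `chi_square_score` is
$100 \,(1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot})$ clamped to
$[0, 100]$ -- an $R^2$-style goodness percentage.  This is a documented
convention of this package; other software may report a differently
normalized statistic under a similar name.

### Chhabra-Jensen multifractal spectrum

Heterogeneous tissue is better described by a *spectrum* of scaling
exponents than a single dimension.  With box masses
$P_i(\varepsilon)$ (box intensity sum over total intensity) and the
$q$-weighted measures

$$ \mu_i(q, \varepsilon) =
   \frac{P_i(\varepsilon)^q}{\sum_j P_j(\varepsilon)^q}, $$

the direct (Chhabra-Jensen) estimators are regression slopes over
scales:

$$ \alpha(q) = \frac{d}{d \ln \varepsilon} \sum_i \mu_i \ln P_i,
   \qquad
   f(q) = \frac{d}{d \ln \varepsilon} \sum_i \mu_i \ln \mu_i,
   \qquad
   \tau(q) = q\,\alpha(q) - f(q). $$

No Legendre transform is needed.  Weights are evaluated in log space so
$|q| \le 10$ is safe down to $P_i = 10^{-300}$; zero-mass boxes are
dropped (their $\ln P_i$ is undefined -- this is the standard treatment,
and it is why the estimator should run on the grayscale measure, not on
a binarized mask).  Two identities hold *exactly* by construction and
are asserted on every analyzed image: $\tau(1) = 0$ and
$f(\alpha(1)) = \alpha(1)$.  Defaults: $q \in [-10, 10]$ in steps of
0.5, dyadic scales $\{8, 16, 32, 64, 128\}$ on a 512 image.  Per-$q$
regression $R^2$ is recorded; low values flag measures that are not
scaling and whose spectrum should not be over-read.

The estimator is validated against randomized quadrant cascades, for
which $\tau(q) = -\log_2 \sum_i p_i^q$ is available in closed form; on
dyadic scales the multiset of box masses of a cascade is exact, so the
estimator agrees with the closed form to machine precision -- the
tolerance of 0.1 in the acceptance suite is in practice consumed only
when a disorder field perturbs the measure.

### Tight-binding IPR as a disorder meter

The optical analogy treats each $32 \times 32$ block as a 2-D lattice
for light.  On-site energies are relative intensity fluctuations
$\varepsilon_i = (I_i - I_0)/I_0$ with $I_0$ the block mean (zero-mean
by construction, invariant under global intensity rescaling), and the
Hamiltonian is

$$ H = \sum_i \varepsilon_i \lvert i \rangle\langle i \rvert
     + t \sum_{\langle ij \rangle}
       (\lvert i \rangle\langle j \rvert +
        \lvert j \rangle\langle i \rvert), $$

with nearest-neighbor hopping $t = 1$ (the energy unit) on an open
(hard-wall) lattice; blocks are independent.  After full
diagonalization, each unit eigenvector $\psi$ contributes
$\mathrm{IPR} = \sum_i \psi_i^4$, and all $N = L^2$ states enter the
block mean -- no energy windowing.  We *report* the area-normalized
value $L^2 \sum \psi^4$, so a fully extended state scores 1 and a
single-site state scores $L^2$; the raw convention is also returned.
Stronger or longer-ranged refractive-index disorder localizes
eigenfunctions and raises the mean IPR; within the perturbative regime
the mean scales like $\langle dn \rangle \cdot l_c$, the structural
disorder product.

Two numerical facts matter when interpreting small IPR values:

* The clean ($\varepsilon_i \equiv 0$) open 32-lattice has many
  degenerate eigenvalues.  A dense symmetric eigensolver returns an
  arbitrary orthonormal basis *within* each degenerate subspace, and
  those rotated combinations have a higher mean IPR (2.4502, the frozen
  reference constant of the test suite) than the separable sine modes
  (2.1157).  Infinitesimal disorder lifts the degeneracy and can
  therefore *lower* the mean IPR slightly before localization raises
  it.  The clean-lattice value is consequently a reference point, not a
  floor; the rigorous floor is 1 (area-normalized).
* The monotonicity of IPR in $\langle dn \rangle$ and $l_c$ is a
  statistical statement about ensemble means.  The test suite verifies
  it on 5-rung parameter ladders with white noise shared across rungs
  (coupled replicates, a variance-reduction device) and with 4 blocks
  per rung for the well-separated $\langle dn \rangle$ ladder and 8 for
  the finer $l_c$ ladder; at strong disorder ($\langle dn \rangle
  \gtrsim 0.3$ on a 32-site block) the $l_c$ dependence saturates and no
  monotone trend should be expected.

## The synthetic study

Real counterpart images of this kind (commercial tissue-microarray
cores) are not redistributable, so validation runs on synthetic cohorts
whose ground truth is known analytically:

* `sierpinski_carpet()` / `vicsek_cross()` -- deterministic fractals
  with exact dimensions $\ln 8/\ln 3$ and $\ln 5/\ln 3$.
* `multiplicative_cascade()` -- randomized quadrant cascades.  The
  weight-to-quadrant assignment is shuffled per cell so images look
  organic, but the box-mass multiset (hence the analytic spectrum) is
  unchanged.
* `disorder_field()` -- stationary Gaussian fields with exponential
  correlation $\exp(-r/l_c)$, sampled by circulant embedding on the
  torus and rescaled to an exact relative fluctuation $dn$.
* `make_cohorts()` -- a 10 + 10 control/disease study.  Each image is
  `clip(base * C * (1 + g), 0, 255)` with `C` the mean-1 cascade
  modulation and `g` the disorder field.  The disease preset has
  stronger fluctuations ($dn$ 0.12 vs 0.06), longer correlation
  ($l_c$ 6 vs 3) and more heterogeneous cascade weights
  ((0.29, 0.26, 0.24, 0.21) vs (0.265, 0.255, 0.245, 0.235)) at base
  intensity 170 -- chosen once so that, at the standard threshold 0.65,
  control images occupy the realistic sub-box dimension band
  (mean $D_f \approx 1.75$) without saturating blocks at exactly 2.

What the generator does *not* emulate is worth stating plainly: no
stain color, no nuclei or vessel morphology, no imaging artifacts, no
inter-patient variability beyond the seed.  Passing cohort tests
demonstrates that the estimators *detect the kinds of differences they
claim to measure* (density heterogeneity, multifractal breadth,
correlated disorder) at realistic effect sizes -- not that any
particular tissue type will show those differences.

### Problem sizes

Simulation sizes were set so a full validation run completes comfortably
on a single core: the default cohort side is 512 (matching the
standardization size), while the validation suite runs the same presets
at side 256 for fractal and multifractal statistics and side 64 for the
IPR companion cohorts, and ladders use single-block (32-pixel) fields.
The dominant cost is dense diagonalization of the $1024 \times 1024$
block Hamiltonians (about 0.3 s each); all other stages are orders of
magnitude cheaper.  Scaling the image side up changes none of the code
paths, only the runtime.

## Reporting conventions

`compare_groups()` reports means and **population** (divide-by-$n$)
standard deviations of pooled sub-box values, differences as disease
minus control, and percentage differences relative to the control
value.  Published comparison tables of this shape round at presentation
time; the package carries full precision and the bundled checks confirm
the arithmetic (e.g. a 0.4555 mean difference over a 1.7728 control
mean is 25.69 %).  `run_full_analysis()` binds the stages together and
is bit-reproducible given the configuration seed, which is also the
determinism contract the test suite enforces.

## Known limitations

* The box-counting fit uses four dyadic scales inside 32-pixel blocks;
  dimensions of very sparse blocks are noisy, and the `[0, 2]` clip is
  active on a few percent of blocks in realistic images.
* The Gaussian `chi_square_score` is a goodness percentage, not a
  p-value; it says nothing about normality in a hypothesis-testing
  sense.
* The functional transform inherits sensitivity to $D_f^{\max}$: a
  single saturated block ($D_f = 2$ exactly) pins the denominator, and
  many saturated blocks will dominate $\ln D_{tf}$ summaries.  Keep the
  threshold away from full saturation.
* IPR magnitudes depend on the normalization convention and on $L$;
  only comparisons within one convention and block size are meaningful.
* No inferential statistics are attached to group differences; the
  report layer describes, it does not test.
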