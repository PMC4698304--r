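---
title: "Petal optics with a Kubelka–Munk layer stack: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Petal optics with a Kubelka–Munk layer stack: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalkm)
```

## The model and its assumptions

A flower corolla is modelled as four optical layers, top (adaxial) to
bottom (abaxial): a reflecting upper surface, a pigmented tissue layer, an
unpigmented tissue layer, and a reflecting lower surface. Three physical
assumptions underlie everything in the package:

1. **Diffuse fluxes.** Light inside the tissue is assumed perfectly
   diffuse, so each homogeneous layer obeys two-flux (Kubelka–Munk)
   theory: two counter-propagating fluxes $I$ (down) and $J$ (up) with
   $dI/dx = -(K+S)I + SJ$ and $dJ/dx = (K+S)J - SI$, where $K$ and $S$ are
   the absorption and scattering coefficients. The closed-form solution
   for a slab, in terms of the dimensionless parameters $K^* = Kd$,
   $S^* = Sd$, is what `km_plate_rt()` evaluates, and the test suite
   verifies it against a direct numerical solution of the boundary-value
   problem (superposition shooting with `deSolve`), so the algebra is
   never taken on faith.
2. **Incoherent addition.** Layers exchange intensity, not amplitude: the
   stack observables come from summing the geometric series of
   inter-plate reflections (the adding equations, `combine_two()`).
   Interference and thin-film effects are outside the model.
3. **Symmetric single layers.** Each individual layer reflects and
   transmits identically from both sides. Stacks of such layers are
   generally *asymmetric* in reflectance — that is the whole point of the
   asymmetric pigmentation analysis — but remain exactly symmetric in
   transmittance. The package carries all four side-dependent observables
   (`r_top`, `t_down`, `r_bottom`, `t_up`) through every combination, and
   obtains bottom-illumination observables of a stack by reversing the
   layer list rather than through separate algebra, so one code path
   serves both sides.

Real petals violate assumption 1 near the illuminated epidermis (the
integrating-sphere beam is directional, and becomes diffuse only after the
first scattering events) and assumption 3 where pigment is granular; the
consequences show up as structured residuals when fitting measured
spectra, not as failures of the algebra.

## Parameters

| Parameter | Meaning | Unit | Default | Rationale |
|---|---|---|---|---|
| `r_surface` | reflectance of each surface | fraction | 0.03 | typical for a cell-wall/air interface (refractive index ≈ 1.4); assumed wavelength-independent |
| `S_u_star` | scattering parameter of the unpigmented layer | — | 0.1 | inter-vein petal tissue; 0.2 suits vein areas; 0 collapses the interior to one homogeneous pigmented layer |
| `S_p_star` | scattering parameter of the pigmented layer | — | 0.5 | long-wavelength asymptote of pigmented petal tissue |
| `d_pigmented`, `d_unpigmented` | effective layer thicknesses | µm | 40 | plausible epidermis/mesophyll thickness; only used to convert $K^*, S^*$ to mm⁻¹ coefficients |
| pigment template | Gaussian bands of $K^*(\lambda)$ | nm, — | (545, 45, 1.4) + (310, 35, 4.0) | a purple, anthocyanin-like pigment: green absorption peak at 545 nm with $K^*{=}1.4$, weak violet absorption, strong UV band |

`S_u_star` is an *assumption*, not a fitted quantity: the inverse problem
from two observables per wavelength ($R, T$) to two unknowns
($K_p^*, S_p^*$) is exactly determined only once the unpigmented layer is
fixed. Refitting the same spectra under different `S_u_star` values shows
the recovered absorption spectrum is robust to that choice while the
recovered scattering spectrum absorbs most of the difference — the basis
for trusting pigment estimates even when the tissue's scattering split is
uncertain.

## The inverse route

`fit_petal()` works per wavelength, in four exact algebraic steps — peel
the upper surface (`peel_top()`), solve for the symmetric middle layer
above the known unpigmented-layer-plus-lower-surface sub-stack
(`solve_symmetric_middle()`), invert the layer to $(K_p^*, S_p^*)$
(`km_invert_rt()`), convert to absorbance $D = \log_{10}(e)\,K_p^*$. There
is no iterative optimisation anywhere: each step is a closed form, so fit
and forward prediction close on each other to round-off
(≈ $10^{-12}$) on noiseless input. An analytic middle-layer solution and
an analytic KM inversion were chosen over 2×2 numerical root-finding
because they are exact, faster, and their degeneracies are enumerable (see
below); a numerical route must coincide wherever both are defined.

## Numerical choices

* **Forward branches.** $S^* = 0$ uses $r = 0$, $t = e^{-K^*}$ exactly;
  $K^* = 0$ uses the conservative closed form; $bS^* > 350$ (where `sinh`
  would overflow) uses the opaque-layer asymptote $r = 1/(a+b)$, $t = 0$.
* **Inversion degeneracies.** $r = 0$ maps to the pure absorber
  $(-\ln t, 0)$. $a \le 1 + 10^{-9}$ (non-absorbing within rounding,
  including inputs with $r + t$ marginally above 1) maps to the exact
  $K^* = 0$ limit $S^* = r/t$, avoiding the $b \to 0$ division. The
  arccoth is computed as $\tfrac12\ln\frac{x+1}{x-1}$ with its domain
  $x > 1$ enforced per wavelength; within the preconditions
  ($r + t \le 1$) the argument is provably $> 1$, so domain violations can
  only come from noise-corrupted inputs and yield flagged `NA`s, never an
  abort. Recovered $K^*$ in $(-10^{-9}, 0)$ is clamped to zero (rounding);
  anything more negative is flagged unphysical.
* **Unphysical totals.** $r + t > 1 + 10^{-9}$ raises an error in direct
  inversion, but inside the fit pipeline noise-inconsistent wavelengths
  are flagged invalid by `solve_symmetric_middle()` and counted per step;
  a fit where *every* wavelength fails raises a dedicated degeneracy
  condition (CLI exit code 3).
* **Resampling.** Spectra are linearly interpolated onto the working grid
  (default 300–700 nm at 1 nm, the UV–visible range of interest);
  extrapolation is never performed. Replicates are averaged arithmetically
  after resampling. No smoothing is applied to derived parameter spectra —
  smoothing would trade noise for bias invisibly, and callers can smooth
  afterwards if they choose.

## The synthetic-data generator

`make_pigment_kstar()` builds $K^*(\lambda)$ as a sum of Gaussian bands;
the default template puts the visible peak at 545 nm with amplitude 1.4
and a stronger band at 310 nm, emulating a purple petal that absorbs
green light strongly, violet weakly, and ultraviolet very strongly. The
UV band's width (35 nm) keeps its tail at 545 nm below $10^{-9}$, so the
default truth at the visible peak is 1.4 to better than that.
`make_scatter_sstar()` is constant by default (0.5), optionally with
troughs proportional to normalised absorption, mimicking the dips real
derived scattering spectra show where absorption is severe.
`simulate_measurement()` adds independent Gaussian noise truncated to
$[0,1]$, with an explicit seed (no global random state is consumed) —
a deliberately minimal instrument model.

What passing the generator-based tests shows: the inverse route exactly
undoes the forward model, is deterministic, and degrades gracefully
(unbiased at the visible peak within Monte-Carlo error at realistic noise).
What it does not show: correctness under directional illumination,
wavelength-dependent surface reflectance, spatially inhomogeneous
pigmentation, or instrument systematics (stray light, dark current) —
none of which the generator emulates.

## Design choices where the design was open

* **Surfaces in the same algebra.** The surface plates enter the same
  diffuse adding equations as tissue layers (reflectance 0.03,
  transmittance 0.97, no absorption), rather than a separate specular
  treatment — one consistent formalism, configurable per wavelength if a
  sensitivity study needs it.
* **Scenario bookkeeping.** The three pigment-distribution strategies
  conserve the per-wavelength totals $\sum K^*$ and $\sum S^*$ over
  interior layers: *asymmetric* = pigmented layer over unpigmented layer;
  *homogeneous* = one layer with $K^*$ and $S_p^* + S_u^*$; *symmetric* =
  two flanks with $K^*/2$ and $S_p^*/2$ around the unpigmented layer.
  Splitting the pigmented layer's scattering along with its pigment in the
  symmetric case is an assumption (the conservation constraint alone does
  not dictate where scattering sits); it is the choice that treats the
  flanks as literal half-thickness copies of the original pigmented layer.
* **Saturation metric.** The qualitative "more saturated" comparison is
  quantified as $1 - R(\lambda_{\max})/\max_\lambda R(\lambda)$, the
  relative depth of the reflectance trough at the absorption peak
  (default $\lambda_{\max} = 545$ nm): 0 for flat spectra, monotone in
  trough depth, and independent of overall brightness.
* **Noisy-recovery criterion.** Recovery under noise is asserted on the
  *mean* fitted $K_p^*(545)$ over seeded replicates (unbiasedness within
  a few percent), not per replicate: single-wavelength inversion under
  noise has irreducible per-replicate scatter, and the scientifically
  meaningful claim is the absence of systematic bias.

## Problem sizes

The test suite runs on 1–5-nm grids (81–401 wavelengths), 100–1000-plate
random property sweeps, and 100 seeded noisy-fit replicates; the whole
suite completes in a few seconds because every step is closed-form and
vectorised over wavelength. These sizes were chosen as the smallest at
which the asserted tolerances ($10^{-6}$–$10^{-12}$) are meaningfully
exercised across the full parameter range.

## Known limitations

* Two observables per wavelength cannot determine three unknowns:
  `S_u_star` must be assumed, and errors in it propagate mainly into
  $S_p^*$.
* At wavelengths where the petal is nearly opaque (deep UV with strong
  pigment), $t$ is tiny and the inversion amplifies noise strongly; those
  wavelengths carry the largest variance and are the first to be flagged
  invalid.
* The model has no angular resolution: it predicts hemispherical
  integrating-sphere observables only, not BRDFs, gloss, or the focusing
  effects of cone-shaped epidermal cells.
* Thicknesses enter only as a final scaling; the model cannot separate
  $K$ from $d$ without external anatomy.
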