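# petalkm

Kubelka–Munk layer-stack modelling of flower petal optics.

Many flowers keep their pigment in a single epidermal layer on the side a
pollinator sees, backed by unpigmented, strongly scattering tissue. `petalkm`
treats such a corolla as a stack of diffusely reflecting and transmitting
plates — an upper surface, a pigmented layer, an unpigmented layer, and a
lower surface — and provides both directions of the associated optics:

* **forward**: from layer parameters to the diffuse reflectance and
  transmittance spectra an integrating sphere would measure, for
  illumination of either petal side;
* **inverse**: from measured adaxial reflectance and transmittance spectra
  back to the pigmented layer's absorption and scattering parameter spectra
  and the pigment's absorbance spectrum.

It is aimed at researchers in flower coloration, plant tissue optics and
pollinator ecology who want quantitative pigment and scattering estimates
from integrating-sphere spectra without sectioning or extraction.

## The model

A homogeneous layer of thickness *d* with absorption coefficient *K* and
scattering coefficient *S* follows two-flux (Kubelka–Munk) theory. Its
diffuse reflectance and transmittance depend only on the dimensionless
parameters *K\** = *Kd* and *S\** = *Sd*: with *a* = 1 + *K\**/*S\**,
*b* = √(*a*² − 1) and *x* = *bS\**,

    r = sinh(x) / (a sinh(x) + b cosh(x))
    t = b       / (a sinh(x) + b cosh(x))

A non-absorbing layer reduces to *r* = *S\**/(1 + *S\**),
*t* = 1/(1 + *S\**); a non-scattering layer to *r* = 0, *t* = e^(−*K\**).
Layers are combined with the plate adding equations (closed-form summation
of the infinite inter-plate reflections), which keep track of the two
illumination sides separately; transmittance is provably side-invariant
for any stack, while reflectance is not. The inversion (*r*, *t*) →
(*K\**, *S\**) is analytic, via *a* = (1 + *r*² − *t*²)/(2*r*) and an
arccoth. Pigment absorbance follows as *D* = 0.4343 *K\**, and coefficients
in mm⁻¹ as *K* = *K\**/*d*, *S* = *S\**/*d*.

The fit peels the known upper surface off the measured stack observables,
solves analytically for the unknown symmetric pigmented layer above the
known sub-stack of unpigmented layer plus lower surface, then inverts the
layer to (*K\**, *S\**) — independently at every wavelength, flagging
rather than dropping wavelengths where noise makes the algebra unphysical.

## Worked example

Generate a synthetic purple-flowered petal (pigment absorbing at 545 nm
with *K\**(545) = 1.4 plus a strong UV band; *S\_p\** = 0.5, *S\_u\** = 0.1,
3% surfaces), simulate a noisy integrating-sphere measurement, and fit it:

```r
library(petalkm)
grid <- default_grid()                       # 300-700 nm, 1-nm steps
K <- make_pigment_kstar(grid = grid)
stack <- build_flower_stack(flower_config(S_u_star = 0.1), K$value, 0.5)
m <- simulate_measurement(stack, noise_sd = 0.005, seed = 42,
                          wavelength = grid)
fit <- fit_petal(m$R_ad, m$T_ad, flower_config(S_u_star = 0.1))
summary(fit)
```

```
Four-layer Kubelka-Munk petal fit
  wavelengths : 401 (300-700 nm), 397 valid
  config      : r_surface = 0.03, S_u* = 0.1
  K_p* peak   : 6.796 at 308 nm (D = 2.952)
  visible absorption peak : K_p* = 1.46 at 544 nm  (absorbance D = 0.635)
  S_p* long-wavelength asymptote : 0.505
  at d = 40 um : K = 36.5 mm^-1, S_p = 12.6 mm^-1
  invalid wavelengths : peel 0, solve 3, invert 1
```

The fit recovers the generating pigment to within the measurement noise:
the visible absorption peak (truth *K\** = 1.4, here 1.46 from one noisy
replicate) and the scattering asymptote (truth 0.5, here 0.505). At a
40-µm effective thickness those correspond to an absorption coefficient of
~35 mm⁻¹ and a scattering coefficient of ~12.5 mm⁻¹. The few UV
wavelengths where the petal is nearly opaque are flagged rather than
silently dropped, and the UV estimates there are the noisiest.

Predicting from the fit shows the asymmetry of the two petal sides:

```r
pred <- predict(fit)
# R_ad(545) = 0.166   R_ab(545) = 0.229   T(545) = 0.122
```

The unpigmented back-side reflects more green light than the pigmented
front (`T_ad` and `T_ab` are identical — a stack theorem). Comparing
pigment-distribution strategies with the same total pigment and scattering:

```r
sc <- scenario_spectra(K, S_p_star = 0.5, S_u_star = 0.1)
sapply(sc, function(x) saturation_metric(x$R_ad, 545))
#  asymmetric homogeneous   symmetric
#       0.607       0.565       0.584
```

The asymmetric petal is the most saturated on its pigmented side: light
backscattered by the unpigmented layer traverses the pigment twice.

A command-line interface wraps the same functions
(`inst/cli/petalkm.R`; commands `simulate`, `fit`, `predict`, `scenario`).

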