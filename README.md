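# foramXRF

Quantitative analysis of synchrotron X-ray fluorescence (XRF) element maps of
planktic foraminifer chamber walls.

Foraminifer tests archive seawater chemistry, and nanometre-resolution XRF
mapping across a chamber wall resolves *where* in the wall's growth
architecture — inner calcitic layer (ICL), Ca-poor primary organic zone
(POZ), outer calcitic layer (OCL), gametogenic crust (GC) — trace metals such
as Mn and Zn were incorporated, down to sub-micrometre alternating
enrichment/depletion nano-bands. foramXRF is for analysts who have (or want
to simulate) fitted per-line count maps of such walls and need the
statistics done properly: Poisson error propagation, significance-thresholded
band detection, reproducible layer segmentation, and matrix-corrected
semi-quantitative element ratios.

## What it computes

* **Synthetic wall models** (`default_wall_model()`, `render_element_maps()`):
  parametric ICL-POZ-OCL-GC walls with per-layer element contrasts and
  periodic nano-banding, rendered through a Gaussian beam into Poisson count
  maps — the package's test harness and a simulator for method studies.
* **Profiles and ratios** (`extract_profile()`, `ratio_profile()`):
  rectangle-averaged traces with `sigma_S = sqrt(N)/w`, and count-rate ratios
  with the quadrature uncertainty
  `sigma_(X/Y) = (X/Y) sqrt((sigma_X/X)^2 + (sigma_Y/Y)^2)`.
* **Nano-band detection** (`second_derivative()`, `d2_uncertainty()`,
  `detect_bands()`): the central-difference second derivative
  `r'' = [r(x+dx) - 2 r(x) + r(x-dx)]/dx^2`, its propagated uncertainty
  (exact `sqrt(6) sigma_r/dx^2`, or the operational factor-2 rule), and
  zero-crossing band segmentation with significance flags.
* **Layer analysis** (`segment_wall()`, `layer_statistics()`,
  `correlate_ratios()`, `trajectory()`): Ca-profile segmentation of the four
  layers, per-layer enrichment over the POZ, and OLS fits with
  heteroscedasticity-robust confidence intervals for cross-element relations
  such as Zn/Ca versus Mn/Ca.
* **Semi-quantification** (`absorption_model()`, `absorbed_fraction()`,
  `quantify_ratio()`, `bulk_enrichment()`): the fundamental-parameter
  relation `c_i = S_i A_i/(sigma_i eps_i)` with Beer-Lambert self-absorption
  corrections (`1 - exp(-chi)`, `chi = (mu/rho) rho_eff t`) for thick
  carbonate slabs, and thin-section validity checks.

## Worked example

```r
library(foramXRF)

model <- default_wall_model("YTT")          # 15 um fossil wall preset
acq   <- default_acquisition(model, seed = 42)
stack <- render_element_maps(model, acq, c("Ca.Ka", "Mn.Ka", "Zn.Ka"))

prof <- lapply(stack$maps, function(m)
  extract_profile(m, c(21, 1), c(21, 250), width = 21))
segment_wall(prof$Ca.Ka)
#> <wall_segmentation> ICL|POZ 3000 nm, POZ|OCL 4260 nm, OCL|GC 10140 nm (inner_first)

mnca <- ratio_profile(prof$Mn.Ka, prof$Ca.Ka)
znca <- ratio_profile(prof$Zn.Ka, prof$Ca.Ka)
detect_bands(attach_uncertainty(second_derivative(mnca), d2_uncertainty(mnca)))
#> <band_set> Mn.Ka/Ca.Ka: 79 candidate band(s), 43 significant
correlate_ratios(mnca, znca)
#> <correlation_result> slope 0.1904 [0.1894, 0.1913], rho 0.9998, n 250

am <- absorption_model(thickness_um = 10)   # 10 um porous calcite slab
round(100 * sapply(c("Ca.Ka", "Mn.Ka", "Zn.Ka"),
                   function(l) absorbed_fraction(am, l)), 1)
#> Ca.Ka Mn.Ka Zn.Ka
#>  23.5  32.4  12.8
totals <- render_bulk_counts(model, acq, c("Ca.Ka", "Mn.Ka", "Zn.Ka"),
                             absorption = am)
quantify_ratio(totals, model = am)$ratios["Mn/Ca"]
#>     Mn/Ca
#> 7.663e-04
```

Reading the output: the segmentation recovers the generator's layer
boundaries (truth 3000 / 4250 / 10250 nm) to within two 60 nm pixels, and the
POZ width (1260 nm) sits in the expected 1-1.5 um range. The Mn/Ca trace
carries 43 significant nano-bands on the ~300 nm scale the model encodes. The
Zn/Ca-vs-Mn/Ca slope recovers the encoded 0.19 proportionality inside its
95% interval. The absorbed fractions quantify why a 10 um wall needs a matrix
correction while a 1 um lamella does not, and the corrected bulk Mn/Ca
returns the generator's calibrated 7.66e-4 weight-basis ratio.

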