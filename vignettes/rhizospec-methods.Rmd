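---
title: "Methods: hyperspectral root phenotyping with rhizospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral root phenotyping with rhizospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Roots grown against the glass front of a soil-filled rhizobox can be
imaged by a push-broom NIR line scanner (900–1700 nm, 256 bands,
0.1 mm/px, 14-bit counts). Soil and root often have poor colour
contrast, but differ spectrally: root tissue carries strong water
absorption near 1450 nm and 1050 nm and structural-carbohydrate
(cellulose / hemicellulose / lignin) features near 1630–1690 nm, while
the soil background is a scattering, slowly varying reflector. The
package turns raw scanner strides into a measured binary root system
and chemometric maps, and ships a seeded synthetic scene generator so
that every stage is testable without instrument data.

## Model and processing chain

1. **Normalization.** Per pixel $i$ and band $\lambda$,
   $N_{i\lambda} = (R_{i\lambda} - D_{i\lambda}) / (W_{i\lambda} - D_{i\lambda})$,
   with $W$ and $D$ the white (Spectralon) and dark standards averaged
   over their scan lines and applied per column (push-broom
   convention). Values are not clipped to $[0, 1]$; specular pixels may
   exceed 1. Bands are trimmed to 1000–1700 nm because the detector is
   noisy at its low-wavelength edge.

2. **Defect masking.** Pixel score $s_i = \mathrm{sd}_\lambda
   (N_{i,\lambda} - N_{i,\lambda+1})$. The API default flags
   $s_i > \mathrm{median}(s) + k\,\mathrm{MAD}(s)$ with $k = 5$. The
   pipeline default instead uses an absolute threshold of 0.3
   (config-exposed): true dead pixels and spikes toggle over most of
   the dynamic range ($s \approx 1$ in reflectance units) while genuine
   spectra stay below $\approx 0.1$; a relative fence calibrated on a
   very uniform background would otherwise swallow the sparse,
   high-contrast foreground — the same reason the original workflow set
   this threshold by inspecting the score histogram rather than by a
   fixed multiple of the MAD.

3. **Pre-treatment bank.** A 2 × 4 × 2 factorial (16 cells):
   linearization (none, $\log_{10}(1/R)$), de-trending (none, 2nd-order
   polynomial residual, Savitzky–Golay 1st derivative with window 7 /
   order 2, asymmetric least squares with $\lambda = 10^4$,
   $p = 10^{-3}$, 10 iterations), multiplicative correction (none,
   SNV with population standard deviation). Composition order is
   linearization → de-trending → multiplicative; the factorial's table
   order varies linearization slowest, then multiplicative, then
   de-trending. MSC is provided as an optional extra (reference = mean
   spectrum) but is not part of the bank. Non-positive reflectance is
   floored at $10^{-6}$ before the log.

4. **Scoring and band selection.** Pre-treatments are ranked three
   ways: (a) average rank over six non-Gaussianity indicators
   (|skewness|, |excess kurtosis|, low entropy, negentropy, SNR,
   KL divergence from a moment-matched Gaussian; 128-bin histograms)
   evaluated at the whole image's best band — the band maximizing the
   average standardized score, a choice the source workflow leaves
   open; (b) maximum per-band Bhattacharyya distance
   $D = -\ln \sum_i \sqrt{p_i q_i}$ between root-ROI and soil-ROI
   histograms (shared 128 equal-width bins over the pooled range); and
   (c) the same over all difference spectra
   $N_{\lambda_n} - N_{\lambda_m}$. The top-10 bands are chosen by
   nomination frequency across criteria, ties broken by mean rank then
   lower wavelength. Reductions: single best band, mean over the ten,
   PCA score image with maximal ROI contrast, a 3-D ten-band stack, or
   the first $k$ PCA scores.

5. **Segmentation.** Multilevel Otsu thresholding (exhaustive
   between-class-variance maximization on a 256-bin histogram),
   k-means (k-means++ seeding, Lloyd iterations, empty clusters
   re-seeded at the worst-fit point), fuzzy c-means (fuzzifier $m = 2$,
   memberships $u \propto d^{-2/(m-1)}$, stop at
   $\max|\Delta u| < 10^{-5}$ or 100 iterations), and a two-class
   linear SVM ($C = 1$, dual coordinate descent, features standardized
   by training statistics). Three classes (root / soil / mixed) are the
   default: two tend to admit noise, more fragment the root class. The
   root class is the cluster whose mean is farthest from the image
   mode, ties to the smaller cluster — roots are sparse and
   contrast-extreme. Quality gate: the segmented binary image's
   population skewness, $(1-2p)/\sqrt{p(1-p)}$ for root fraction $p$,
   must reach 2.5; below that the image is noise-dominated
   ($p \gtrsim 0.1096$) and the result is flagged failed.

6. **Post-processing.** Strides (10% nominal overlap) are registered
   pairwise by the phase-correlation peak of the normalized cross-power
   spectrum; the peak search is confined to a neighbourhood of the
   nominal offset, because windows that overlap on only part of their
   width produce sidelobes that can out-vote the true peak on sparse
   binary content. Low-confidence registrations fall back to the
   nominal offset with a warning. Overlap is fused by logical OR for
   masks (preserves thin axes crossing seams) and by the mean for
   grayscale. Noise objects are removed when both short (ellipse
   major-axis length below the extent floor) and small (area floor);
   elongated components always survive.

7. **Root length.** The mask is thinned (Zhang–Suen, followed by a
   connectivity-preserving removal of redundant pixels — staircase
   corners and 2-px diagonal runs that the basic algorithm leaves and
   that would inflate step counts). Length is
   $(N_{orth} + \sqrt{2} N_{diag}) \cdot \text{mm/px}$ over skeleton
   adjacency steps. This convention is exact for axis-aligned and 45°
   paths and carries the classical chain-code bias of up to ≈ +8% for
   straight runs near 22.5°; we keep it because it is simple, stated,
   and calibratable, and because the synthetic truth paths are measured
   with the same stepping, so biases largely cancel in recovery tests.

8. **Chemometrics.** Root-pixel spectra are shape-corrected by ALS and
   reduced to 5 principal components. Radial classes: distance of each
   root pixel to the nearest skeleton pixel, binned left-closed at
   0.1 mm then 0.2 mm steps to an open-ended 8th class (> 1.3 mm) —
   left-closed so that at 0.1 mm/px the first flanking pixel (exactly
   0.1 mm) falls in class 2. Distance to the skeleton, not to the
   border, is the default operationalization of "distance from root
   centre". Classification is one-vs-one ECOC over depth-10 CART trees
   (Gini splits) with a stratified 50/50 train/validation split;
   quality is the Pearson correlation between labelled and predicted
   class index, plus an allocation matrix whose columns each sum
   to 100%.

9. **Decay.** The most decay-discriminative feature is found by
   Bhattacharyya distance between the first and last time point over
   {raw, SG 1st derivative} × {single band, band-pair difference}.
   The forward model is $t = a e^{b x}$ fitted by least squares on
   $\ln t$ vs $x$, with held-out days (28, 101 in the reference
   sampling) reported as validation residuals; prediction is clipped at
   0 days and mapped per root pixel (background = NA). Because the
   synthetic water-band depth decays as $e^{-kt}$, the mean designed
   feature is itself exponential in time with no offset, and the rate
   $k$ is recovered with the flagged alternative direction
   ($x = c\,e^{-kt}$, log-linear in $t$); the forward direction is
   exercised on data drawn from its own model, which is the only case
   in which it is exactly log-linear.

## The synthetic scene: what it emulates, what it does not

`generate_scene()` builds: smooth gravitropic root axes (heading =
AR(1) curvature plus weak pull toward vertical; real axes are straight
at the 0.1 mm scale, which also keeps the truth centerline and the
mask skeleton consistent) with disk-stamped widths (primaries 5 px,
laterals 3 px at CI scale); a stele core with 1.5× deeper water bands
than the cortex; Gaussian absorption dips at 1450 ± 30, 1050 ± 20 and
1660 ± 25 nm; a spatially correlated multiplicative scatter field
applied to soil *and* root (surface-geometry scatter is exactly what
the multiplicative pre-treatments exist to remove); additive Gaussian
noise in counts; 14-bit quantization through synthetic white/dark
standards at ~85% dynamic range; dead pixels toggling across the full
range at rate 5 × 10⁻⁴; and strides with 10% overlap. Truth includes
the mask, the marginal centerline length (shared segments between
crossing axes counted once), the tissue map and the decay parameters.

Defaults define the stated world: CI preset 600 × 160 × 64
(paper-geometry preset 3000 × 2912 × 256), root fraction constrained
to 2–12%, reflectance noise sd 0.01 (0.02 in decay series), scatter sd
0.05 at an 8-px correlation scale. These were chosen once for realism
and are not tuned against tests.

It does **not** emulate: radiative transfer or real soil mineralogy
spectra, mixed border pixels at sub-pixel scale, illumination drift
between strides, specular glass reflections, or root topology beyond
primaries-with-laterals. A green test therefore establishes that the
algorithms recover what the stated model encodes, not that they would
meet the same error bounds on instrument data.

## Numerical choices and degenerate inputs

* Bhattacharyya: 128 equal-width bins over the pooled range; disjoint
  supports give $D = \infty$, a zero-width pooled range gives 0.
* ALS: banded (bandwidth-2) Cholesky in C++ for cube-scale work; the
  reference R route solves the same sparse system via Matrix, and both
  are tested against a dense penalized-LS oracle at $10^{-6}$. A
  roughness-penalized baseline may undershoot the data by ~1% of the
  amplitude at curvature changes; it is not a strict envelope.
* Otsu: exhaustive over 256 bins for 2–3 classes, 64 bins for 4.
* k-means/FCM determinism: all seeding is explicit; the same seed gives
  byte-identical masks.
* SVM: hinge-loss dual coordinate descent with a fixed sweep order —
  deterministic without randomization.
* Zero-variance spectra: SNV returns zeros and counts the pixel;
  non-Gaussian scores refuse (flagged).
* Degenerate calibration cells ($W = D$) zero the affected band with a
  warning rather than failing the scan.
* Empty masks: length 0, empty radial labels; constant images give a
  failed segmentation result, not an exception.

## Open design points resolved here

* ENVI (header + raw binary) replaces the instrument's proprietary
  stride format; BIL/BIP/BSQ interleaves, float32 on write.
* Whether SNV precedes or follows de-trending when both are selected
  is not externally fixed; the factorial's column order (de-trending
  first) is used.
* The whole-image non-Gaussianity ranking collapses over bands via the
  best-band rule above; per-band vs pooled ranking is config-visible
  in the code path and documented.
* "Circular" noise objects are operationalized by ellipse major-axis
  extent, so elongated but faint axes are never removed by the area
  rule alone.
* The fuzzy clustering is standard FCM; spatially regularized variants
  exist but are not implemented, and results are labelled accordingly.

## Known limitations

* The chain-code length convention is biased up to ≈ +8% for straight
  runs near 22.5°; calibrated step weights would reduce this but break
  the stated convention. Users calibrating against other tools should
  expect a small angle-dependent offset.
* The radial classifier separates stele from cortex nearly perfectly
  in the synthetic world (distinct designed spectra); on the 8-class
  radial task most information sits in the first two classes, and
  validation correlation drops accordingly — consistent with the
  behaviour of the reference workflow on real data.
* Difference-spectrum search is $O(B^2)$ histograms; for 222+ bands
  use `band_stride` or accept minutes of compute.
* Registration assumes rigid integer shifts; rotation and sub-pixel
  offsets are out of scope.
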