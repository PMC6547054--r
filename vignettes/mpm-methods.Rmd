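---
title: "Multi-parameter map creation: models, corrections, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter map creation: models, corrections, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmmaps)
```

## The signal model

Multi-parameter mapping (MPM) acquires three multi-echo spoiled
gradient-echo (FLASH) scans with predominant PD-, T1- and MT-weighting,
obtained by varying the flip angle and adding an off-resonance
magnetisation-transfer pulse. The steady-state signal at echo time zero
follows the Ernst equation

$$S_c(0) = f_R \, A \sin\alpha_c \frac{1 - e^{-TR_c R_1}}
  {1 - \cos\alpha_c \, e^{-TR_c R_1}}, \qquad \alpha_c = f_T\,
  \alpha_{\mathrm{nom},c},$$

and decays across echoes as $S_c(TE) = S_c(0)\, e^{-TE \cdot R_2^*}$. Here
$A$ is the apparent amplitude (proportional to proton density), $f_T$ the
transmit (B1+) field as a fraction of the nominal flip angle, and $f_R$
the receive-sensitivity field. Four parameter maps are estimated: $R_2^*$,
$R_1$, PD and the MT saturation $\delta$.

### Joint decay estimation (ESTATICS)

All echoes of all available contrasts are pooled into one log-linear model
per voxel,

$$\ln S_c(TE) = \ln S_c(0) - R_2^*\, TE,$$

with a single shared decay rate and one intercept per contrast, solved by
unweighted ordinary least squares (`fit_estatics()`). Sharing the slope
across 12--18 observations instead of 6 raises the precision of $R_2^*$
relative to per-contrast fits; the package's Monte-Carlo acceptance check
measures a joint/single variance ratio well below 1 at echo-1 SNR 50.
Voxels with any non-positive signal among the used echoes are excluded
via the validity mask rather than epsilon-clipped: the log transform is
undefined there and masking keeps the estimator's statistics untouched.
Negative $R_2^*$ estimates are preserved internally (residual statistics
and QA use them) and clipped to zero only in the exported map, with the
clipped count reported.

The fitted intercepts $\exp(\widehat{\ln S_c(0)})$ are the TE=0
extrapolations used downstream; they remove the $T_2^*$ modulation from
the PD, R1 and MT inputs. With single-echo data this correction is
impossible; the pipeline then uses the first echo directly and flags the
resulting multiplicative bias $\approx e^{-TE_1 R_2^*}$ in provenance.

### Rational approximations for R1, A and MT saturation

In the small-TR/small-angle regime ($TR \cdot R_1 \ll 1$,
$\alpha^2 \ll 1$) the Ernst equation admits rational approximations that
invert the dual-flip-angle system in closed form:

$$R_1 \approx \frac{1}{2}\,
 \frac{S_{T1}\alpha_{T1}/TR_{T1} - S_{PD}\alpha_{PD}/TR_{PD}}
      {S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}}, \qquad
A \approx S_{PD} S_{T1}\,
 \frac{TR_{PD}\alpha_{T1}/\alpha_{PD} - TR_{T1}\alpha_{PD}/\alpha_{T1}}
      {S_{T1} TR_{PD}\alpha_{T1} - S_{PD} TR_{T1}\alpha_{PD}},$$

with local (transmit-corrected) angles in radians. The MT saturation,
the fractional saturation of longitudinal magnetisation per excitation
caused by the MT pulse, is

$$\delta = 100\left[\left(\frac{A\,\alpha_{MT}}{S_{MT}} - 1\right) R_1
  TR_{MT} - \frac{\alpha_{MT}^2}{2}\right] \;\text{(percent units)}.$$

Unit regimes are deliberately explicit in the code: the R1/A formulas work
in ms and radians and convert to s$^{-1}$ on output; the MT formula takes
$R_1$ in s$^{-1}$ and $TR$ in seconds. Keeping the conversion points
explicit guards against silent factor-1000 errors.

The exact Ernst inversion (`ernst_invert()`, one-dimensional root finding
on the signal ratio) is shipped as a validation oracle only — the
production path uses the rational forms. For the default protocol (TR 25
ms, 6°/21°) the approximation error is about −1.0 % to −1.3 % in $R_1$
and +0.2 % to +0.4 % in $A$ for tissue-like $R_1 \in [0.7, 1.05]$
s$^{-1}$, growing to −2.1 % at $R_1 = 0.24$ s$^{-1}$ (CSF-like). Long-T1
fluids are therefore outside the approximation's comfort zone — a known
limitation of variable-flip-angle mapping, which is why the default
digital phantom contains brain-tissue-like compartments only. MT
saturation computed from the estimated $A$ and $R_1$ inherits their
approximation errors (about −0.7 % to −1.1 % end to end); with
model-consistent $A$ and $R_1$ its inversion is exact to machine
precision, which the operation-level tests verify.

## Instrumental bias corrections

**Transmit (B1+).** $f_T$ scales the local flip angle and therefore
biases $R_1$, $A$ and $\delta$. Three sources are supported: a
pre-computed map (percent units or fraction, auto-detected from the
median over positive voxels, ambiguity rejected), an actual-flip-angle
imaging (AFI) pair, or none. The AFI inversion uses the standard relation
$\cos\alpha = (rn - 1)/(n - r)$ with $r = S_2/S_1$, $n = TR_2/TR_1$,
valid under ideal spoiling in the $TR \ll T_1$ regime; the bundled AFI
forward simulator works in exactly that regime (first-order saturation
recovery), which makes simulate-then-invert an algebraic identity — the
acceptance check demands agreement to $10^{-6}$ across 10°–80°. The
derived field is smoothed (masked-normalised Gaussian, default 8 mm FWHM)
before use. Without a measured field the maps are produced uncorrected;
the B1-sensitivity acceptance check quantifies the cost (R1 errors above
5 % wherever the true field deviates by 15 % or more).

**Receive (B1−).** $f_R$ cancels in the intercept ratio and thus only
affects $A$/PD — provided it is identical across contrasts. Subject
motion between contrasts breaks that assumption, which is why a
per-contrast mode exists: each contrast is divided by its own measured
sensitivity (ratio of smoothed head-coil to body-coil images, default 12
mm FWHM). The body coil is used as reference *as measured*; its own
profile is not corrected (reciprocity is not assumed at 3T), and this
residual modulation is recorded in provenance. The acceptance ordering
check verifies strictly decreasing PD error from no correction to
single-map to per-contrast correction under distinct per-contrast fields.

**Imperfect spoiling.** Residual transverse coherence biases $R_1$
protocol-specifically. The correction
$T_{1,\mathrm{corr}} = A_{\mathrm{coef}}(f_T) + B_{\mathrm{coef}}(f_T)
\, T_{1,\mathrm{app}}$ accepts user-supplied polynomial coefficients per
protocol; deriving them (EPG/Bloch simulation) is out of scope. Disabled
by default, and the disabled state is written to provenance.

**MT transmit residual.** The $\delta$ map retains a residual transmit
dependence beyond the angle correction; the empirical factor
$\delta_{\mathrm{corr}} = \delta (1 - C)/(1 - C f_T)$ with the
conventional $C = 0.4$ (configurable) reduces the coefficient of
variation across transmit levels, which the acceptance check asserts as a
strict inequality rather than a fixed constant. One caveat specific to
the digital phantom: its MT model is exactly invertible once the local
angle is known, so on phantom data the empirical correction slightly
*moves* an already-exact $\delta$ (by up to ≈10 % at $|f_T - 1| = 0.2$).
Real tissue retains a residual dependence that the angle correction does
not remove — that is the regime $C = 0.4$ was calibrated for — so the
correction stays in the default pipeline and the phantom behaviour is
documented rather than "fixed".

**PD calibration.** The amplitude map is scaled so its mean over a
user-supplied (typically white-matter) mask equals 69 p.u. — the
literature convention for white matter at 3T. Without a mask the map is
scaled to mean 100 p.u. over the validity mask and marked
"uncalibrated-relative" in provenance; ratios between tissues are exact
under either choice.

The pipeline order is fixed and recorded: receive correction → decay fit
→ transmit-dependent maps → spoiling correction → MT saturation → MT
B1-correction → PD calibration. The main text of the method leaves this
order open; applying spoiling correction before computing $\delta$ means
the MT formula sees the best available $R_1$.

## Tissue-weighted (VBQ) smoothing

Plain Gaussian smoothing of quantitative maps mixes values across tissue
boundaries and corrupts the quantitative interpretation. The
tissue-weighted alternative computes, per tissue class,

$$p = \frac{g \ast (w\,q)}{g \ast w},$$

a locally weighted mean in which voxels of the other class carry no
weight. Numerical conventions chosen here:

* `mask_threshold` (default 0.05) applies to the smoothed weights after
  normalisation by their maximum, which makes the output *exactly*
  invariant to global rescaling of the weight map, mask included.
* Boundary handling defaults to zero padding — the weight map absorbs the
  edge effect since weights vanish outside the head; `replicate` is
  available by configuration.
* Output voxels below threshold are `NA` with a companion 0/1 mask
  volume, never silent zeros (zero is a valid quantitative value).
* Singleton axes are left untouched by the separable kernel.

On a crisp two-class phantom the weighted estimate preserves within-class
interior means exactly (the weighted mean of a within-class constant is
that constant) while plain smoothing errs by more than 5 % at
boundary-adjacent voxels; the acceptance check also asserts the
weighted-mean bound (output between class extrema).

## The digital phantom

`make_layered_phantom()` builds concentric spherical compartments with
3T-typical values — deep grey matter ($R_1$ 0.9 s$^{-1}$, $R_2^*$ 30
s$^{-1}$, $\delta$ 1.3 p.u.), white matter (1.05, 21, 2.0; $A = 690$,
i.e. 69 p.u.), cortical grey matter (0.7, 16, 1.0) — plus smooth
low-order-polynomial transmit (default ±20 %) and per-contrast receive
(default ±10 %) fields whose stated range is attained inside the
foreground. Signals are forward-modelled with the exact Ernst equation
for PDw/T1w and with the small-angle MT steady state for MTw, so that the
MT round trip is algebraically exact while R1/A round trips expose the
rational approximation's error, quantifiable against the exact-inversion
oracle. Noise is Gaussian or Rician ($|S + n_1 + i n_2|$), one
independent seed-determined draw per volume.

What the phantom deliberately does **not** emulate: subject motion (beyond
per-contrast receive fields), susceptibility-induced $R_2^*$ artefacts,
slice profiles, k-space artefacts, chemical shift, and spatially
correlated noise. Passing tests on this phantom therefore validate the
estimator algebra, the bias-correction logic and the I/O contracts — not
robustness to real-world artefacts.

## Validation scale and numerical choices

The acceptance checks run the noiseless round trips on a 48³ grid
(≈ 40 000 foreground voxels), Monte-Carlo estimator comparisons with 200
single-voxel repetitions at echo-1 SNR 50, the QA noise sweep with 5 σ
levels × 50 repetitions on a 12³ grid, and the I/O conformance on a 16³
grid — sizes chosen so each check isolates its property at comfortable
statistical resolution. Determinism is by construction: every stochastic
step derives its seed from the run seed, and repeated runs produce
bit-identical NIfTI outputs, which the provenance-re-execution check
asserts byte for byte.

Degenerate inputs are handled by explicit contract: non-finite voxels are
zeroed on load and counted; grids must match to $10^{-4}$ on affine
entries (no resampling is ever performed — registration is out of scope);
identical effective flip angles make the dual-angle system unsolvable and
raise a degenerate-protocol error; empty calibration masks and all-zero
body-coil references are rejected.

## Known limitations

* Rician noise biases log-domain decay fits at low SNR; no Rician bias
  correction is implemented (the Monte-Carlo acceptance check documents
  < 2 % bias at SNR ≥ 50, where the Gaussian approximation holds).
* The rational approximations degrade for long-T1 fluids (≈ −2 % R1 at
  CSF-like $R_1 = 0.24$ s$^{-1}$ under the default protocol).
* End-to-end MT saturation accuracy is bounded by the propagated R1/A
  approximation error (≈ 1 %), not by the MT inversion itself.
* Receive-field estimates retain the body coil's own profile; data-driven
  (segmentation-based) bias estimation, UNICORT, DICOM import,
  registration and group statistics are out of scope.
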