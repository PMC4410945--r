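---
title: "Methods: multi-field calibrated BOLD in boldcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-field calibrated BOLD in boldcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldcal)
```

# The problem

Calibrated BOLD fMRI turns a qualitative signal into a physiological one.
The BOLD signal reflects deoxyhemoglobin content, which depends jointly on
cerebral blood flow (CBF), blood volume (CBV) and oxygen metabolism
(CMRO₂). The Davis model collapses this dependence into

$$\frac{\Delta BOLD}{BOLD_0} = M\left(1 - \left(\frac{CMRO_2}{CMRO_2|_0}\right)^{\beta}\left(\frac{CBF}{CBF_0}\right)^{\alpha-\beta}\right)$$

with the Grubb exponent $\alpha$ coupling CBV to CBF
($CBV \propto CBF^{\alpha}$) and $\beta$ absorbing the nonlinear
susceptibility-to-signal transduction. A mild hypercapnic challenge, assumed
isometabolic, determines the calibration parameter $M$ per session; task
CMRO₂ ratios then follow in closed form. Because both $\beta$ and the MR
physics behind $M$ change with field strength, the package treats 1.5, 3 and
7 T as first-class configurations and asks everywhere: *what stays invariant
across fields, and what does not?*

`boldcal` implements (i) a four-compartment BOLD signal simulator that
predicts $M$ from baseline physiology per field, (ii) the Davis calibration
engine, (iii) a desk-scale voxelwise analysis chain standing in for a full
FSL/FEAT analysis, and (iv) a synthetic ASL/BOLD phantom generator with
known ground truth that exercises the chain end to end.

# The signal model

The tissue signal is a volume-weighted sum of arterial (a), capillary (c),
venous (v) and extravascular (e) compartments:

$$S = (1 - V_a - V_c - V_v)S_e + V_aS_a + V_cS_c + V_vS_v$$

**Intravascular compartments** decay with the empirical quadratic law
$R_2^*(Y) = C_1 + C_2(1-Y)^2$, with per-field constants $C_1, C_2$ (and the
resting extravascular rate $R_{2E}^*(0)$ and echo times) shipped in
`inst/extdata/field_presets.csv` and accessed via `fieldPreset()`. The law
is calibrated at a fixed haematocrit of 0.44; generalising it in both
oxygenation and haematocrit is not supported by multi-field relaxometry, so
haematocrit enters only through the extravascular frequency offset.

**Compartment states.** Given flow and metabolism ratios $(f, r)$, oxygen
extraction follows Fick's principle at constant arterial content,
$OEF = OEF_0\,r/f$; saturations are $Y_v = Y_a(1-OEF)$ and
$Y_c = Y_a(1-\kappa_c OEF)$ with arterial saturation $Y_a = 0.98$ and a
capillary desaturation weight $\kappa_c = 0.4$ (the mean capillary
desaturation as a fraction of full extraction — a standard detailed-model
assumption; the source constants do not pin it). Total CBV scales as
$V_{T0}f^{\alpha}$ and is split with fixed fractions
$\Omega = (0.2, 0.4, 0.4)$. Whether the hypercapnic volume change should be
arterial-dominated rather than uniform is genuinely open; the uniform split
is the simplest reading of the Grubb relation and is used throughout.

**Extravascular compartment.** The published multi-field chain cites
numerical vessel-scale simulations whose coefficients are not printed, so
the package adopts the standard closed forms: a linear dependence on the
characteristic frequency offset for the large-vessel (static-dephasing)
scale and a quadratic one for the capillary (diffusion-narrowed) scale,

$$\Delta R_{2E}^* = s\left[k_{lin}(V_a\delta\omega_a + V_v\delta\omega_v) + k_{quad} V_c\,\delta\omega_c^2\right],
\qquad \delta\omega_i = \gamma B_0 \Delta\chi_0 Hct (1 - Y_i)$$

with defaults $k_{lin} = 4.3$ (dimensionless), $k_{quad} = 0.04$ s,
$\Delta\chi_0 = 0.264$ ppm, $\gamma = 2.675\times10^8$ rad s⁻¹ T⁻¹. This
preserves the essential field dependence — linear terms $\propto B_0$,
capillary term $\propto B_0^2$ — that drives the growth of $M$ with field.
Susceptibility-unit conventions vary between sources, so the global factor
$s$ (`scale`) can be **anchored once**: `anchorExtravascularScale()` solves
for $s$ such that the simulated 3 T calibration gives $M = 0.076$, after
which 1.5 T and 7 T are genuine predictions (they land within ~6% and ~13%
of the multi-field study's printed simulated values; unanchored, all three
fields agree within 20%). Baseline deoxyhemoglobin dephasing is added on top
of $R_{2E}^*(0)$ in both states; any double-counting this implies is
absorbed by the anchoring. Compartments share a common effective spin
density.

Internal units are seconds and s⁻¹ everywhere; constructors accept echo
times in milliseconds and convert on entry (values above 0.5 are read as
ms).

**Hypercapnia simulation.** `simulateHypercapniaCalibration()` applies a 30%
CBF increase at constant CMRO₂, forms the fractional BOLD change from the
compartment model, and inverts the Davis relation for $M$, plus the
echo-time-scaled $M_{opt} = M\,TE_{opt}/TE$. The Davis form is not exact for
the compartment model: across challenge sizes $\Delta CBF \in [0.2, 0.4]$
the recovered $M$ drifts by about ±1% around the 30% value. That drift *is*
the model mismatch under study; the test suite records it as a regression
bound rather than assuming invariance. `sweepPhysiology()` reproduces the
design of the simulation study: CBV swept over {0.03, 0.05, 0.07} at OEF
0.4, and OEF over {0.3, 0.4, 0.5} at CBV 0.05; $M_{opt}$ rises with CBV and
its physiological range widens monotonically with field — the reason
inter-subject variance of $M$ grows at high field.

# The Davis engine

`estimateM()` and `estimateCMRO2()` are the closed-form inversions

$$M = \frac{\Delta BOLD_{hc}}{1 - f_{hc}^{\alpha-\beta}}, \qquad
r = f^{(\beta-\alpha)/\beta}\left(1 - \frac{\Delta BOLD}{M}\right)^{1/\beta}.$$

Numerical choices: the closed form is used in production and verified in the
test suite against a brute-force bisection of the forward model to 1e−9, and
against forward–inverse round trips to 1e−10 over a dense grid. A task
response reaching $\Delta BOLD \ge M$ has no physical inverse (it would
require negative deoxyhemoglobin) and raises an error rather than returning
a boundary value — in practice it signals a measurement or ROI failure. A
hypercapnic flow ratio at or below 1 likewise raises a calibration error
(division by zero at $f_{hc}=1$). No warning is currently emitted for weak
challenges ($f_{hc}$ barely above 1); the error surface is left to the
caller since group pipelines drop such subjects explicitly.

# The analysis chain

The voxel-level chain mirrors a FEAT-style analysis at desk scale.

**Design.** Seven regressors: (1) the tag-control alternation (±½, tag at
even 0-based volumes — the sign convention makes the baseline perfusion
effect positive); (2)–(4) boxcars for motor tasks A+B, motor tasks C+D and
hypercapnia, convolved with moment-matched gamma responses (task: mean lag
6 s, SD 3 s ⇒ shape 4, scale 1.5 s; hypercapnia: mean lag 42 s, SD 30 s,
reflecting the slow end-tidal CO₂ rise), truncated 5 SD past the mean and
normalised to unit sum so effect sizes carry amplitude units; (5)–(7) the
elementwise products of (1) with (2)–(4), which model flow responses carried
by the ASL difference signal. The default paradigm is a 48 s lead-in, four
48 s motor blocks alternating with 48 s rest, then two 180 s CO₂ blocks each
followed by 120 s of air: 344 volumes at TR 3 s. Motor A+B drive ROI
definition and motor C+D quantification, avoiding circularity.

**Centring convention.** Whether interaction regressors should be built
from mean-centred responses is not externally fixed. `boldcal` multiplies
the *uncentred* convolved boxcars by the alternation and fits an explicit
intercept. This is deliberate: centring before multiplication aliases part
of the flow response into the tag-control effect, biasing
$f = 1 + cope_{int}/cope_{tc}$ by a factor $1 + \Delta f\,\overline{c}$
(about 6% for the hypercapnia regressor, whose time-course mean is ~0.35),
which would contaminate even noise-free data. With uncentred interactions
the tag-control cope estimates *baseline* perfusion exactly.

**Filtering.** FEAT's Gaussian-weighted running-line highpass is replaced by
a DCT-basis projection at the same cutoff — deterministic and spectrally
equivalent at this scale. The BOLD analysis copy uses a 300 s cutoff, the
ASL copy 10 s; each copy filters data and regressors together. The ASL copy
retains the BOLD waveforms as nuisance regressors: about 2% of their RMS
survives a 10 s cutoff, and if unmodelled that residue aliases into the
interaction effects (flow-ratio errors up to 0.08 in noise-free data). A
linear drift under the 300 s cutoff is attenuated to a few percent RMS (the
DCT tail of a ramp), while the tag-control alternation at the Nyquist
frequency passes the 10 s filter with >99% of its amplitude.

**Fitting and normalisation.** Ordinary least squares per voxel; the
generator produces white noise, keeping the stage self-consistent without
prewhitening, and no spatial smoothing is applied anywhere. z-statistics map
the t statistic through the normal quantile of the t cumulative probability
(log-scale tails for stability); zero-residual voxels get z = 0 with a
warning. BOLD responses are normalised to the per-voxel *baseline* signal —
the GLM intercept, i.e. the time-course mean corrected for modelled
responses. Normalising to the raw time-course mean instead would deflate
responses by the response mass itself (~0.4% at 3 T); the intercept
convention keeps noise-free recovery exact, and `normalizeResponses()`
accepts any baseline map if the raw-mean convention is wanted. Flow ratios
are $f = 1 + cope_{int}/cope_{tc}$; voxels with non-positive perfusion
copes are flagged non-perfused.

**ROI and exclusion.** ROIs take the top 40% of voxels by uncorrected z
(count = ceiling, ties broken by ascending voxel index, evaluated within a
brain mask derived from the baseline signal): "BOLD-only" from the motor
A+B BOLD z, "BOLD/GM" intersecting it with the top 40% by tag-control z — a
grey-matter surrogate used when registration to structural images is
unavailable. Voxels are then kept only if both fractional BOLD responses
lie in [0, 0.10] and both CBF ratios in [1, 3]; the exclusion rule is
written as strict inequalities, so boundary voxels are retained (closed
intervals). Subject-level estimates apply the Davis inversions to the
arithmetic means of the kept-voxel responses; subjects with empty kept sets
are flagged and dropped pairwise from group statistics. Group summaries
report means of per-subject estimates (mean of ratios), not the Davis
inversion of group-mean responses — both are available and differ slightly
by Jensen's inequality.

**Group statistics.** Paired two-sided t-tests (`pairedTTest()`, with a
sign convention for zero-variance differences), Bland–Altman mean
difference with 95% limits of agreement interpreted as mean ± 1.96 × sample
SD of differences (the standard construction for such plots), and resting
ASL SNR: the mean of a single baseline tag-control difference volume over
the ROI — *before* noisy-voxel exclusion, to avoid biasing the comparison —
divided by its SD over a non-brain region.

# The synthetic phantom

`generatePhantom()` builds a 24×24×6 slab (voxels 4.1×4.1×5 mm in the NIfTI
header) with a deterministic geometry: ≥20% background (the SNR noise
region), a grey-matter ring with an active motor band, a white-matter core,
a small CSF pocket, and a row of partial-volume voxels mixing active grey
and white matter 50/50. Per voxel the time course is

$$y(t) = b\,[1 + \Delta B_m(c_{AB}(t)+c_{CD}(t)) + \Delta B_{hc}c_{hc}(t)]
 + p\,x_1(t)\,f(t) + \sigma\varepsilon(t)$$

with $b$ the baseline level, $p$ the perfusion amplitude, $x_1$ the ±½
alternation, $c$ the HRF-convolved boxcars and $f(t)$ the flow time course.
Response amplitudes derive from each voxel's true $M$, $f$ and $r$ through
the Davis forward model evaluated at the block amplitudes, modulated by the
convolved boxcar. Applying the Davis nonlinearity sample-by-sample instead
would make the data nonlinear in the GLM regressors and leave a systematic
~0.5–1% effect-size bias; the amplitude-level construction matches the
linear-systems assumption the GLM itself makes, and noise-free recovery is
then exact to machine precision.

**Ground truth and heterogeneity.** Active grey matter draws per-voxel
truths $f_{motor} \sim N(1.4, 0.4)$, $f_{hc} \sim N(1.2, 0.25)$,
$r \sim N(1.17, 0.05)$, and $M$ with 15% relative scatter around the
field's simulated value; inactive tissue has unit ratios. The dispersions
are deliberate: motor activation is focal and graded (voxelwise motor flow
responses span roughly −1 to 4 in real pooled histograms), and
cerebrovascular CO₂ reactivity is strongly heterogeneous across voxels. The
exclusion filters only have work to do on dispersed distributions. For
partial-volume voxels the *measured* quantities are signal-weighted
mixtures of the pure-tissue ones, and the stored "true" $M$ and $r$ are the
values those mixtures imply — which is what makes ROI choice matter: the
BOLD-only ROI admits partial-volume voxels with diluted effective $M$,
while the BOLD/GM intersection screens them out by their weaker perfusion,
so ROI choice moves $M$ far more than it moves the CMRO₂ estimate.

**Noise and SNR presets.** Noise is i.i.d. Gaussian, a documented
simplification of physiological noise, with $\sigma$ set so the resting
single-subtraction ASL SNR matches the target:
$\sigma = p_{GM}/(\mathrm{SNR}\sqrt2)$. The per-field presets (0.45 / 1.3 /
2.5 at 1.5 / 3 / 7 T) come from a first-principles estimate: EPI thermal
SNR of roughly 45 / 130 / 250 at this voxel size (a 12-channel coil at
1.5 T versus 32-channel coils at 3 and 7 T) and an ASL difference signal of
~1% of the tissue signal. They are configuration, not claims about any
particular scanner, but they matter: error propagation through the GLM
gives voxelwise flow-ratio noise of about $0.23/\mathrm{SNR}$ for the motor
regressor, so much larger presets would make the [1, 3] exclusion window
unreachable by measurement noise and silently turn the truncation-bias
analysis below into dead code. The realised SNR is measured, not assumed,
and is within 10% of target; the field ordering is preserved.

**The low-field over-estimation mechanism.** At low SNR the [1, 3] window
clips the noisy lower tail of the voxelwise flow-ratio distributions, so
kept-voxel mean CBF ratios inflate — and with them the CMRO₂ estimate. The
chain is subtle: inflation of the *hypercapnic* ratio deflates $\hat M$,
which by itself would deflate $\hat r$, while inflation of the *motor*
ratio inflates $\hat r$. Which effect wins depends on whether the
hypercapnic dispersion is truth-dominated or noise-dominated: when voxel
reactivity genuinely varies, the exclusion selects voxels whose (Davis-
coupled) hypercapnic BOLD response rises in tandem with their flow ratio,
so $\hat M$ is approximately preserved and the motor-ratio inflation wins —
the estimated CMRO₂ ratio rises at low SNR, qualitatively reproducing the
over-estimation reported at 1.5 T. With near-homogeneous reactivity the
selection would act on noise alone, $\hat M$ would collapse, and the sign
would invert. The package's defaults sit in the first, physiologically
realistic regime; the acceptance suite verifies the inflation of both the
kept-voxel motor CBF ratio and the CMRO₂ estimate on identical truth at
paired seeds.

**What passing tests do and do not show.** The phantom has white noise, no
motion, no slow drift (unless requested), no arterial-arrival or bolus
kinetics (perfusion is an additive tag-control difference term, which is
all the pipeline consumes), a single echo per field, and truth generated
under the same Davis family the estimator inverts. Recovery results
therefore validate the *pipeline* — its algebra, conventions and selection
behaviour — not the Davis model's fidelity to brain tissue; the
signal-model module probes that separately, and the residual
challenge-size drift of $M$ quantifies it.

# Problem sizes and tolerances used by the test suite

Unit tests run on a quarter-size slab (12×12×2) where geometry permits;
end-to-end checks use the full 24×24×6 slab and the 344-volume paradigm.
Stochastic checks use 20 seeded replicates at the 3 T preset for recovery
(median relative $M$ error < 10%, median absolute CMRO₂-ratio error < 0.03)
and 12 paired seeds for the truncation comparison; the forward–inverse
identity grid has 10⁴ points at 1e−10 and the bisection cross-check 10³
random instances. These sizes were chosen as the smallest that make the
stochastic assertions stable across seeds.

# Known limitations

- The intravascular law is oxygenation-only at fixed haematocrit 0.44;
  inter-subject haematocrit effects enter only extravascularly.
- Extravascular coefficients are convention-dependent; quantitative $M$
  values should be read relative to the 3 T anchoring, trends across field
  are the robust output.
- One echo per field; no dual-echo combination.
- The phantom's noise is white; autocorrelated physiological noise would
  widen all voxelwise distributions and strengthen the truncation effects
  shown here.
- Motion correction, registration, fieldmap correction and brain extraction
  are out of scope — inputs are assumed preprocessed.
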