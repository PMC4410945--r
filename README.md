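# boldcal

Hypercapnia-calibrated BOLD fMRI across magnetic field strengths.

Gas-calibrated fMRI estimates stimulus-evoked changes in the cerebral
metabolic rate of oxygen consumption (CMRO₂) by combining BOLD and arterial
spin labelling (ASL) measurements with a mild CO₂ challenge. The method rests
on the Davis model,

    ΔBOLD/BOLD₀ = M · (1 − (CMRO₂/CMRO₂|₀)^β · (CBF/CBF₀)^(α−β)),

where α is the Grubb flow–volume exponent (0.2) and β a field-dependent
susceptibility exponent (1.5 / 1.3 / 1.0 at 1.5 / 3 / 7 T). The calibration
parameter M — the maximum BOLD increase if all deoxyhemoglobin were removed —
is obtained by applying the model to an isometabolic hypercapnic challenge,
after which task CMRO₂ ratios follow from the task BOLD and CBF responses.

`boldcal` is for researchers who want to study how this calibration behaves
across field strengths without scanner access. It provides:

- **Four-compartment signal simulator** — arterial/capillary/venous
  intravascular compartments with a quadratic blood R2\*(Y) law and a
  two-scale extravascular model, predicting the BOLD response and hence M at
  1.5, 3 and 7 T from baseline physiology (haematocrit, OEF, CBV), with
  physiology sweeps and an optional one-parameter 3 T anchoring.
- **Davis calibration engine** — forward model, isometabolic M estimation,
  closed-form CMRO₂ inversion, echo-time scaling.
- **Voxelwise analysis chain** — gamma-HRF design matrices with tag-control
  interaction regressors, DCT highpass filtering, OLS fitting with
  z-statistics, response normalisation, top-fraction ROI construction
  (BOLD-only and BOLD∩grey-matter), physiological voxel exclusion,
  per-subject estimates, paired t-tests, Bland–Altman agreement and ASL SNR.
- **Synthetic phantom generator** — seeded 4D tag-control ASL/BOLD datasets
  with per-voxel ground truth (true M, CBF and CMRO₂ responses,
  partial-volume voxels, field-dependent SNR), so the full chain is testable
  end to end; NIfTI + plain-text round-trip IO.

## Worked example

```r
library(boldcal)

## simulate hypercapnia calibration at 7 T (extravascular scale anchored at 3 T)
simulateHypercapniaCalibration(fc = fieldPreset("7T"),
                               ev = anchorExtravascularScale())
#> Simulated calibration (7T): dBOLD=0.0408 for f=1.30 -> M=0.2157 (M at optimal TE 0.3172)

## Davis inversion of 3 T group-mean responses (BOLD/GM ROI)
M <- estimateM(0.009, 1.13, davisParams(beta = 1.3))       # 0.0715
estimateCMRO2(0.006, 1.31, M, davisParams(beta = 1.3))     # 1.1748

## end-to-end: synthetic 3 T acquisition through the full pipeline
ph <- generatePhantom(phantomSpec("3T", seed = 1))
out <- runSubjectPipeline(ph, roiSpec(0.4, "BOLD_GM"))
out$result
#> SubjectResult: 90/256 voxels analysed
#>   dBOLD (motor 0.0187, CO2 0.0176); CBF ratio (motor 1.560, CO2 1.321)
#>   M=0.0668, M at optimal TE=0.1375, relative CMRO2=1.131
subjectEstimates(out$kept, trueSummaries(ph), fieldPreset("3T"))
#> SubjectResult: 90/NA voxels analysed
#>   ... M=0.0688, ... relative CMRO2=1.160
```

The first call predicts the 7 T calibration parameter from baseline
physiology (M ≈ 0.22 at the 17 ms acquisition echo time, ≈ 0.32 at the
field-optimal 25 ms). The Davis inversion turns group-mean hypercapnic
responses into M and motor responses into a ~17 % CMRO₂ increase. The
pipeline run recovers the phantom's subject-level truth (M 0.069, rCMRO₂
1.16) to within the noise level of a single synthetic session; the measured
resting ASL SNR for this phantom is ≈ 1.4.

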