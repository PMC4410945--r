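#' @import methods
#' @importFrom stats convolve dgamma pt qnorm rnorm sd t.test uniroot quantile
#'   median setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Field-dependent acquisition and relaxometry constants
#'
#' Per-field parameters of the signal model: the quadratic blood R2* law
#' \eqn{R_2^*(Y) = C_1 + C_2 (1-Y)^2}, the resting extravascular decay rate,
#' the acquisition and field-optimal BOLD echo times, and the Davis
#' susceptibility exponent \eqn{\beta}. Shipped presets for 1.5/3/7 T are
#' available through [fieldPreset()].
#'
#' @slot B0 main field strength (tesla).
#' @slot C1 constant term of intravascular R2* (1/s).
#' @slot C2 quadratic coefficient of intravascular R2* (1/s).
#' @slot R2E0 resting extravascular decay rate (1/s).
#' @slot TEactual acquisition BOLD echo time (s).
#' @slot TEoptimal field-optimal BOLD echo time (s).
#' @slot beta Davis susceptibility exponent (dimensionless).
#' @slot field label, e.g. "3T".
#' @export
setClass("FieldConstants",
  representation(B0 = "numeric", C1 = "numeric", C2 = "numeric",
                 R2E0 = "numeric", TEactual = "numeric", TEoptimal = "numeric",
                 beta = "numeric", field = "character"),
  prototype(field = ""))

setValidity("FieldConstants", function(object) {
  for (s in c("B0", "C1", "C2", "R2E0", "TEactual", "TEoptimal", "beta"))
    if (!.scalarNum(slot(object, s)) || slot(object, s) <= 0)
      return(sprintf("slot '%s' must be a positive finite scalar", s))
  if (object@TEactual > 0.1)
    return("TEactual must be given in seconds (<= 0.1 s)")
  TRUE
})

#' Baseline haemodynamic physiology
#'
#' Baseline state of the modelled tissue: haematocrit, resting oxygen
#' extraction fraction, total blood volume fraction, the split of that volume
#' across arterial/capillary/venous compartments, arterial saturation, the
#' capillary desaturation weight, and the Grubb flow-volume exponent.
#'
#' @slot Hct haematocrit fraction.
#' @slot OEF0 baseline oxygen extraction fraction.
#' @slot VT0 baseline total blood volume fraction of tissue.
#' @slot OmegaA,OmegaC,OmegaV compartment fractions of total CBV (sum to 1).
#' @slot Ya arterial oxygen saturation fraction.
#' @slot kappaC capillary desaturation weight (mean capillary desaturation as a
#'   fraction of the full extraction).
#' @slot alpha Grubb exponent coupling CBV to CBF.
#' @export
setClass("Physiology",
  representation(Hct = "numeric", OEF0 = "numeric", VT0 = "numeric",
                 OmegaA = "numeric", OmegaC = "numeric", OmegaV = "numeric",
                 Ya = "numeric", kappaC = "numeric", alpha = "numeric"))

setValidity("Physiology", function(object) {
  fr <- c(Hct = object@Hct, OEF0 = object@OEF0, VT0 = object@VT0,
          OmegaA = object@OmegaA, OmegaC = object@OmegaC,
          OmegaV = object@OmegaV, Ya = object@Ya)
  if (any(fr <= 0) || any(fr >= 1))
    return("all fractions must lie strictly in (0, 1)")
  if (abs(object@OmegaA + object@OmegaC + object@OmegaV - 1) > 1e-8)
    return("compartment fractions OmegaA + OmegaC + OmegaV must sum to 1")
  if (object@VT0 >= 0.2)
    return("VT0 must be < 0.2 (blood volume fraction of tissue)")
  if (!.scalarNum(object@kappaC) || object@kappaC <= 0 || object@kappaC > 1)
    return("kappaC must lie in (0, 1]")
  if (!.scalarNum(object@alpha) || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  TRUE
})

#' Extravascular susceptibility-effect model
#'
#' Closed-form extravascular contribution to R2*: a linear term for the
#' large-vessel (static dephasing) scale and a quadratic term for the
#' capillary (diffusion-narrowed) scale, both driven by the characteristic
#' frequency offset \eqn{\delta\omega = \gamma B_0 \Delta\chi_0 Hct (1 - Y)}.
#'
#' @slot kLin linear large-vessel coefficient (dimensionless).
#' @slot kQuad quadratic capillary coefficient (s).
#' @slot dchi0 susceptibility difference between fully deoxygenated and fully
#'   oxygenated blood at unit haematocrit (ppm).
#' @slot scale global magnitude factor; 1 by default, optionally set by
#'   [anchorExtravascularScale()].
#' @export
setClass("ExtravascularModel",
  representation(kLin = "numeric", kQuad = "numeric", dchi0 = "numeric",
                 scale = "numeric"))

setValidity("ExtravascularModel", function(object) {
  for (s in c("kLin", "kQuad", "dchi0", "scale"))
    if (!.scalarNum(slot(object, s)) || slot(object, s) <= 0)
      return(sprintf("slot '%s' must be a positive finite scalar", s))
  TRUE
})

#' Haemodynamic state of the four-compartment model
#'
#' A consistent state derived from the CBF and CMRO2 ratios: oxygen extraction
#' by Fick's principle (constant arterial content), compartment saturations,
#' and compartment volumes after Grubb scaling of total CBV. Built with
#' [hemodynamicState()].
#'
#' @slot f CBF ratio relative to baseline.
#' @slot r CMRO2 ratio relative to baseline.
#' @slot OEF state oxygen extraction fraction.
#' @slot Ya,Yc,Yv arterial/capillary/venous oxygen saturation fractions.
#' @slot Va,Vc,Vv compartment volume fractions of tissue.
#' @export
setClass("HemodynamicState",
  representation(f = "numeric", r = "numeric", OEF = "numeric",
                 Ya = "numeric", Yc = "numeric", Yv = "numeric",
                 Va = "numeric", Vc = "numeric", Vv = "numeric"))

setValidity("HemodynamicState", function(object) {
  if (object@f <= 0 || object@r <= 0) return("f and r must be positive")
  if (object@OEF <= 0 || object@OEF >= 1) return("OEF must lie in (0, 1)")
  if (!(object@Ya >= object@Yc && object@Yc >= object@Yv))
    return("saturations must be ordered Ya >= Yc >= Yv")
  if (any(c(object@Va, object@Vc, object@Vv) <= 0))
    return("compartment volumes must be positive")
  TRUE
})

#' Per-compartment transverse signals
#'
#' Signal magnitudes of the arterial, capillary, venous and extravascular
#' compartments at the acquisition echo time, plus the volume-weighted total.
#'
#' @slot Sa,Sc,Sv,Se per-compartment signal magnitudes in (0, 1].
#' @slot S volume-weighted total signal.
#' @export
setClass("CompartmentSignals",
  representation(Sa = "numeric", Sc = "numeric", Sv = "numeric",
                 Se = "numeric", S = "numeric"))

setValidity("CompartmentSignals", function(object) {
  v <- c(object@Sa, object@Sc, object@Sv, object@Se, object@S)
  if (any(v <= 0) || any(v > 1 + 1e-12)) return("signals must lie in (0, 1]")
  TRUE
})

#' Simulated hypercapnia calibration
#'
#' Result of simulating an isometabolic CBF increase with the compartment
#' model and inverting the Davis model: the fractional BOLD change, the
#' calibration parameter M at the acquisition echo time, and M scaled to the
#' field-optimal echo time.
#'
#' @slot dBOLD fractional BOLD signal change.
#' @slot M calibration parameter at the acquisition TE.
#' @slot Mopt M scaled to the field-optimal TE.
#' @slot f CBF ratio of the simulated challenge.
#' @slot field field label.
#' @export
setClass("SimulatedCalibration",
  representation(dBOLD = "numeric", M = "numeric", Mopt = "numeric",
                 f = "numeric", field = "character"))

#' Davis model exponents
#'
#' @slot alpha Grubb flow-volume exponent.
#' @slot beta susceptibility exponent (field dependent: 1.5/1.3/1.0 at
#'   1.5/3/7 T).
#' @export
setClass("DavisParams",
  representation(alpha = "numeric", beta = "numeric"))

setValidity("DavisParams", function(object) {
  if (!.scalarNum(object@alpha) || !.scalarNum(object@beta))
    return("alpha and beta must be finite scalars")
  if (object@alpha <= 0) return("alpha must be positive")
  if (object@alpha >= object@beta) return("alpha must be smaller than beta")
  TRUE
})

#' Block paradigm timing
#'
#' Timing of the acquisition: repetition time, a leading rest period, motor
#' task blocks and hypercapnia blocks. The default ([defaultParadigm()]) is
#' four 48 s motor blocks separated by 48 s rest followed by two 3 min
#' hypercapnia blocks each followed by 2 min of air (17 min 12 s total).
#'
#' @slot TR repetition time (s).
#' @slot motorBlocks two-column matrix (onset, duration) in seconds.
#' @slot hypercapniaBlocks two-column matrix (onset, duration) in seconds.
#' @slot totalDuration total paradigm length (s).
#' @export
setClass("Paradigm",
  representation(TR = "numeric", motorBlocks = "matrix",
                 hypercapniaBlocks = "matrix", totalDuration = "numeric"))

setValidity("Paradigm", function(object) {
  if (!.scalarNum(object@TR) || object@TR <= 0) return("TR must be positive")
  blocks <- rbind(object@motorBlocks, object@hypercapniaBlocks)
  if (ncol(object@motorBlocks) != 2 || ncol(object@hypercapniaBlocks) != 2)
    return("block matrices must have columns (onset, duration)")
  if (nrow(blocks)) {
    if (any(blocks[, 2] <= 0)) return("block durations must be positive")
    if (any(blocks[, 1] < 0)) return("block onsets must be non-negative")
    if (any(blocks[, 1] + blocks[, 2] > object@totalDuration + 1e-9))
      return("blocks must end within totalDuration")
    ord <- order(blocks[, 1])
    b <- blocks[ord, , drop = FALSE]
    if (nrow(b) > 1 && any(b[-nrow(b), 1] + b[-nrow(b), 2] > b[-1, 1] + 1e-9))
      return("blocks must not overlap")
  }
  TRUE
})

#' Gamma haemodynamic response specification
#'
#' @slot meanLag mean lag of the gamma response (s).
#' @slot sd standard deviation of the gamma response (s).
#' @export
setClass("HRFSpec", representation(meanLag = "numeric", sd = "numeric"))

setValidity("HRFSpec", function(object) {
  if (!.scalarNum(object@meanLag) || object@meanLag <= 0)
    return("meanLag must be positive")
  if (!.scalarNum(object@sd) || object@sd <= 0) return("sd must be positive")
  TRUE
})

#' GLM design matrix with tag-control interaction regressors
#'
#' Seven regressors: (1) the +/- 1/2 tag-control alternation, (2)-(4) the
#' HRF-convolved BOLD responses to motor tasks A+B, motor tasks C+D and
#' hypercapnia, and (5)-(7) the elementwise products of (1) with (2)-(4),
#' which model the flow responses carried by the ASL difference signal.
#'
#' @slot X numeric matrix, timepoints by 7 named regressors.
#' @slot TR repetition time (s).
#' @export
setClass("DesignMatrix", representation(X = "matrix", TR = "numeric"))

#' Voxelwise GLM fit
#'
#' @slot copes matrix (voxels x regressors) of effect-size estimates.
#' @slot variances matrix of estimate variances.
#' @slot z matrix of z-statistics (t mapped through the normal quantile of the
#'   t cumulative probability).
#' @slot baseline per-voxel intercept estimate (baseline signal level).
#' @slot meanSignal per-voxel mean of the fitted time course.
#' @slot df residual degrees of freedom.
#' @export
setClass("VoxelFit",
  representation(copes = "matrix", variances = "matrix", z = "matrix",
                 baseline = "numeric", meanSignal = "numeric", df = "numeric"))

#' ROI construction specification
#'
#' @slot fraction top fraction of voxels selected by z-statistic (default 0.4).
#' @slot kind "BOLD_only" (top motor-BOLD z) or "BOLD_GM" (intersection with
#'   the top tag-control z, a grey-matter surrogate).
#' @export
setClass("ROISpec", representation(fraction = "numeric", kind = "character"))

setValidity("ROISpec", function(object) {
  if (!.scalarNum(object@fraction) || object@fraction <= 0 ||
      object@fraction >= 1)
    return("fraction must lie strictly in (0, 1)")
  if (!object@kind %in% c("BOLD_only", "BOLD_GM"))
    return('kind must be "BOLD_only" or "BOLD_GM"')
  TRUE
})

#' Per-subject calibration result
#'
#' Mean responses over the analysed voxels and the derived Davis-model
#' estimates.
#'
#' @slot M calibration parameter at the acquisition TE.
#' @slot Mopt M at the field-optimal TE.
#' @slot rMotor relative CMRO2 during the motor task.
#' @slot nROI number of voxels in the ROI before exclusion.
#' @slot nAnalyzed number of voxels surviving exclusion.
#' @slot dBOLDmotor,dBOLDhc mean fractional BOLD responses.
#' @slot fMotor,fHc mean CBF ratios.
#' @slot valid FALSE when the kept set was empty (subject dropped from group
#'   statistics).
#' @export
setClass("SubjectResult",
  representation(M = "numeric", Mopt = "numeric", rMotor = "numeric",
                 nROI = "numeric", nAnalyzed = "numeric",
                 dBOLDmotor = "numeric", dBOLDhc = "numeric",
                 fMotor = "numeric", fHc = "numeric", valid = "logical"))

#' Synthetic phantom specification
#'
#' Describes a synthetic ASL/BOLD acquisition: grid, field preset, target
#' single-subtraction ASL SNR, seed, paradigm and the physiological truth
#' parameters used to draw per-voxel ground truth.
#'
#' @slot grid integer vector of 3D dimensions.
#' @slot field a [FieldConstants-class] preset.
#' @slot snr target ASL SNR of a single tag-control difference volume
#'   (Inf for a noise-free phantom).
#' @slot seed integer random seed; all randomness flows from it.
#' @slot paradigm a [Paradigm-class].
#' @slot params named list of truth parameters (signal levels, perfusion
#'   amplitudes, response means and heterogeneity SDs, drift amplitude).
#' @export
setClass("PhantomSpec",
  representation(grid = "integer", field = "FieldConstants", snr = "numeric",
                 seed = "integer", paradigm = "Paradigm", params = "list"))

setValidity("PhantomSpec", function(object) {
  if (length(object@grid) != 3 || any(object@grid[1:2] < 6) ||
      object@grid[3] < 1)
    return("grid must give three dimensions (in-plane >= 6, slices >= 1)")
  if (length(object@snr) != 1 || is.na(object@snr) || object@snr <= 0)
    return("snr must be positive (Inf for noise-free)")
  TRUE
})

#' Synthetic ASL/BOLD phantom
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are voxels and
#' whose columns are timepoints. The "signal" assay holds the simulated time
#' series; `rowData` carries the per-voxel ground truth (tissue class, true M,
#' CBF ratios, CMRO2 ratio, perfusion and baseline signal amplitudes);
#' `colData` carries acquisition time and tag/control parity; `metadata`
#' carries the [PhantomSpec-class] and the noise SD actually used.
#'
#' @export
setClass("ASLPhantom", contains = "SummarizedExperiment")
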