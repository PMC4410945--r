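#' @describeIn FieldConstants-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "FieldConstants", function(object) {
  cat(sprintf(
    "FieldConstants %s: B0=%g T, C1=%g /s, C2=%g /s, R2E0=%g /s,\n",
    object@field, object@B0, object@C1, object@C2, object@R2E0))
  cat(sprintf("  TE=%g ms (optimal %g ms), beta=%g\n",
              1000 * object@TEactual, 1000 * object@TEoptimal, object@beta))
})

#' @describeIn Physiology-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "Physiology", function(object) {
  cat(sprintf(
    "Physiology: Hct=%g, OEF0=%g, VT0=%g, Omega=(%g, %g, %g),\n",
    object@Hct, object@OEF0, object@VT0, object@OmegaA, object@OmegaC,
    object@OmegaV))
  cat(sprintf("  Ya=%g, kappaC=%g, alpha=%g\n", object@Ya, object@kappaC,
              object@alpha))
})

#' @describeIn SimulatedCalibration-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "SimulatedCalibration", function(object) {
  cat(sprintf(
    "Simulated calibration (%s): dBOLD=%.4f for f=%.2f -> M=%.4f (M at optimal TE %.4f)\n",
    object@field, object@dBOLD, object@f, object@M, object@Mopt))
})

#' @describeIn SubjectResult-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "SubjectResult", function(object) {
  if (!object@valid) {
    cat("SubjectResult: invalid (empty kept set)\n")
    return(invisible(NULL))
  }
  cat(sprintf("SubjectResult: %d/%d voxels analysed\n",
              object@nAnalyzed, object@nROI))
  cat(sprintf("  dBOLD (motor %.4f, CO2 %.4f); CBF ratio (motor %.3f, CO2 %.3f)\n",
              object@dBOLDmotor, object@dBOLDhc, object@fMotor, object@fHc))
  cat(sprintf("  M=%.4f, M at optimal TE=%.4f, relative CMRO2=%.3f\n",
              object@M, object@Mopt, object@rMotor))
})

#' @describeIn DesignMatrix-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d timepoints x %d regressors (TR %g s)\n",
              nrow(object@X), ncol(object@X), object@TR))
  cat("  ", paste(colnames(object@X), collapse = ", "), "\n")
})

#' @describeIn ASLPhantom-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "ASLPhantom", function(object) {
  spec <- S4Vectors::metadata(object)$spec
  cat(sprintf(
    "ASLPhantom: %s grid, %d volumes, field %s, target ASL SNR %g, seed %d\n",
    paste(spec@grid, collapse = "x"), ncol(object), spec@field@field,
    spec@snr, spec@seed))
  tab <- table(SummarizedExperiment::rowData(object)$class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
})

#' Accessors for simulated calibrations and subject results
#'
#' @param x a [SimulatedCalibration-class], [SubjectResult-class] or
#'   [VoxelFit-class].
#' @return the corresponding numeric component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
calM <- function(x) x@M

#' @rdname accessors
#' @export
calMopt <- function(x) x@Mopt

#' @rdname accessors
#' @export
calDBOLD <- function(x) x@dBOLD

#' @rdname accessors
#' @export
cmro2Ratio <- function(x) x@rMotor

#' @rdname accessors
#' @export
copes <- function(x) x@copes

#' @rdname accessors
#' @export
zstats <- function(x) x@z

#' @rdname accessors
#' @export
designMatrix <- function(x) x@X
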