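#' Select the top fraction of voxels by a statistic
#'
#' Deterministic percentile thresholding: the \eqn{\lceil fraction \cdot
#' |mask| \rceil} voxels with the largest statistic, ties broken by ascending
#' voxel index.
#'
#' @param stat per-voxel statistic.
#' @param mask logical vector of evaluable voxels (default all).
#' @param fraction top fraction to select.
#' @return sorted integer indices of selected voxels.
#' @export
selectTopFraction <- function(stat, mask = rep(TRUE, length(stat)),
                              fraction = 0.4) {
  idx <- which(mask & is.finite(stat))
  if (!length(idx)) stop("mask selects no evaluable voxels")
  k <- ceiling(fraction * length(idx))
  ord <- idx[order(-stat[idx], idx)]
  sort(ord[seq_len(k)])
}

#' Build a motor ROI from activation and perfusion z-maps
#'
#' "BOLD_only": the top fraction of voxels by motor (tasks A+B) BOLD z.
#' "BOLD_GM": its intersection with the top fraction by tag-control
#' (baseline perfusion) z, a grey-matter surrogate when no structural
#' registration is available.
#'
#' @param summaries per-voxel data.frame from [normalizeResponses()].
#' @param spec an [ROISpec-class].
#' @param mask logical evaluable-voxel (brain) mask.
#' @return sorted integer voxel indices.
#' @export
buildROI <- function(summaries, spec = roiSpec(),
                     mask = rep(TRUE, nrow(summaries))) {
  bold <- selectTopFraction(summaries$z_motor_AB, mask, spec@fraction)
  if (spec@kind == "BOLD_only") return(bold)
  gm <- selectTopFraction(summaries$z_perfusion, mask, spec@fraction)
  roi <- intersect(bold, gm)
  if (!length(roi))
    stop("BOLD and grey-matter voxel sets are disjoint; ",
         "increase the ROI fraction")
  sort(roi)
}

#' Apply the voxel exclusion criteria
#'
#' Keeps a voxel iff both fractional BOLD responses lie in \[0, 0.10\] and
#' both CBF ratios lie in \[1, 3\] (closed intervals: the exclusion rule is
#' written as strict inequalities, so boundary voxels are retained). Voxels
#' outside these ranges are taken to be noise or to contain substantial white
#' matter / CSF. Voxels with undefined responses are excluded.
#'
#' @param roi integer voxel indices of the ROI.
#' @param summaries per-voxel data.frame from [normalizeResponses()].
#' @param dBOLDrange,cbfRange closed acceptance intervals.
#' @return list with sorted integer vectors `kept` and `excluded`
#'   (a partition of `roi`).
#' @export
applyExclusion <- function(roi, summaries, dBOLDrange = c(0, 0.10),
                           cbfRange = c(1, 3)) {
  s <- summaries[roi, ]
  ok <- with(s,
    is.finite(dBOLD_motor) & dBOLD_motor >= dBOLDrange[1] &
      dBOLD_motor <= dBOLDrange[2] &
    is.finite(dBOLD_hc) & dBOLD_hc >= dBOLDrange[1] &
      dBOLD_hc <= dBOLDrange[2] &
    is.finite(f_motor) & f_motor >= cbfRange[1] & f_motor <= cbfRange[2] &
    is.finite(f_hc) & f_hc >= cbfRange[1] & f_hc <= cbfRange[2])
  list(kept = sort(roi[ok]), excluded = sort(roi[!ok]))
}

#' Per-subject Davis estimates from the analysed voxels
#'
#' Takes arithmetic means of the responses over the kept voxels, then
#' estimates M from the mean hypercapnic responses ([estimateM()]), relative
#' CMRO2 from the mean motor responses ([estimateCMRO2()]) and M at the
#' field-optimal echo time ([scaleMToOptimalTE()]).
#'
#' @param kept integer voxel indices surviving exclusion.
#' @param summaries per-voxel data.frame from [normalizeResponses()].
#' @param fc a [FieldConstants-class].
#' @param params a [DavisParams-class]; defaults to the field's beta with
#'   alpha 0.2.
#' @param nROI ROI size before exclusion (for bookkeeping).
#' @return A [SubjectResult-class]; `valid` is FALSE (all estimates NA) when
#'   `kept` is empty.
#' @export
subjectEstimates <- function(kept, summaries, fc, params = davisParams(fc),
                             nROI = NA_real_) {
  if (!length(kept)) {
    warning("empty kept set; subject flagged invalid")
    return(new("SubjectResult", M = NA_real_, Mopt = NA_real_,
               rMotor = NA_real_, nROI = nROI, nAnalyzed = 0,
               dBOLDmotor = NA_real_, dBOLDhc = NA_real_, fMotor = NA_real_,
               fHc = NA_real_, valid = FALSE))
  }
  s <- summaries[kept, ]
  mdBm <- mean(s$dBOLD_motor); mdBh <- mean(s$dBOLD_hc)
  mfm <- mean(s$f_motor); mfh <- mean(s$f_hc)
  M <- estimateM(mdBh, mfh, params)
  new("SubjectResult",
      M = M,
      Mopt = scaleMToOptimalTE(M, fc@TEactual, fc@TEoptimal),
      rMotor = estimateCMRO2(mdBm, mfm, M, params),
      nROI = nROI, nAnalyzed = length(kept),
      dBOLDmotor = mdBm, dBOLDhc = mdBh, fMotor = mfm, fHc = mfh,
      valid = TRUE)
}

#' Run the full single-subject analysis chain
#'
#' Reproduces the voxel-level analysis on one 4D dataset: builds the design
#' from the paradigm, highpass filters a BOLD copy (300 s) and an ASL copy
#' (10 s) together with their regressors, fits the GLM to each (BOLD effects
#' are read from the BOLD copy, tag-control and interaction effects from the
#' ASL copy), normalises responses, constructs the ROI, applies the
#' exclusion criteria, forms the per-subject Davis estimates, and measures
#' the resting ASL SNR from a single baseline tag-control pair.
#'
#' @param phantom an [ASLPhantom-class] (or any object accepted by
#'   [fitGLM()] if `par` and `fc` are given).
#' @param spec an [ROISpec-class].
#' @param par the [Paradigm-class]; defaults to the phantom's.
#' @param fc the [FieldConstants-class]; defaults to the phantom's.
#' @param params a [DavisParams-class]; defaults to the field's.
#' @param cutoffBold,cutoffAsl highpass cutoffs (s).
#' @param mask logical brain mask; by default voxels whose baseline signal
#'   exceeds a quarter of the 99th-percentile baseline.
#' @return list with `result` ([SubjectResult-class]), `summaries`, `roi`,
#'   `kept`, `excluded`, `mask`, `snr` and the two [VoxelFit-class] objects.
#' @export
runSubjectPipeline <- function(phantom, spec = roiSpec(), par = NULL,
                               fc = NULL, params = NULL,
                               cutoffBold = 300, cutoffAsl = 10,
                               mask = NULL) {
  if (is(phantom, "ASLPhantom")) {
    meta <- S4Vectors::metadata(phantom)
    if (is.null(par)) par <- meta$spec@paradigm
    if (is.null(fc)) fc <- meta$spec@field
  }
  if (is.null(par) || is.null(fc))
    stop("paradigm and field constants are required for non-phantom input")
  if (is.null(params)) params <- davisParams(fc)
  Y <- .asVoxelMatrix(phantom)
  design <- buildDesign(par)

  # each analysis copy is filtered together with its regressors; the ASL
  # copy keeps the (largely filtered-out) BOLD waveforms as nuisance
  # regressors so their high-frequency residue cannot alias into the
  # tag-control interaction effects
  Yb <- t(highpassFilter(t(Y), cutoffBold, par@TR))
  Xb <- highpassFilter(design@X, cutoffBold, par@TR)
  colnames(Xb) <- colnames(design@X)
  fitBold <- fitGLM(Yb, Xb)

  Ya <- t(highpassFilter(t(Y), cutoffAsl, par@TR))
  Xa <- highpassFilter(design@X, cutoffAsl, par@TR)
  colnames(Xa) <- colnames(design@X)
  fitAsl <- fitGLM(Ya, Xa)

  summaries <- normalizeResponses(fitBold, fitAsl)
  if (is.null(mask)) {
    b <- fitBold@baseline
    mask <- is.finite(b) & b > 0.25 * quantile(b, 0.99, names = FALSE)
  }
  roi <- buildROI(summaries, spec, mask)
  part <- applyExclusion(roi, summaries)
  result <- subjectEstimates(part$kept, summaries, fc, params,
                             nROI = length(roi))
  snr <- if (is(phantom, "ASLPhantom")) {
    # undefined for a noise-free phantom (zero-variance noise region)
    tryCatch(aslSNR(baselineDifferenceVolume(phantom), roi, which(!mask)),
             error = function(e) NA_real_)
  } else NA_real_
  list(result = result, summaries = summaries, roi = roi,
       kept = part$kept, excluded = part$excluded, mask = mask, snr = snr,
       fitBold = fitBold, fitAsl = fitAsl)
}
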