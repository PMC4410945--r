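#' Davis model forward evaluation
#'
#' The Davis relation links the fractional BOLD change to the CBF ratio `f`
#' and CMRO2 ratio `r`:
#' \deqn{\Delta BOLD / BOLD_0 = M (1 - r^\beta f^{\alpha - \beta})}
#'
#' @param M calibration parameter (> 0).
#' @param f CBF ratio relative to baseline (> 0).
#' @param r CMRO2 ratio relative to baseline (> 0).
#' @param params a [DavisParams-class].
#' @return fractional BOLD change (vectorised over `M`, `f`, `r`).
#' @examples
#' davisForward(0.072, 1.31, 1.175, davisParams(beta = 1.3))
#' @export
davisForward <- function(M, f, r, params) {
  if (any(M <= 0) || any(f <= 0) || any(r <= 0))
    stop("M, f and r must all be positive")
  M * (1 - r^params@beta * f^(params@alpha - params@beta))
}

#' Estimate M from an isometabolic (hypercapnia) challenge
#'
#' Under the assumption that CMRO2 is unchanged by mild hypercapnia (r = 1),
#' the Davis relation inverts to
#' \eqn{M = \Delta BOLD_{hc} / (1 - f_{hc}^{\alpha - \beta})}.
#'
#' @param dBOLDhc fractional BOLD response to hypercapnia (>= 0).
#' @param fhc hypercapnic CBF ratio (> 1).
#' @param params a [DavisParams-class].
#' @return estimate of M at the acquisition echo time (vectorised).
#' @examples
#' estimateM(0.009, 1.13, davisParams(beta = 1.3))  # ~0.072
#' @export
estimateM <- function(dBOLDhc, fhc, params) {
  if (any(fhc <= 1))
    stop("calibration undefined: hypercapnic CBF ratio must exceed 1")
  if (any(dBOLDhc < 0))
    stop("hypercapnic BOLD response must be non-negative")
  dBOLDhc / (1 - fhc^(params@alpha - params@beta))
}

#' Estimate relative CMRO2 from a task response
#'
#' Closed-form inversion of the Davis relation for the CMRO2 ratio:
#' \deqn{r = f^{(\beta-\alpha)/\beta} (1 - \Delta BOLD / M)^{1/\beta}}
#'
#' @param dBOLDtask fractional BOLD response to the task (must be < M).
#' @param ftask task CBF ratio (> 0).
#' @param M calibration parameter (> 0).
#' @param params a [DavisParams-class].
#' @return CMRO2 ratio relative to baseline (vectorised).
#' @examples
#' estimateCMRO2(0.006, 1.31, 0.072, davisParams(beta = 1.3))  # ~1.17
#' @export
estimateCMRO2 <- function(dBOLDtask, ftask, M, params) {
  if (any(M <= 0) || any(ftask <= 0))
    stop("M and ftask must be positive")
  if (any(dBOLDtask >= M))
    stop("non-physical response: task BOLD change reaches or exceeds M ",
         "(measurement or ROI failure)")
  ftask^((params@beta - params@alpha) / params@beta) *
    (1 - dBOLDtask / M)^(1 / params@beta)
}

#' Scale M between echo times
#'
#' M is proportional to the BOLD-weighted echo time (its definition is linear
#' in TE), so values acquired at different echo times are compared by scaling
#' with the TE ratio.
#'
#' @param M calibration parameter at `TEactual`.
#' @param TEactual acquisition echo time.
#' @param TEoptimal target (field-optimal) echo time; same units as
#'   `TEactual`.
#' @return M at the target echo time.
#' @examples
#' scaleMToOptimalTE(0.076, 17, 35)  # 0.156
#' @export
scaleMToOptimalTE <- function(M, TEactual, TEoptimal) {
  if (any(TEactual <= 0) || any(TEoptimal <= 0))
    stop("echo times must be positive")
  M * TEoptimal / TEactual
}
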