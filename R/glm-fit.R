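#' Voxelwise ordinary-least-squares GLM fit
#'
#' Fits the seven-regressor design (plus an explicit intercept) to every
#' voxel time course by QR least squares. z-statistics are obtained by
#' mapping the t statistic (cope / sqrt(variance), residual dof) through the
#' normal quantile of the t cumulative probability. Voxels with (numerically)
#' zero residual variance get z = 0 and a single aggregated warning.
#'
#' @param data voxel time series: matrix (voxels x timepoints), 4D array
#'   (x, y, z, t), or an [ASLPhantom-class].
#' @param design a [DesignMatrix-class], or a plain numeric matrix of
#'   regressors (timepoints in rows).
#' @return A [VoxelFit-class].
#' @export
fitGLM <- function(data, design) {
  Y <- .asVoxelMatrix(data)
  X <- if (is(design, "DesignMatrix")) design@X else as.matrix(design)
  if (ncol(Y) != nrow(X))
    stop("timepoints of data (", ncol(Y), ") and design (", nrow(X),
         ") do not match")
  Xf <- cbind(`(Intercept)` = 1, X)
  n <- nrow(Xf); p <- ncol(Xf)
  qrX <- qr(Xf)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  B <- qr.coef(qrX, t(Y))                       # p x V
  res <- t(Y) - Xf %*% B
  df <- n - p
  rss <- colSums(res^2)
  sigma2 <- rss / df
  d <- diag(chol2inv(qr.R(qrX)))                # (X'X)^-1 diagonal
  V <- outer(d, sigma2)                         # p x V variances
  degenerate <- sigma2 <= max(colMeans(Y^2), 1) * 1e-24
  tstat <- B / sqrt(V)
  tstat[, degenerate] <- 0
  if (any(degenerate))
    warning(sum(degenerate), " voxel(s) with zero residual variance; ",
            "z set to 0")
  z <- .tToZ(tstat, df)
  keep <- -1L                                   # drop intercept row
  new("VoxelFit",
      copes = t(B[keep, , drop = FALSE]),
      variances = t(V[keep, , drop = FALSE]),
      z = t(z[keep, , drop = FALSE]),
      baseline = as.numeric(B[1L, ]),
      meanSignal = rowMeans(Y),
      df = df)
}

# t statistic -> z via log-scale tail probabilities (stable for large |t|)
.tToZ <- function(tstat, df) {
  s <- sign(tstat)
  lp <- pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE)
  s * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

.asVoxelMatrix <- function(data) {
  if (is(data, "ASLPhantom"))
    return(SummarizedExperiment::assay(data, "signal"))
  if (is.array(data) && length(dim(data)) == 4)
    return(matrix(data, prod(dim(data)[1:3]), dim(data)[4]))
  if (is.matrix(data)) return(data)
  stop("data must be a voxels x time matrix, a 4D array, or an ASLPhantom")
}

#' Normalise GLM effects to physiological response units
#'
#' Converts copes to the quantities the Davis model consumes, per voxel:
#' fractional BOLD responses are the BOLD copes divided by the baseline
#' signal, and CBF ratios are one plus the interaction cope divided by the
#' tag-control (baseline perfusion) cope. Voxels with non-positive perfusion
#' cope are flagged non-perfused and get NA flow ratios.
#'
#' @param fitBold [VoxelFit-class] from the BOLD analysis copy (300 s
#'   highpass).
#' @param fitAsl [VoxelFit-class] from the ASL analysis copy (10 s highpass);
#'   defaults to `fitBold` when a single fit is used. Must contain the
#'   tag-control and interaction regressors.
#' @param baseline per-voxel baseline signal map; defaults to the GLM
#'   intercept of `fitBold` (the time-course mean corrected for modelled
#'   responses).
#' @return data.frame with one row per voxel: `dBOLD_motor`, `dBOLD_hc`
#'   (motor C+D and hypercapnia BOLD responses), `f_motor`, `f_hc` (CBF
#'   ratios), `z_motor_AB`, `z_perfusion`, and logical `perfused`.
#' @export
normalizeResponses <- function(fitBold, fitAsl = fitBold, baseline = NULL) {
  if (is.null(baseline)) baseline <- fitBold@baseline
  cb <- fitBold@copes
  ca <- fitAsl@copes
  tc <- ca[, "tagcontrol"]
  perfused <- is.finite(tc) & tc > 0
  f_motor <- ifelse(perfused, 1 + ca[, "flow_motor_CD"] / tc, NA_real_)
  f_hc <- ifelse(perfused, 1 + ca[, "flow_hc"] / tc, NA_real_)
  data.frame(
    voxel = seq_len(nrow(cb)),
    dBOLD_motor = cb[, "bold_motor_CD"] / baseline,
    dBOLD_hc = cb[, "bold_hc"] / baseline,
    f_motor = f_motor,
    f_hc = f_hc,
    z_motor_AB = fitBold@z[, "bold_motor_AB"],
    z_perfusion = fitAsl@z[, "tagcontrol"],
    perfused = perfused)
}
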