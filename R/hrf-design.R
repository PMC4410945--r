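#' Discrete gamma haemodynamic response kernel
#'
#' Moment-matched gamma density (shape \eqn{(\mu/\sigma)^2}, scale
#' \eqn{\sigma^2/\mu}) sampled at the repetition time, truncated 5 SD past the
#' mean and normalised to unit sum so that convolved regressors carry the
#' response amplitude.
#'
#' @param spec an [HRFSpec-class].
#' @param TR sampling interval (s).
#' @return numeric kernel summing to 1.
#' @export
gammaHRF <- function(spec, TR) {
  shape <- (spec@meanLag / spec@sd)^2
  scale <- spec@sd^2 / spec@meanLag
  t <- seq(0, spec@meanLag + 5 * spec@sd, by = TR)
  w <- dgamma(t, shape = shape, scale = scale)
  w / sum(w)
}

# boxcar sampled at volume acquisition times (i - 1) * TR
.boxcar <- function(blocks, n, TR) {
  t <- (seq_len(n) - 1) * TR
  box <- numeric(n)
  for (i in seq_len(nrow(blocks)))
    box[t >= blocks[i, 1] & t < blocks[i, 1] + blocks[i, 2]] <- 1
  box
}

.convRegressor <- function(box, kernel) {
  convolve(box, rev(kernel), type = "open")[seq_along(box)]
}

#' Build the seven-regressor design matrix
#'
#' Column (1) is the tag-control alternation (tag = -1/2 at even 0-based
#' volume indices, control = +1/2), columns (2)-(4) are the HRF-convolved
#' boxcars for motor tasks A+B, motor tasks C+D and hypercapnia, and columns
#' (5)-(7) are the elementwise products of column (1) with columns (2)-(4):
#' the flow responses carried by the tag-control difference signal. The
#' convolved regressors are stored uncentred and [fitGLM()] adds an explicit
#' intercept, so the tag-control effect estimates baseline perfusion (see the
#' methods vignette for the centring convention).
#'
#' @param par a [Paradigm-class]; the first half of the motor blocks is
#'   assigned to tasks A+B and the second half to C+D.
#' @param taskSpec HRF for the motor responses (default [taskHRF()]).
#' @param hcSpec HRF for the hypercapnia response (default
#'   [hypercapniaHRF()]).
#' @return A [DesignMatrix-class] (344 timepoints x 7 for the default
#'   paradigm).
#' @export
buildDesign <- function(par, taskSpec = taskHRF(), hcSpec = hypercapniaHRF()) {
  n <- nVolumes(par)
  x1 <- rep_len(c(-0.5, 0.5), n)               # volume 0 is a tag
  mb <- par@motorBlocks[order(par@motorBlocks[, 1]), , drop = FALSE]
  nAB <- ceiling(nrow(mb) / 2)
  kTask <- gammaHRF(taskSpec, par@TR)
  kHc <- gammaHRF(hcSpec, par@TR)
  X <- cbind(
    tagcontrol    = x1,
    bold_motor_AB = .convRegressor(.boxcar(mb[seq_len(nAB), , drop = FALSE],
                                           n, par@TR), kTask),
    bold_motor_CD = .convRegressor(.boxcar(mb[-seq_len(nAB), , drop = FALSE],
                                           n, par@TR), kTask),
    bold_hc       = .convRegressor(.boxcar(par@hypercapniaBlocks, n, par@TR),
                                   kHc))
  X <- cbind(X,
             flow_motor_AB = X[, 1] * X[, 2],
             flow_motor_CD = X[, 1] * X[, 3],
             flow_hc       = X[, 1] * X[, 4])
  full <- cbind(`(Intercept)` = 1, X)
  if (qr(full)$rank < ncol(full)) {
    norms <- sqrt(colSums(scale(X, center = TRUE, scale = FALSE)^2))
    bad <- colnames(X)[norms < 1e-10 * max(norms, 1)]
    if (!length(bad)) bad <- "(collinear combination)"
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  new("DesignMatrix", X = X, TR = par@TR)
}

#' Discrete-cosine highpass filter
#'
#' Projects out the discrete cosine components with period longer than the
#' cutoff (DCT order \eqn{k} has period \eqn{2 n TR / k}), keeping the mean,
#' which is added back. A deterministic, spectrally equivalent stand-in for
#' running-line highpass filters at desk scale; apply with a 10 s cutoff for
#' the ASL analysis copy and 300 s for the BOLD copy.
#'
#' @param ts numeric vector, or matrix with timepoints in rows (each column a
#'   series).
#' @param cutoffS cutoff period (s); must exceed 2 TR.
#' @param TR sampling interval (s).
#' @return filtered series, same shape as `ts`.
#' @export
highpassFilter <- function(ts, cutoffS, TR) {
  v <- is.null(dim(ts))
  x <- if (v) matrix(ts, ncol = 1) else ts
  n <- nrow(x)
  if (cutoffS <= 2 * TR)
    stop("cutoff must exceed 2 TR (nothing lies beyond Nyquist)")
  K <- ceiling(2 * n * TR / cutoffS) - 1
  mu <- colMeans(x)
  if (K >= 1) {
    B <- .dctBasis(n, K)
    xc <- sweep(x, 2, mu)
    # DCT columns are mutually orthogonal; project by normalised inner product
    coef <- crossprod(B, xc) / colSums(B^2)
    x <- xc - B %*% coef
    x <- sweep(x, 2, mu, `+`)
  }
  if (v) drop(x) else x
}

.dctBasis <- function(n, K) {
  t <- seq_len(n) - 1
  vapply(seq_len(K), function(k) cos(pi * k * (t + 0.5) / n), numeric(n))
}
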