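#' Default phantom truth parameters
#'
#' Signal levels, perfusion amplitudes, mean responses and their voxel-to-voxel
#' heterogeneity used when drawing ground truth. Response means follow the
#' grey-matter group values the analysis is designed around (hypercapnic CBF
#' ratio ~1.2, motor CBF ratio ~1.4, motor CMRO2 ratio ~1.17); heterogeneity
#' SDs give the voxelwise response distributions the exclusion filters act on.
#' See the methods vignette.
#'
#' @param baseGM,baseWM,baseCSF baseline signal levels (arbitrary units).
#' @param perfusionGM,perfusionWM,perfusionCSF tag-control difference
#'   amplitudes (same units); grey matter gets voxel scatter `perfusionSD`.
#' @param perfusionSD SD of grey-matter perfusion across voxels.
#' @param fMotor,fMotorSD motor CBF ratio mean and voxel SD (active voxels).
#' @param fHc,fHcSD hypercapnic CBF ratio mean and voxel SD.
#' @param rMotor,rMotorSD motor CMRO2 ratio mean and voxel SD.
#' @param MRelSD relative voxel SD of the calibration parameter around the
#'   field's simulated value.
#' @param pvWeight grey-matter fraction of partial-volume voxels.
#' @param driftAmplitude peak-to-peak linear drift added to brain voxels
#'   (signal units; 0 disables).
#' @param anchor use the 3 T-anchored extravascular scale when computing the
#'   field's true M.
#' @return named list of parameters.
#' @export
phantomParams <- function(baseGM = 1000, baseWM = 900, baseCSF = 1200,
                          perfusionGM = 10, perfusionWM = 3,
                          perfusionCSF = 1, perfusionSD = 1,
                          fMotor = 1.4, fMotorSD = 0.4,
                          fHc = 1.2, fHcSD = 0.25,
                          rMotor = 1.17, rMotorSD = 0.05,
                          MRelSD = 0.15, pvWeight = 0.5,
                          driftAmplitude = 0, anchor = TRUE) {
  as.list(environment())
}

#' Construct a phantom specification
#'
#' @param field field preset name or a [FieldConstants-class].
#' @param snr target single-subtraction ASL SNR (default the field's preset;
#'   Inf gives a noise-free phantom).
#' @param seed integer seed; truth and noise are both drawn from it, truth
#'   first, so phantoms with the same seed share identical ground truth at
#'   any SNR.
#' @param grid 3D dimensions; the first two must be multiples of 6 (the
#'   tissue geometry is defined in sixths of the slab).
#' @param par a [Paradigm-class].
#' @param params truth parameters from [phantomParams()].
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(field = "3T", snr = NULL, seed = 1L,
                        grid = c(24L, 24L, 6L), par = defaultParadigm(),
                        params = phantomParams()) {
  fc <- if (is(field, "FieldConstants")) field else fieldPreset(field)
  if (is.null(snr)) snr <- snrPreset(fc@field)
  if (any(grid[1:2] %% 6 != 0))
    stop("grid x and y dimensions must be multiples of 6")
  new("PhantomSpec", grid = as.integer(grid), field = fc, snr = snr,
      seed = as.integer(seed), paradigm = par, params = params)
}

# deterministic tissue geometry, defined in sixths of the in-plane grid:
# outer third background, inner square brain; central third WM with a small
# CSF core; grey-matter ring; an active motor band on one side of the ring,
# whose row adjacent to WM is partial-volume
.classMap <- function(grid) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  x0 <- rep(rep(0:(nx - 1), times = ny), times = nz)
  y0 <- rep(rep(0:(ny - 1), each = nx), times = nz)
  cls <- rep("background", nx * ny * nz)
  brain <- x0 >= nx / 6 & x0 < nx - nx / 6 & y0 >= ny / 6 & y0 < ny - ny / 6
  cls[brain] <- "GM_inactive"
  wm <- x0 >= nx / 3 & x0 < 2 * nx / 3 & y0 >= ny / 3 & y0 < 2 * ny / 3
  cls[wm] <- "WM"
  csf <- x0 >= nx / 2 - 1 & x0 < nx / 2 + 1 & y0 >= ny / 2 - 1 &
    y0 < ny / 2 + 1
  cls[csf] <- "CSF"
  active <- brain & y0 >= ny / 6 & y0 < ny / 3
  cls[active] <- "GM_active"
  pv <- active & y0 == ny / 3 - 1 & x0 >= nx / 3 & x0 < 2 * nx / 3
  cls[pv] <- "GM_active_pv"
  data.frame(x = x0 + 1L, y = y0 + 1L,
             z = rep(seq_len(nz), each = nx * ny), class = cls)
}

.clip <- function(x, lo, hi = Inf) pmin(pmax(x, lo), hi)

#' Generate a synthetic ASL/BOLD dataset with ground truth
#'
#' Builds a 4D tag-control alternating time series: per voxel,
#' baseline x (1 + BOLD response time course) plus a signed perfusion term
#' alternating with tag/control parity and modulated by the CBF response,
#' plus white Gaussian noise scaled so that the resting ASL SNR of a single
#' subtracted volume matches the specification. BOLD response amplitudes are
#' derived from each voxel's true M, CBF and CMRO2 ratios through
#' [davisForward()]; partial-volume voxels mix grey- and white-matter signal.
#' All randomness (truth heterogeneity, then noise) flows from the single
#' seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return An [ASLPhantom-class]; ground truth in `rowData`, the
#'   specification and realised noise SD in `metadata`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (spec@snr <= 0) stop("snr must be positive")
  pm <- spec@params
  fc <- spec@field
  dp <- davisParams(fc)
  set.seed(spec@seed)

  vox <- .classMap(spec@grid)
  V <- nrow(vox)
  cls <- vox$class
  gm <- cls %in% c("GM_inactive", "GM_active", "GM_active_pv")
  act <- cls %in% c("GM_active", "GM_active_pv")

  ev <- if (isTRUE(pm$anchor)) anchorExtravascularScale()
        else extravascularModel()
  Mfield <- simulateHypercapniaCalibration(physiology(), fc, ev)@M

  base <- numeric(V)
  base[gm] <- pm$baseGM
  base[cls == "WM"] <- pm$baseWM
  base[cls == "CSF"] <- pm$baseCSF
  perf <- numeric(V)
  perf[gm] <- .clip(rnorm(sum(gm), pm$perfusionGM, pm$perfusionSD),
                    0.6 * pm$perfusionGM, 1.4 * pm$perfusionGM)
  perf[cls == "WM"] <- pm$perfusionWM
  perf[cls == "CSF"] <- pm$perfusionCSF

  fm <- rep(1, V); fh <- rep(1, V); r <- rep(1, V)
  M <- rep(NA_real_, V)
  M[gm] <- Mfield
  nact <- sum(act)
  fm[act] <- .clip(rnorm(nact, pm$fMotor, pm$fMotorSD), 0.2)
  fh[act] <- .clip(rnorm(nact, pm$fHc, pm$fHcSD), 0.2)
  r[act] <- .clip(rnorm(nact, pm$rMotor, pm$rMotorSD), 0.5)
  M[act] <- Mfield * .clip(rnorm(nact, 1, pm$MRelSD), 0.3)

  dBm <- numeric(V); dBh <- numeric(V)
  dBm[act] <- davisForward(M[act], fm[act], r[act], dp)
  dBh[act] <- davisForward(M[act], fh[act], 1, dp)

  # partial-volume voxels: mix with white matter at pvWeight grey fraction;
  # measured responses are signal-weighted mixtures of the pure-tissue ones
  pv <- cls == "GM_active_pv"
  if (any(pv)) {
    w <- pm$pvWeight
    basePV <- w * pm$baseGM + (1 - w) * pm$baseWM
    dBm[pv] <- w * pm$baseGM * dBm[pv] / basePV
    dBh[pv] <- w * pm$baseGM * dBh[pv] / basePV
    perfPV <- w * perf[pv] + (1 - w) * pm$perfusionWM
    fm[pv] <- (w * perf[pv] * fm[pv] + (1 - w) * pm$perfusionWM) / perfPV
    fh[pv] <- (w * perf[pv] * fh[pv] + (1 - w) * pm$perfusionWM) / perfPV
    base[pv] <- basePV
    perf[pv] <- perfPV
    # effective calibration parameters implied by the mixed responses
    M[pv] <- ifelse(fh[pv] > 1,
                    dBh[pv] / (1 - fh[pv]^(dp@alpha - dp@beta)), NA_real_)
    r[pv] <- ifelse(is.finite(M[pv]) & dBm[pv] < M[pv] & fm[pv] > 0,
                    fm[pv]^((dp@beta - dp@alpha) / dp@beta) *
                      (1 - dBm[pv] / M[pv])^(1 / dp@beta), NA_real_)
  }

  design <- buildDesign(spec@paradigm)
  n <- nrow(design@X)
  x1 <- design@X[, "tagcontrol"]
  cm <- design@X[, "bold_motor_AB"] + design@X[, "bold_motor_CD"]
  ch <- design@X[, "bold_hc"]

  Y <- outer(base, rep(1, n)) +
    outer(base * dBm, cm) + outer(base * dBh, ch) +
    outer(perf, x1) +
    outer(perf * (fm - 1), x1 * cm) + outer(perf * (fh - 1), x1 * ch)
  if (pm$driftAmplitude > 0) {
    ramp <- seq(-0.5, 0.5, length.out = n)
    Y <- Y + outer(ifelse(cls == "background", 0, pm$driftAmplitude), ramp)
  }
  sigma <- if (is.infinite(spec@snr)) 0 else
    pm$perfusionGM / (spec@snr * sqrt(2))
  if (sigma > 0) Y <- Y + matrix(rnorm(V * n, sd = sigma), V, n)

  rd <- S4Vectors::DataFrame(
    vox, baseline = base, perfusion = perf, M = M,
    f_motor = fm, f_hc = fh, r_motor = r,
    dBOLD_motor = dBm, dBOLD_hc = dBh)
  cd <- S4Vectors::DataFrame(
    volume = seq_len(n) - 1L,
    time = (seq_len(n) - 1) * spec@paradigm@TR,
    tag = rep_len(c(TRUE, FALSE), n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = Y), rowData = rd, colData = cd,
    metadata = list(spec = spec, sigma = sigma, Mfield = Mfield,
                    evScale = ev@scale))
  new("ASLPhantom", se)
}

#' Ground truth of a phantom
#'
#' @param phantom an [ASLPhantom-class].
#' @return data.frame of per-voxel truth (coordinates, tissue class, baseline
#'   and perfusion amplitudes, effective M, CBF ratios, CMRO2 ratio, BOLD
#'   responses).
#' @export
groundTruth <- function(phantom)
  as.data.frame(SummarizedExperiment::rowData(phantom))

#' True per-voxel response summaries
#'
#' Ground-truth counterpart of [normalizeResponses()] output, usable with
#' [applyExclusion()] and [subjectEstimates()] to form the reference
#' ("true") subject-level estimates for a given voxel set.
#'
#' @param phantom an [ASLPhantom-class].
#' @return data.frame with the columns of [normalizeResponses()] filled from
#'   ground truth.
#' @export
trueSummaries <- function(phantom) {
  g <- groundTruth(phantom)
  data.frame(voxel = seq_len(nrow(g)),
             dBOLD_motor = g$dBOLD_motor, dBOLD_hc = g$dBOLD_hc,
             f_motor = g$f_motor, f_hc = g$f_hc,
             z_motor_AB = NA_real_, z_perfusion = NA_real_,
             perfused = g$perfusion > 0)
}

#' Baseline tag-control difference volume
#'
#' @param phantom an [ASLPhantom-class].
#' @param pair which baseline tag-control pair to subtract (default the
#'   first; the pair must fall in the leading rest period).
#' @return numeric vector, control minus tag, one value per voxel.
#' @export
baselineDifferenceVolume <- function(phantom, pair = 1L) {
  Y <- SummarizedExperiment::assay(phantom, "signal")
  Y[, 2L * pair] - Y[, 2L * pair - 1L]
}

#' Write a phantom to disk as NIfTI + plain-text sidecars
#'
#' Writes the 4D time series as NIfTI (double precision, 4.1 x 4.1 x 5 mm
#' voxels), the paradigm as a text table of (onset, duration, condition), the
#' ground truth as CSV, and the specification as a DCF header. The trio
#' round-trips bit-exactly through [readPhantom()].
#'
#' @param phantom an [ASLPhantom-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- S4Vectors::metadata(phantom)
  spec <- meta$spec
  grid <- spec@grid
  Y <- SummarizedExperiment::assay(phantom, "signal")
  arr <- array(Y, dim = c(grid, ncol(Y)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(4.1, 4.1, 5.0, spec@paradigm@TR)
  paths <- c(
    data = file.path(dir, "asl_bold.nii.gz"),
    paradigm = file.path(dir, "paradigm.txt"),
    truth = file.path(dir, "truth.csv"),
    spec = file.path(dir, "spec.dcf"))
  RNifti::writeNifti(img, paths["data"], datatype = "double")
  par <- spec@paradigm
  ptab <- rbind(
    data.frame(onset = par@motorBlocks[, 1],
               duration = par@motorBlocks[, 2], condition = "motor"),
    data.frame(onset = par@hypercapniaBlocks[, 1],
               duration = par@hypercapniaBlocks[, 2],
               condition = "hypercapnia"))
  writeLines(c(sprintf("# TR %g", par@TR),
               sprintf("# total %g", par@totalDuration),
               sprintf("%g %g %s", ptab$onset, ptab$duration,
                       ptab$condition)),
             paths["paradigm"])
  utils::write.csv(groundTruth(phantom), paths["truth"], row.names = FALSE)
  write.dcf(data.frame(field = spec@field@field, snr = spec@snr,
                       seed = spec@seed,
                       grid = paste(grid, collapse = "x"),
                       sigma = meta$sigma), paths["spec"])
  invisible(paths)
}

#' Read a phantom written by [writePhantom()]
#'
#' @param dir directory containing `asl_bold.nii.gz`, `paradigm.txt`,
#'   `truth.csv` and `spec.dcf`.
#' @return An [ASLPhantom-class].
#' @export
readPhantom <- function(dir) {
  hdr <- read.dcf(file.path(dir, "spec.dcf"))
  grid <- as.integer(strsplit(hdr[1, "grid"], "x")[[1]])
  img <- RNifti::readNifti(file.path(dir, "asl_bold.nii.gz"))
  arr <- as.array(img)
  Y <- matrix(arr, prod(grid), dim(arr)[4])
  lines <- readLines(file.path(dir, "paradigm.txt"))
  TR <- as.numeric(sub("# TR ", "", lines[1]))
  total <- as.numeric(sub("# total ", "", lines[2]))
  ptab <- utils::read.table(text = lines[-(1:2)],
                            col.names = c("onset", "duration", "condition"))
  par <- paradigm(TR,
                  ptab[ptab$condition == "motor", 1:2],
                  ptab[ptab$condition == "hypercapnia", 1:2], total)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  spec <- phantomSpec(field = hdr[1, "field"],
                      snr = as.numeric(hdr[1, "snr"]),
                      seed = as.integer(hdr[1, "seed"]),
                      grid = grid, par = par)
  n <- ncol(Y)
  cd <- S4Vectors::DataFrame(
    volume = seq_len(n) - 1L, time = (seq_len(n) - 1) * TR,
    tag = rep_len(c(TRUE, FALSE), n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = Y), rowData = S4Vectors::DataFrame(truth),
    colData = cd,
    metadata = list(spec = spec, sigma = as.numeric(hdr[1, "sigma"])))
  new("ASLPhantom", se)
}
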