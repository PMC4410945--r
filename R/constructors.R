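#' Construct field constants
#'
#' @param B0 field strength (T).
#' @param C1,C2 intravascular R2* law coefficients (1/s).
#' @param R2E0 resting extravascular decay rate (1/s).
#' @param TEactual,TEoptimal echo times; values > 0.5 are interpreted as
#'   milliseconds and converted (internal units are seconds throughout).
#' @param beta Davis susceptibility exponent.
#' @param field label.
#' @return A [FieldConstants-class] object.
#' @export
fieldConstants <- function(B0, C1, C2, R2E0, TEactual, TEoptimal, beta,
                           field = sprintf("%gT", B0)) {
  new("FieldConstants", B0 = B0, C1 = C1, C2 = C2, R2E0 = R2E0,
      TEactual = .asSeconds(TEactual), TEoptimal = .asSeconds(TEoptimal),
      beta = beta, field = field)
}

# configuration may give TE in ms; anything > 0.5 cannot be seconds here
.asSeconds <- function(te) if (te > 0.5) te / 1000 else te

.presetTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- utils::read.csv(system.file("extdata", "field_presets.csv",
                                            package = "boldcal"),
                                stringsAsFactors = FALSE)
    cache
  }
})

.normFieldName <- function(field) {
  key <- tolower(gsub("[ _]", "", as.character(field)))
  key <- sub("p", ".", key, fixed = TRUE)
  key <- sub("t$", "", key)
  hit <- match(key, c("1.5", "3", "7"))
  if (is.na(hit)) stop("unknown field preset: ", field,
                       ' (use "1.5T", "3T" or "7T")')
  c("1.5T", "3T", "7T")[hit]
}

#' Shipped field presets (1.5, 3 and 7 T)
#'
#' Returns the relaxometry/echo-time constants of the three supported field
#' strengths, read from the versioned parameter file shipped with the package.
#'
#' @param field one of "1.5T", "3T", "7T" (also accepts "1p5", "3", "7").
#' @return A [FieldConstants-class] object.
#' @examples
#' fieldPreset("3T")
#' @export
fieldPreset <- function(field = c("3T", "1.5T", "7T")) {
  if (length(field) > 1) field <- field[1]
  name <- .normFieldName(field)
  p <- .presetTable()
  r <- p[p$field == name, ]
  fieldConstants(B0 = r$B0, C1 = r$C1, C2 = r$C2, R2E0 = r$R2E0,
                 TEactual = r$TE_actual_s, TEoptimal = r$TE_optimal_s,
                 beta = r$beta, field = name)
}

#' Default single-subtraction ASL SNR preset for a field
#'
#' Configuration values (not claims about any particular scanner) ordered with
#' field strength; see the methods vignette for how they were chosen.
#'
#' @param field field name accepted by [fieldPreset()].
#' @return numeric SNR target.
#' @export
snrPreset <- function(field) {
  p <- .presetTable()
  p$snr_preset[p$field == .normFieldName(field)]
}

#' Construct baseline physiology
#'
#' Defaults describe an average healthy grey-matter voxel: Hct 0.44, resting
#' OEF 0.4, total CBV 0.05 distributed 20/40/40% over
#' arterial/capillary/venous compartments, arterial saturation 0.98, capillary
#' desaturation weight 0.4 and Grubb exponent 0.2.
#'
#' @param Hct haematocrit fraction.
#' @param OEF0 baseline oxygen extraction fraction.
#' @param VT0 baseline total blood volume fraction.
#' @param Omega length-3 numeric of compartment fractions (arterial,
#'   capillary, venous); must sum to 1.
#' @param Ya arterial oxygen saturation.
#' @param kappaC capillary desaturation weight.
#' @param alpha Grubb exponent.
#' @return A [Physiology-class] object.
#' @export
physiology <- function(Hct = 0.44, OEF0 = 0.4, VT0 = 0.05,
                       Omega = c(0.2, 0.4, 0.4), Ya = 0.98, kappaC = 0.4,
                       alpha = 0.2) {
  stopifnot(length(Omega) == 3)
  new("Physiology", Hct = Hct, OEF0 = OEF0, VT0 = VT0,
      OmegaA = Omega[1], OmegaC = Omega[2], OmegaV = Omega[3],
      Ya = Ya, kappaC = kappaC, alpha = alpha)
}

#' Construct the extravascular signal model
#'
#' @param kLin linear large-vessel coefficient.
#' @param kQuad quadratic capillary coefficient (s).
#' @param dchi0 susceptibility difference of fully deoxygenated blood at unit
#'   haematocrit (ppm).
#' @param scale global magnitude factor (see [anchorExtravascularScale()]).
#' @return An [ExtravascularModel-class] object.
#' @export
extravascularModel <- function(kLin = 4.3, kQuad = 0.04, dchi0 = 0.264,
                               scale = 1) {
  new("ExtravascularModel", kLin = kLin, kQuad = kQuad, dchi0 = dchi0,
      scale = scale)
}

#' Construct Davis model exponents
#'
#' @param beta susceptibility exponent, or a [FieldConstants-class] whose
#'   `beta` is used.
#' @param alpha Grubb exponent (0.2 at all fields).
#' @return A [DavisParams-class] object.
#' @examples
#' davisParams(fieldPreset("3T"))
#' @export
davisParams <- function(beta, alpha = 0.2) {
  if (is(beta, "FieldConstants")) beta <- beta@beta
  new("DavisParams", alpha = alpha, beta = beta)
}

#' Construct an HRF specification
#'
#' @param meanLag mean lag (s).
#' @param sd standard deviation (s).
#' @return An [HRFSpec-class] object.
#' @export
hrfSpec <- function(meanLag, sd) new("HRFSpec", meanLag = meanLag, sd = sd)

#' Task and hypercapnia HRF defaults
#'
#' Gamma responses with mean lag 6 s / SD 3 s for the motor task and mean lag
#' 42 s / SD 30 s for hypercapnia (the slow cerebrovascular response to a
#' change of inspired gas).
#' @return An [HRFSpec-class].
#' @export
taskHRF <- function() hrfSpec(6, 3)

#' @rdname taskHRF
#' @export
hypercapniaHRF <- function() hrfSpec(42, 30)

#' Construct a paradigm
#'
#' @param TR repetition time (s).
#' @param motorBlocks matrix/data.frame with columns (onset, duration) s.
#' @param hypercapniaBlocks matrix with columns (onset, duration) s.
#' @param totalDuration total length (s).
#' @return A [Paradigm-class] object.
#' @export
paradigm <- function(TR, motorBlocks, hypercapniaBlocks, totalDuration) {
  mb <- unname(as.matrix(motorBlocks))
  hb <- unname(as.matrix(hypercapniaBlocks))
  if (!nrow(hb)) hb <- matrix(numeric(0), 0, 2)
  colnames(mb) <- colnames(hb) <- c("onset", "duration")
  new("Paradigm", TR = TR, motorBlocks = mb, hypercapniaBlocks = hb,
      totalDuration = totalDuration)
}

#' The default acquisition paradigm
#'
#' 48 s leading rest; four 48 s motor blocks each followed by 48 s rest; two
#' 180 s hypercapnia blocks each followed by 120 s of air; TR 3 s; total
#' 1032 s (17 min 12 s, 344 volumes).
#'
#' @param TR repetition time (s).
#' @param leadIn leading rest before the first motor block (s).
#' @return A [Paradigm-class] object.
#' @export
defaultParadigm <- function(TR = 3, leadIn = 48) {
  motor <- cbind(onset = leadIn + (0:3) * 96, duration = 48)
  hc <- cbind(onset = leadIn + 384 + c(0, 300), duration = 180)
  paradigm(TR, motor, hc, totalDuration = leadIn + 384 + 600)
}

#' Number of volumes in a paradigm
#' @param par a [Paradigm-class].
#' @return integer volume count.
#' @export
nVolumes <- function(par) as.integer(round(par@totalDuration / par@TR))

#' Construct an ROI specification
#'
#' @param fraction top fraction of voxels selected (default 0.40).
#' @param kind "BOLD_GM" or "BOLD_only".
#' @return An [ROISpec-class] object.
#' @export
roiSpec <- function(fraction = 0.4, kind = c("BOLD_GM", "BOLD_only")) {
  new("ROISpec", fraction = fraction, kind = match.arg(kind))
}
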