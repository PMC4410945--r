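test_that("blood R2* follows the quadratic oxygenation law at each field", {
  expect_equal(bloodR2star(1, fieldPreset("3T")), 13.8)
  expect_equal(bloodR2star(0, fieldPreset("7T")), 75.2 + 831.9)
  expect_equal(bloodR2star(0.6, fieldPreset("1.5T")), 7.2 + 95.1 * 0.16)
  expect_error(bloodR2star(1.2, fieldPreset("3T")), "\\[0, 1\\]")
  expect_error(bloodR2star(-0.1, fieldPreset("3T")), "\\[0, 1\\]")
})

test_that("hemodynamic state obeys Fick, saturation ordering and Grubb scaling", {
  phys <- physiology()
  st <- hemodynamicState(1.3, 1.1, phys)
  expect_equal(st@OEF, 0.4 * 1.1 / 1.3)
  expect_equal(st@Yv, 0.98 * (1 - st@OEF))
  expect_equal(st@Yc, 0.98 * (1 - 0.4 * st@OEF))
  expect_true(st@Ya >= st@Yc && st@Yc >= st@Yv)
  expect_equal(st@Va + st@Vc + st@Vv, 0.05 * 1.3^0.2)
  expect_error(hemodynamicState(0.1, 1.2), "OEF")
})

test_that("extravascular rate vanishes without deoxyhemoglobin and scales with B0", {
  phys <- physiology()
  fc <- fieldPreset("3T")
  ev <- extravascularModel()
  # fully oxygenated everywhere: no susceptibility difference, no effect
  st <- hemodynamicState(1, 1, phys)
  st@Ya <- st@Yc <- st@Yv <- 1
  expect_equal(extravascularDeltaR2star(st, phys, fc, ev), 0)

  # capillary-only term quadruples when B0 doubles
  base <- hemodynamicState(1, 1, phys)
  onlyCap <- function(fc) {
    s <- base; s@Va <- 1e-12; s@Vv <- 1e-12
    extravascularDeltaR2star(s, phys, fc, ev)
  }
  fc6 <- fieldConstants(6, 13.8, 276, 18.1, 0.017, 0.035, 1.3)
  expect_equal(onlyCap(fc6) / onlyCap(fc), 4, tolerance = 1e-9)

  # frozen scalar oracle: independent hand evaluation of the closed form at
  # 3 T baseline (gamma*B0*dchi*Hct = 93.21840 rad/s; saturations
  # 0.98/0.8232/0.588; volumes 0.01/0.02/0.02)
  u <- 2.675e8 * 3 * 0.264e-6 * 0.44
  expected <- 4.3 * (0.01 * u * 0.02 + 0.02 * u * 0.412) +
    0.04 * 0.02 * (u * (1 - 0.8232))^2
  expect_equal(extravascularDeltaR2star(base, phys, fc, ev), expected,
               tolerance = 1e-12)
})

test_that("compartment signals reduce to 1 at TE = 0 and increase with oxygenation", {
  phys <- physiology()
  ev <- extravascularModel()
  fc0 <- fieldPreset("3T"); fc0@TEactual <- 1e-12
  st <- hemodynamicState(1, 1, phys)
  cs <- compartmentSignals(st, phys, fc0, ev)
  expect_equal(c(cs@Sa, cs@Sc, cs@Sv, cs@Se, cs@S), rep(1, 5),
               tolerance = 1e-9)

  # frozen formula oracle at 3 T baseline defaults
  fc <- fieldPreset("3T")
  dR2e <- extravascularDeltaR2star(st, phys, fc, ev)
  Sexp <- 0.95 * exp(-0.017 * (18.1 + dR2e)) +
    0.01 * exp(-0.017 * (13.8 + 276 * 0.02^2)) +
    0.02 * exp(-0.017 * (13.8 + 276 * (1 - 0.8232)^2)) +
    0.02 * exp(-0.017 * (13.8 + 276 * 0.412^2))
  tot <- compartmentSignals(st, phys, fc, ev)@S
  expect_equal(tot, Sexp, tolerance = 1e-12)
  expect_gt(tot, 0); expect_lt(tot, 1)

  # raising venous oxygenation strictly raises the total signal
  hi <- st; hi@Yv <- st@Yv + 0.05
  expect_gt(compartmentSignals(hi, phys, fc, ev)@S, tot)

  # total signal strictly decreasing in TE
  fcLong <- fc; fcLong@TEactual <- fc@TEactual * 2
  expect_lt(compartmentSignals(st, phys, fcLong, ev)@S, tot)
})

test_that("BOLD response is zero at rest and positive for an isometabolic flow increase", {
  phys <- physiology()
  for (f in c("1.5T", "3T", "7T")) {
    fc <- fieldPreset(f)
    b <- hemodynamicState(1, 1, phys)
    expect_equal(boldResponse(b, b, phys, fc), 0)
    expect_gt(boldResponse(b, hemodynamicState(1.3, 1, phys), phys, fc), 0)
  }
})

test_that("simulated hypercapnia calibration matches the Davis inversion of its own response", {
  phys <- physiology()
  fc <- fieldPreset("3T")
  s <- simulateHypercapniaCalibration(phys, fc)
  db <- boldResponse(hemodynamicState(1, 1, phys),
                     hemodynamicState(1.3, 1, phys), phys, fc)
  expect_equal(s@dBOLD, db)
  expect_equal(s@M, db / (1 - 1.3^(0.2 - 1.3)), tolerance = 1e-12)
  expect_error(simulateHypercapniaCalibration(phys, fc, dCBF = 0),
               "calibration undefined")

  # TE scaling identity at 1.5 T where actual and optimal TE coincide
  s15 <- simulateHypercapniaCalibration(fc = fieldPreset("1.5T"))
  expect_equal(s15@M, s15@Mopt)

  # dBOLD -> 0 as f -> 1 and as total blood volume vanishes
  expect_lt(abs(simulateHypercapniaCalibration(phys, fc, dCBF = 1e-6)@dBOLD),
            1e-7)
  tiny <- simulateHypercapniaCalibration(physiology(VT0 = 1e-4), fc)@dBOLD
  expect_lt(abs(tiny), 0.01 * s@dBOLD)
})

test_that("M is ordered with field strength and only mildly sensitive to the challenge size", {
  ms <- vapply(c("1.5T", "3T", "7T"),
               function(f) simulateHypercapniaCalibration(
                 fc = fieldPreset(f))@Mopt, numeric(1))
  expect_true(ms[["7T"]] > ms[["3T"]] && ms[["3T"]] > ms[["1.5T"]])

  # the Davis form is not exact for the compartment model: M drifts slowly
  # (but monotonically) with the assumed CBF challenge -- the residual model
  # mismatch, recorded here as a regression bound
  fc <- fieldPreset("3T")
  curve <- vapply(seq(0.2, 0.4, by = 0.05),
                  function(d) simulateHypercapniaCalibration(
                    fc = fc, dCBF = d)@M, numeric(1))
  dev <- abs(curve / simulateHypercapniaCalibration(fc = fc)@M - 1)
  expect_gt(max(dev), 1e-3)   # the mismatch is real ...
  expect_lt(max(dev), 0.05)   # ... and small
  expect_true(all(diff(curve) > 0))
})

test_that("anchoring pins 3 T M and leaves other fields as predictions", {
  ev <- anchorExtravascularScale(targetM = 0.076)
  expect_equal(simulateHypercapniaCalibration(fc = fieldPreset("3T"),
                                              ev = ev)@M, 0.076,
               tolerance = 1e-8)
  expect_gt(ev@scale, 0)
  m7 <- simulateHypercapniaCalibration(fc = fieldPreset("7T"), ev = ev)@M
  expect_gt(m7, 0.076)
})

test_that("physiology sweeps are monotone in CBV and widen with field", {
  sw <- lapply(c("1.5T", "3T", "7T"),
               function(f) sweepPhysiology(fieldPreset(f)))
  rngCBV <- vapply(sw, function(s)
    diff(range(s$M_opt[s$sweep == "CBV"])), numeric(1))
  rngOEF <- vapply(sw, function(s)
    diff(range(s$M_opt[s$sweep == "OEF"])), numeric(1))
  for (s in sw)
    expect_true(all(diff(s$M_opt[s$sweep == "CBV"]) > 0))
  expect_true(all(diff(rngCBV) > 0))
  expect_true(all(diff(rngOEF) > 0))

  # single-element sweep equals the direct simulation
  one <- sweepPhysiology(fieldPreset("3T"), VT0values = 0.05,
                         OEF0values = numeric(0))
  expect_equal(one$M, simulateHypercapniaCalibration(fc = fieldPreset("3T"))@M)
})

test_that("field presets reproduce the published acquisition table", {
  p15 <- fieldPreset("1.5T"); p3 <- fieldPreset("3T"); p7 <- fieldPreset("7T")
  expect_equal(c(p15@C1, p15@C2, p15@R2E0, p15@TEactual), c(7.2, 95.1, 11.6, 0.050))
  expect_equal(c(p3@C1, p3@C2, p3@R2E0, p3@TEactual), c(13.8, 276.0, 18.1, 0.017))
  expect_equal(c(p7@C1, p7@C2, p7@R2E0, p7@TEactual), c(75.2, 831.9, 30.8, 0.017))
  expect_equal(c(p15@TEoptimal, p3@TEoptimal, p7@TEoptimal), c(0.050, 0.035, 0.025))
  expect_equal(c(p15@beta, p3@beta, p7@beta), c(1.5, 1.3, 1.0))
  expect_equal(fieldPreset("1p5")@B0, 1.5)
  expect_error(fieldPreset("4T"), "unknown field")
})
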