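# The double-sigmoid melting model: evaluation, normalization, fitting and
# mono/biphasic classification.

test_that("evalMeltingModel obeys midpoints, asymptotes and symmetry", {
  p1 <- c(a = 0.8, x0 = 50, b = 3, c = 0, x2 = 80, d = 3)
  expect_equal(evalMeltingModel(p1, 50), 0.4)            # a/2 at x0
  expect_lt(evalMeltingModel(p1, -200), 1e-10)           # low-T asymptote
  p2 <- c(a = 0.5, x0 = 50, b = 3, c = 0.5, x2 = 80, d = 3)
  expect_equal(evalMeltingModel(p2, 1e4), 1)             # a + c
  ## midway between symmetric transitions the tails cancel exactly
  expect_equal(evalMeltingModel(p2, 65), 0.5)
  ## monotone for non-negative amplitudes
  t <- seq(5, 95, 0.5)
  expect_true(all(diff(evalMeltingModel(p2, t)) >= 0))
  expect_error(evalMeltingModel(c(a = 1, x0 = 50, b = -1, c = 0, x2 = 80,
                                  d = 3), 50), "positive")
  expect_error(evalMeltingModel(c(a = 1, x0 = 50, b = 1), 50), "missing")
})

test_that("normalizeEllipticity is affine-invariant and oriented upward", {
  ramp <- seq(0, 1, length.out = 21)
  expect_equal(normalizeEllipticity(ramp), ramp)          # idempotent
  expect_equal(normalizeEllipticity(-ramp), ramp)         # flipped
  set.seed(801)
  for (i in 1:10) {
    raw <- cumsum(runif(30, -0.2, 1))
    aff <- runif(1, 0.2, 5) * raw + runif(1, -10, 10)
    expect_equal(normalizeEllipticity(raw), normalizeEllipticity(aff))
    expect_equal(normalizeEllipticity(raw), normalizeEllipticity(-aff))
  }
  expect_error(normalizeEllipticity(rep(1, 10)), "constant")
})

test_that("MeltingCurve enforces its structural invariants", {
  expect_error(MeltingCurve(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(MeltingCurve(c(2, 1, 3), c(1, 2, 3)), "increasing")
  cv <- MeltingCurve(seq(5, 95, 5), seq(0, 1, length.out = 19), "x")
  expect_equal(length(cv), 19L)
  expect_equal(curveId(cv), "x")
  ## too few points or too narrow a span refuse to fit
  expect_error(fitMelting(MeltingCurve(1:5, 1:5 / 5)), "12 points")
  expect_error(
    fitMelting(MeltingCurve(seq(50, 64, 1), seq(0, 1, length.out = 15))),
    "span")
  expect_error(
    fitMelting(makeMeltingCurve(0, 50, 3, 0, 80, 3)), "degenerate")
})

test_that("noiseless fits recover the published transitions to < 0.1 degC", {
  mref <- meltingReference()
  mono <- mref[mref$model == "monophasic" & mref$tm_c < 90, ]
  for (i in seq_len(nrow(mono))) {
    cv <- makeMeltingCurve(1, mono$tm_c[i], 3, 0, 80, 3,
                           curveId = mono$construct[i])
    fit <- fitMelting(cv, "monophasic")
    expect_lt(abs(meltingTemperatures(fit)[["tm1"]] - mono$tm_c[i]), 0.1)
  }
  bi <- mref[mref$model == "biphasic", ]
  for (cs in unique(bi$construct)) {
    tm <- bi$tm_c[bi$construct == cs]
    cv <- makeMeltingCurve(0.5, tm[1], 3, 0.5, tm[2], 3, curveId = cs)
    fit <- fitMelting(cv, "biphasic")
    got <- meltingTemperatures(fit)
    expect_lt(abs(got[["tm1"]] - tm[1]), 0.1)
    expect_lt(abs(got[["tm2"]] - tm[2]), 0.1)
  }
})

test_that("biphasic fits are reported in canonical order tm1 < tm2", {
  cv <- makeMeltingCurve(0.3, 75, 2, 0.7, 45, 4)  # generated reversed
  fit <- fitMelting(cv, "biphasic")
  tm <- meltingTemperatures(fit)
  expect_lt(tm[["tm1"]], tm[["tm2"]])
  expect_lt(abs(tm[["tm1"]] - 45), 0.1)
  expect_lt(abs(tm[["tm2"]] - 75), 0.1)
  ## amplitudes follow their transitions through the swap
  expect_equal(unname(coef(fit)[["a"]]), 0.7, tolerance = 1e-3)
})

test_that("classifyTransition separates biphasic from monophasic curves", {
  set.seed(802)
  ## biphasic, midpoints 30 degC apart, noise sd 0.02
  callsBi <- vapply(1:20, function(s) {
    cv <- makeMeltingCurve(0.5, 45, 3, 0.5, 75, 3, noiseSd = 0.02,
                           seed = 9000 + s)
    classifyTransition(cv)$model
  }, character(1))
  expect_gte(mean(callsBi == "biphasic"), 0.95)

  callsMono <- vapply(1:20, function(s) {
    cv <- makeMeltingCurve(1, 60, 3, 0, 80, 3, noiseSd = 0.02,
                           seed = 9100 + s)
    classifyTransition(cv)$model
  }, character(1))
  expect_gte(mean(callsMono == "monophasic"), 0.95)

  ## coincident midpoints collapse to the parsimonious model
  same <- makeMeltingCurve(0.5, 60, 3, 0.5, 60, 3)
  expect_equal(classifyTransition(same)$model, "monophasic")

  ## affine transforms of the raw signal do not change the call
  cv <- makeMeltingCurve(0.5, 45, 3, 0.5, 75, 3, noiseSd = 0.02, seed = 7)
  flipped <- MeltingCurve(temperatures(cv), -3 * ellipticities(cv) + 11)
  expect_equal(classifyTransition(cv)$model,
               classifyTransition(flipped)$model)
})

test_that("noisy parameter recovery stays within half a degree", {
  set.seed(803)
  errs <- vapply(1:20, function(s) {
    cv <- makeMeltingCurve(0.5, 49.52, 3, 0.5, 70, 3, noiseSd = 0.02,
                           seed = 9200 + s)
    tm <- meltingTemperatures(fitMelting(cv, "biphasic"))
    max(abs(tm[["tm1"]] - 49.52), abs(tm[["tm2"]] - 70))
  }, numeric(1))
  expect_gte(mean(errs < 0.5), 0.95)
})
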