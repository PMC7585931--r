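test_that("default protocol reproduces the printed session timings", {
  p <- defaultProtocol()
  expect_identical(p$total_length_s[p$id == "Exp1"], 750)
  expect_identical(p$total_length_s[p$id == "Exp5"], 1050)
  expect_identical(p$total_length_s[p$id == "Exp7"], 1050)
  expect_identical(p$total_length_s[p$id == "Exp8"], 750)
  expect_identical(p$gas_switch_s[p$id == "Exp3"], 105)
  expect_identical(p$gas_switch_s[p$id == "Exp6"], 105)
  expect_identical(sum(p$n_trials, na.rm = TRUE), 120)
  expect_identical(p$id, paste0("Exp", 1:8))
})

test_that("stimulation events expand to the right pulse counts", {
  p <- defaultProtocol()
  ev1 <- experimentEvents(p[p$id == "Exp1", ])
  expect_identical(sum(ev1$kind == "stim_train_on"), 30L)
  # 2 s at 5 Hz -> 10 pulses per trial
  expect_identical(sum(ev1$kind == "stim_pulse"), 300L)
  ev5 <- experimentEvents(p[p$id == "Exp5", ])
  # 16 s at 5 Hz -> 80 pulses per trial
  expect_identical(sum(ev5$kind == "stim_pulse"), 15L * 80L)
  ev3 <- experimentEvents(p[p$id == "Exp3", ])
  expect_identical(ev3$kind, "gas_switch")
})

test_that("phantom geometry is seeded, disjoint and non-empty", {
  a <- makePhantom(c(48L, 48L), seed = 4)
  b <- makePhantom(c(48L, 48L), seed = 4)
  expect_identical(a@masks, b@masks)
  expect_false(any(a@masks$artery & a@masks$vein))
  for (m in a@masks[c("artery", "vein", "parenchyma")])
    expect_gt(sum(m), 0)
  tot <- a@masks$artery + a@masks$vein + a@masks$parenchyma +
    a@masks$background
  expect_true(all(tot == 1))
  expect_identical(a@pixelUm, 75)
  expect_error(makePhantom(c(16L, 16L)), "too small")
})

test_that("evoked time courses have the constructed compartment shapes", {
  p <- shortProtocol(nShort = 1)
  ev <- experimentEvents(p[p$id == "Exp1", ])
  rp <- defaultResponseParams()
  cond <- conditionSpec("wt", "chronic")

  none <- evokedTimecourse(data.frame(time_s = numeric(), kind = character(),
                                      value = numeric()),
                           25, 8, rp$artery, cond, "oxygen")
  expect_true(all(none$dHbt == 0) && all(none$dHbr == 0))

  oxy <- evokedTimecourse(ev, 25, 8, rp$artery, cond, "oxygen")
  air <- evokedTimecourse(ev, 25, 8, rp$artery, cond, "air")
  t <- (seq_along(oxy$dHbt) - 1) / 8
  post <- t > 5 + 2                       # after stimulus offset
  expect_gte(min(oxy$dHbt), -1e-12)       # oxygen: monotone return
  expect_lt(min(air$dHbt[post]), 0)       # air: post-stimulus undershoot
  expect_lt(min(oxy$dHbr), 0)             # Hbr washout is negative-going

  # artery leads vein in onset
  veinOxy <- evokedTimecourse(ev, 25, 8, rp$vein, cond, "oxygen")
  expect_lt(which.max(oxy$dHbt), which.max(veinOxy$dHbt))
})

test_that("longer stimulation drives a response at least as large", {
  rp <- defaultResponseParams()
  cond <- conditionSpec("wt", "chronic")
  p <- shortProtocol(nShort = 1, nLong = 1)
  ev2 <- experimentEvents(p[p$id == "Exp1", ])
  ev16 <- experimentEvents(p[p$id == "Exp7", ])
  s2 <- evokedTimecourse(ev2, 25, 8, rp$artery, cond, "oxygen")
  s16 <- evokedTimecourse(ev16, 70, 8, rp$artery, cond, "oxygen")
  expect_gte(max(s16$dHbt), max(s2$dHbt))
  # convolution oracle at one interior time point: direct Riemann sum
  drive <- numeric(70 * 8); drive[(10 * 8 + 1):(26 * 8)] <- 1
  k <- ois2d:::gammaKernel(rp$artery$latencyS, rp$artery$kShape,
                           rp$artery$kScale, 8)
  i <- 200
  direct <- sum(drive[i:1] * k[1:i]) / 8 * rp$artery$ampHbt
  expect_equal(s16$dHbt[i], direct, tolerance = 1e-9)
})

test_that("spreading-depression multiplier matches its closed form", {
  chronic <- csdPerturbation(conditionSpec("wt", "chronic"), 100, 8)
  expect_true(all(chronic == 1))
  wt <- conditionSpec("wt", "acute"); ad <- conditionSpec("ad", "acute")
  mWt <- csdPerturbation(wt, 60, 8)
  mAd <- csdPerturbation(ad, 60, 8)
  expect_gt(abs(1 - mAd[1]), abs(1 - mWt[1]))
  # end-of-session envelope: |m - 1| <= A * exp(-t / tau) < 1% of 1
  endT <- 6600
  mEnd <- csdPerturbation(ad, 10, 8, t0S = endT)
  expect_lt(max(abs(mEnd - 1)), 0.01)
  expect_error(conditionSpec("wt", "chronic", csdAmplitude = 0.1),
               "chronic")
})

test_that("simulated recordings are seeded and sized by the protocol", {
  ph <- makePhantom(c(32L, 32L), seed = 3)
  sp <- shortProtocol(nShort = 2)
  cond <- conditionSpec("wt", "chronic")
  r1 <- simulateSession(ph, sp, cond, ttTable(), ttPaths(), seed = 17,
                        experiments = "Exp1")
  r2 <- simulateSession(ph, sp, cond, ttTable(), ttPaths(), seed = 17,
                        experiments = "Exp1")
  expect_identical(r1@experiments$Exp1$intensities,
                   r2@experiments$Exp1$intensities)
  # per-wavelength frame count = total_length_s x 8
  nFrames <- nrow(r1@experiments$Exp1$intensities[[1]])
  expect_identical(nFrames, as.integer(sp$total_length_s[1] * 8))
  expect_identical(length(r1@experiments$Exp1$intensities), 4L)
  expect_true(all(vapply(r1@experiments$Exp1$intensities,
                         function(m) all(m >= 0), logical(1))))
})

test_that("field potential simulation obeys the acquisition constants", {
  sp <- shortProtocol(nShort = 2)
  rec <- simulateLfp(sp, conditionSpec("wt", "chronic"), seed = 5)
  expect_identical(nrow(rec@samples), 16L)
  expect_identical(rec@rateHz, 6000)
  expect_identical(rec@channelSpacingUm, 100)
  expect_identical(length(rec@events), 2L * 10L)  # 2 trials x 10 pulses

  # injected evoked amplitude is group-independent by construction
  wt <- simulateLfp(sp, conditionSpec("wt", "acute"), seed = 5)
  ad <- simulateLfp(sp, conditionSpec("ad", "acute"), seed = 5)
  expect_identical(wt@samples, ad@samples)
})

test_that("a record without stimuli averages to noise", {
  sp <- shortProtocol(gasLengthS = 60)
  rec <- simulateLfp(sp, conditionSpec("wt", "chronic"), seed = 6,
                     experimentId = "Exp3")
  expect_identical(length(rec@events), 0L)
  ep <- epochLfp(rec, events = seq(5, 50, by = 5), preMs = 5, postMs = 50)
  ev <- evokedFieldPotential(ep)
  se <- sd(ev) / sqrt(length(ev))
  expect_lt(abs(mean(ev)), 3 * sd(ev))
})
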