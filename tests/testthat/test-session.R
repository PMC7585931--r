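test_that("dark correction removes a known offset exactly", {
  truth <- matrix(runif(60, 100, 200), 10, 6)
  dark <- runif(6, 5, 20)
  noisy <- sweep(truth, 2, dark, "+")
  out <- darkCorrect(list(noisy), dark)
  expect_equal(out[[1]], truth, tolerance = 1e-12)
  # zero dark frame is the identity
  out0 <- darkCorrect(list(truth), numeric(6))
  expect_identical(out0[[1]], truth)
  expect_error(darkCorrect(list(truth), NULL), "no dark frame")
  # clamping is counted
  expect_message(darkCorrect(list(matrix(1, 2, 2)), rep(5, 2)), "clamped")
})

test_that("epoching returns one epoch per trial of the printed protocol", {
  p <- defaultProtocol()
  for (id in c("Exp1", "Exp5")) {
    row <- p[p$id == id, ]
    series <- rnorm(row$total_length_s * 8)
    ev <- experimentEvents(row)
    tens <- epochTrials(series, ev, preS = row$stim_onset_s,
                        postS = row$trial_length_s - row$stim_onset_s,
                        rateHz = 8)
    expect_identical(tens@nTrials, as.integer(row$n_trials))
    expect_lt(min(tens@timeAxisS), 0)  # includes a pre-stimulus interval
  }
  expect_error(epochTrials(rnorm(100),
                           data.frame(time_s = numeric(),
                                      kind = character(),
                                      value = numeric()), 1, 5, 8),
               "no stimulus-train onsets")
})

test_that("total epochs across the five stimulation experiments is 120", {
  p <- defaultProtocol()
  stim <- p[!is.na(p$n_trials), ]
  total <- 0L
  for (i in seq_len(nrow(stim))) {
    row <- stim[i, ]
    series <- numeric(row$total_length_s * 8)
    tens <- epochTrials(series, experimentEvents(row), row$stim_onset_s,
                        row$trial_length_s - row$stim_onset_s, 8)
    total <- total + tens@nTrials
  }
  expect_identical(total, 120L)
})

test_that("out-of-record trials are excluded with a log, not silently", {
  series <- numeric(100)  # 12.5 s at 8 Hz
  ev <- data.frame(time_s = c(5, 12), kind = "stim_train_on",
                   value = 1:2)
  expect_message(tens <- epochTrials(series, ev, 1, 4, 8), "excluded")
  expect_identical(tens@nTrials, 1L)
})

test_that("trial averaging reduces to the exact mean and SD", {
  a <- sin(seq(0, 2, length.out = 20)); b <- a + 1
  tens <- new("TrialTensor", values = array(rbind(a, b), c(2, 20)),
              timeAxisS = seq(0, by = 0.125, length.out = 20),
              nTrials = 2L)
  avg <- trialAverage(tens)
  expect_equal(avg$mean, (a + b) / 2, tolerance = 1e-12)
  expect_equal(avg$sd, rep(sd(c(0, 1)), 20), tolerance = 1e-9)
  # identical trials: SD collapses to zero
  tens2 <- new("TrialTensor", values = array(rbind(a, a), c(2, 20)),
               timeAxisS = tens@timeAxisS, nTrials = 2L)
  expect_lt(max(trialAverage(tens2)$sd), 1e-7)
  expect_error(trialAverage(new("TrialTensor",
                                values = array(a, c(1, 20)),
                                timeAxisS = tens@timeAxisS,
                                nTrials = 1L)),
               "fewer than 2")
})

test_that("the 1.5-SD rule selects exactly the constructed pixels", {
  set.seed(12)
  nT <- 120; nP <- 400
  timeAxis <- (seq_len(nT) - 1) / 8 - 5
  movie <- matrix(rnorm(nT * nP, 0, 0.01), nT, nP)
  elevated <- sample(nP, 40)
  stimIdx <- timeAxis >= 0 & timeAxis < 5
  # elevate by 5 pre-stimulus SDs of each pixel
  preSd <- apply(movie[timeAxis < 0, ], 2, sd)
  movie[stimIdx, elevated] <- sweep(movie[stimIdx, elevated, drop = FALSE],
                                    2, 5 * preSd[elevated], "+")
  roi <- selectWhiskerRoi(movie, timeAxis, c(0, 5), c(-5, 0), 1.5,
                          shape = c(20L, 20L))
  expect_identical(sort(which(as.vector(roi@pixels))), sort(elevated))

  # raising k never grows the mask
  roi2 <- selectWhiskerRoi(movie, timeAxis, c(0, 5), c(-5, 0), 3,
                           shape = c(20L, 20L))
  expect_true(all(roi2@pixels[roi2@pixels] %in% roi@pixels[roi2@pixels]))
  expect_true(!any(roi2@pixels & !roi@pixels))

  # no modulation -> no-activation error
  flat <- matrix(rnorm(nT * nP, 0, 0.01), nT, nP)
  expect_error(selectWhiskerRoi(flat, timeAxis, c(0, 5), c(-5, 0), 5,
                                shape = c(20L, 20L)),
               "no activation")
})

test_that("ROI series reduce correctly for uniform and single-pixel masks", {
  movie <- matrix(rep(as.numeric(1:10), 4), 10, 4)
  uni <- roiTimeseries(movie, c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(uni, as.numeric(1:10))
  single <- roiTimeseries(movie, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(single, movie[, 2])
  expect_error(roiTimeseries(movie, rep(FALSE, 4)), "empty")
})

test_that("response magnitude is the stimulus-window mean deviation", {
  t <- seq(-5, 19.875, by = 0.125)
  s <- rep(1, length(t)); s[t >= 0 & t < 2] <- 1.05
  expect_equal(responseMagnitude(s, t, c(0, 2)), 0.05, tolerance = 1e-12)
  expect_equal(responseMagnitude(rep(1, length(t)), t, c(0, 2)), 0)
  expect_error(responseMagnitude(s, t, c(30, 32)), "outside")
})

test_that("concatenation preserves duration and annotates boundaries", {
  p <- shortProtocol(nShort = 2, nLong = 2, gasLengthS = 60,
                     hypercapniaLengthS = 90)
  series <- lapply(seq_len(nrow(p)), function(i)
    numeric(p$total_length_s[i] * 8))
  names(series) <- p$id
  cc <- concatenateSession(series, p, 8)
  expect_identical(nrow(cc), as.integer(sum(p$total_length_s) * 8))
  expect_identical(names(attr(cc, "boundaries")), p$id)
  # gaps are real: successive experiments are offset by the gap
  b <- attr(cc, "boundaries")
  expect_equal(unname(b[2] - b[1]),
               p$total_length_s[1] + attr(p, "gap_s"))
  # single experiment is the identity
  one <- concatenateSession(series["Exp1"], p, 8)
  expect_identical(one$value, series$Exp1)
  expect_error(concatenateSession(series, p, 10), "inconsistent")
})

test_that("full session analysis completes with all stages present", {
  run <- ttChronicRun()
  res <- run$result
  expect_s3_class(res, "SessionResult")
  expect_identical(names(res$experiments), run$recording@protocol$id)
  expect_s4_class(res$roi, "RoiMask")
  expect_s4_class(res$airBaseline, "BaselineState")
  expect_true(all(c("artery", "vein") %in% names(res$compartments$masks)))
  # magnitudes exist for the five stimulation experiments
  stimIds <- c("Exp1", "Exp2", "Exp4", "Exp5", "Exp7")
  for (id in stimIds) expect_length(res$experiments[[id]]$magnitude, 3)
  # 16 s responses exceed 2 s responses in Hbt
  expect_gt(res$experiments$Exp7$magnitude[["hbt"]],
            res$experiments$Exp1$magnitude[["hbt"]])
})

test_that("a recording missing the ROI source fails at the ROI stage", {
  ph <- makePhantom(c(32L, 32L), seed = 3)
  sp <- shortProtocol(nShort = 2)
  rec <- simulateSession(ph, sp, conditionSpec("wt", "chronic"),
                         ttTable(), ttPaths(), seed = 21,
                         experiments = c("Exp1", "Exp3"))
  expect_error(suppressMessages(runSession(rec, ttTable(), ttPaths())),
               "stage roi")
})

test_that("the SD-threshold mask finds the active patch at full trial count", {
  ph <- makePhantom(c(32L, 32L), seed = 5)
  sp <- shortProtocol(nShort = 2, nLong = 15)
  rec <- simulateSession(ph, sp, conditionSpec("wt", "chronic"),
                         ttTable(), ttPaths(), seed = 4,
                         experiments = "Exp7")
  ex <- rec@experiments$Exp7
  att <- computeAttenuation(darkCorrect(ex$intensities, ex$dark), 1:80,
                            rec@meta$wavelengths_nm, 8, rec@meta$shape)
  cm <- unmixStack(att, ttTable(), ttPaths(), ttOxygen())
  avg <- trialAverage(epochTrials(fractionalMovie(cm, "hbt"), ex$events,
                                  10, 60, 8))
  roi <- selectWhiskerRoi(avg$mean, avg$timeAxisS, c(0, 16), c(-10, 0),
                          1.5, rec@meta$shape)
  truthRoi <- ph@active & !ph@masks$background
  expect_gt(jaccard(roi@pixels, truthRoi), 0.5)
})
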