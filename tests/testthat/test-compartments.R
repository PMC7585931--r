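test_that("a rank-1 movie is recovered exactly up to sign", {
  set.seed(3)
  nT <- 50; nP <- 36
  s <- sin(seq(0, 3 * pi, length.out = nT))
  m <- rnorm(nP); m <- m / sqrt(sum(m^2))
  movie <- outer(s, m)
  pm <- firstPrincipalMap(movie, rep(TRUE, nP), shape = c(6L, 6L))
  got <- as.vector(pm@spatialMap)
  flip <- sign(sum(got * m))
  expect_lt(max(abs(flip * got - m)), 1e-10)
  expect_equal(pm@explainedFraction, 1, tolerance = 1e-12)
})

test_that("small noise perturbs the map only slightly", {
  set.seed(4)
  nT <- 60; nP <- 49
  s <- sin(seq(0, 3 * pi, length.out = nT))
  m <- abs(rnorm(nP)) + 0.5; m <- m / sqrt(sum(m^2))
  movie <- outer(s, m) + matrix(rnorm(nT * nP, 0, 0.02), nT, nP)
  pm <- firstPrincipalMap(movie, rep(TRUE, nP), shape = c(7L, 7L))
  expect_gt(abs(cor(as.vector(pm@spatialMap), m)), 0.95)
})

test_that("degenerate movies and sign conventions are handled", {
  expect_error(firstPrincipalMap(matrix(2, 10, 9), rep(TRUE, 9),
                                 shape = c(3L, 3L)),
               "zero variance")
  # sign convention: score covaries positively with the regressor
  set.seed(5)
  s <- c(rep(0, 20), rep(1, 20)) + rnorm(40, 0, 0.01)
  m <- runif(16, 0.5, 1)
  movie <- outer(-s, m)   # deliberately inverted
  reg <- c(rep(0, 20), rep(1, 20))
  pm <- firstPrincipalMap(movie, rep(TRUE, 16), stimulusRegressor = reg,
                          shape = c(4L, 4L))
  expect_gt(sum(pm@temporalScore * (reg - mean(reg))), 0)
  expect_true(pm@signFixed)
})

test_that("first and second temporal scores are orthogonal", {
  set.seed(6)
  movie <- matrix(rnorm(80 * 25), 80, 25)
  pm <- firstPrincipalMap(movie, rep(TRUE, 25), shape = c(5L, 5L))
  X <- sweep(movie, 2, colMeans(movie))
  sv <- svd(X)
  second <- sv$u[, 2] * sv$d[2]
  expect_lt(abs(sum(pm@temporalScore * second)), 1e-10)
  expect_gte(sv$d[1], sv$d[2])
  expect_equal(sqrt(sum(pm@spatialMap^2, na.rm = TRUE)), 1,
               tolerance = 1e-12)
})

test_that("vessel masks are disjoint and fail cleanly at quantile 1", {
  run <- ttChronicRun()
  masks <- run$result$compartments$masks
  expect_false(any(masks$artery@pixels & masks$vein@pixels))
  expect_error(vesselMasks(run$result$compartments$hbtMap,
                           run$result$compartments$hbrMap,
                           run$result$roi, quantile = 1),
               "empty")
})

test_that("phantom vessel compartments are recovered from the movies", {
  run <- ttChronicRun()
  ph <- run$phantom
  roiPx <- run$result$roi@pixels
  masks <- run$result$compartments$masks
  expect_gt(jaccard(masks$artery@pixels, ph@masks$artery & roiPx), 0.5)
  expect_gt(jaccard(masks$vein@pixels, ph@masks$vein & roiPx), 0.5)
  # first Hbt score tracks the injected arterial time course
  ev <- run$recording@experiments$Exp7$events
  tr <- run$recording@truth$Exp7$evoked$artery$dHbt
  tens <- epochTrials(tr, ev, 10, 60, 8)
  inj <- trialAverage(tens)$mean
  expect_gt(cor(run$result$compartments$hbtMap@temporalScore, inj), 0.9)
})

test_that("compartment series show the air undershoot and venous lag", {
  run <- ttChronicRun()
  res <- run$result
  airArt <- res$experiments$Exp4$compartmentAverage$artery$hbt
  oxyArt <- res$experiments$Exp1$compartmentAverage$artery$hbt
  post <- airArt$timeAxisS > 4 & airArt$timeAxisS < 15
  noiseBand <- 3 * max(oxyArt$sd[post]) / sqrt(oxyArt$nTrials)
  # air: arterial post-stimulus undershoot below baseline
  expect_lt(min(airArt$mean[post]), 1 - noiseBand)
  # oxygen: no undershoot beyond noise
  expect_gt(min(oxyArt$mean[post]), 1 - noiseBand)
  # vein lags artery: compare sharp 2 s response peaks (the 16 s plateau
  # makes argmax noise-dominated)
  art1 <- res$experiments$Exp1$compartmentAverage$artery$hbt
  vein1 <- res$experiments$Exp1$compartmentAverage$vein$hbt
  expect_lt(which.max(art1$mean), which.max(vein1$mean))
})

test_that("single-pixel compartment masks return those pixels' series", {
  z <- matrix(rnorm(48), 12, 4)
  att <- new("AttenuationStack", values = list(z, z, z, z),
             wavelengths = imagingWavelengths(), frameRateHz = 8,
             shape = c(2L, 2L), dead = integer())
  cm <- unmixStack(att, ttTable(), ttPaths(), ttOxygen())
  mk <- function(i) {
    px <- matrix(FALSE, 2, 2); px[i] <- TRUE
    new("RoiMask", pixels = px, kSd = NA_real_, sourceExperiment = "t")
  }
  cs <- compartmentSeries(cm, list(artery = mk(1), vein = mk(4)))
  expect_identical(cs$artery$hbt, fractionalMovie(cm, "hbt")[, 1])
  expect_identical(cs$vein$hbr, fractionalMovie(cm, "hbr")[, 4])
})
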