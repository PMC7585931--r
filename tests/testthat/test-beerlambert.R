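test_that("attenuation identities hold on constructed intensities", {
  nT <- 20; nP <- 9
  i0 <- matrix(500, nT, nP)
  att <- computeAttenuation(list(i0, i0, i0, i0), 1:5,
                            imagingWavelengths(), 8, c(3L, 3L))
  for (v in att@values) expect_true(all(v == 0))

  dipped <- i0
  dipped[10, ] <- 500 * exp(-1)
  att2 <- computeAttenuation(list(dipped, i0, i0, i0), 1:5,
                             imagingWavelengths(), 8, c(3L, 3L))
  expect_equal(att2@values[[1]][10, ], rep(1, nP), tolerance = 1e-12)
  # noise-free baseline-window mean is zero by construction
  expect_lt(max(abs(colMeans(att2@values[[1]][1:5, ]))), 1e-12)
})

test_that("non-positive pixels are flagged dead and excluded", {
  i0 <- matrix(500, 10, 4)
  i0[3, 2] <- 0
  expect_message(
    att <- computeAttenuation(list(i0, i0, i0, i0), 1:3,
                              imagingWavelengths(), 8, c(2L, 2L)),
    "1 dead")
  expect_identical(att@dead, 2L)
  expect_true(all(is.na(att@values[[1]][, 2])))
  expect_false(anyNA(att@values[[1]][, -2]))
})

test_that("unmixing recovers forward-generated concentration changes", {
  tab <- ttTable(); paths <- ttPaths()
  M <- ois2d:::blDesignMatrix(tab, paths)
  expect_equal(unname(unmixPixel(rep(0, 4), tab, paths)), c(0, 0))
  dC <- c(5, -2)
  dA <- as.numeric(M %*% dC)
  expect_equal(unname(unmixPixel(dA, tab, paths)), dC, tolerance = 1e-10)
})

test_that("noisy unmixing equals the explicit normal-equations solution", {
  tab <- ttTable(); paths <- ttPaths()
  M <- ois2d:::blDesignMatrix(tab, paths)
  set.seed(4)
  for (i in 1:20) {
    dA <- as.numeric(M %*% rnorm(2, 0, 3)) + rnorm(4, 0, 0.01)
    ours <- unmixPixel(dA, tab, paths)
    # independent normal-equations formula
    oracle <- solve(t(M) %*% M) %*% t(M) %*% dA
    expect_equal(unname(ours), as.numeric(oracle), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected naming the wavelengths", {
  tab <- ttTable()
  # equal oxy/deoxy spectra make the two design columns exactly collinear
  degen <- new("ExtinctionTable", wavelength = c(450, 650),
               epsHbo = c(1000, 2000), epsHbr = c(1000, 2000),
               logBase = "log10", source = "constructed")
  expect_error(unmixPixel(rep(0.1, 4), degen, ttPaths()), "559")
})

test_that("all-zero stacks give fractional movies of exactly one", {
  z <- matrix(0, 8, 6)
  att <- new("AttenuationStack", values = list(z, z, z, z),
             wavelengths = imagingWavelengths(), frameRateHz = 8,
             shape = c(2L, 3L), dead = integer())
  cm <- unmixStack(att, ttTable(), ttPaths(), ttOxygen())
  expect_true(all(cm@dHbt == 0))
  expect_true(all(fractionalMovie(cm, "hbt") == 1))
  expect_true(all(fractionalMovie(cm, "hbo") == 1))
  expect_true(all(fractionalMovie(cm, "hbr") == 1))
})

test_that("dead pixels propagate through unmixing with their count", {
  i0 <- matrix(400, 12, 9)
  bad <- c(2L, 5L, 8L)
  i0[1, bad] <- -1
  expect_message(
    att <- computeAttenuation(list(i0, i0, i0, i0), 1:4,
                              imagingWavelengths(), 8, c(3L, 3L)),
    "3 dead")
  cm <- unmixStack(att, ttTable(), ttPaths(), ttOxygen())
  expect_identical(cm@dead, bad)
  expect_identical(sum(colSums(is.na(cm@dHbt)) > 0), 3L)
})

test_that("forward model round trip is exact with noise off", {
  ph <- makePhantom(c(32L, 32L), seed = 6)
  rec <- simulateSession(ph, ttShortProtocol(),
                         conditionSpec("wt", "chronic"), ttTable(),
                         ttPaths(), seed = 8, noise = FALSE,
                         experiments = "Exp1")
  ex <- rec@experiments$Exp1
  att <- computeAttenuation(darkCorrect(ex$intensities, ex$dark), 1:40,
                            rec@meta$wavelengths_nm, 8, rec@meta$shape)
  cm <- unmixStack(att, ttTable(), ttPaths(), ttOxygen())
  # conservation is exact element-wise
  expect_true(all(cm@dHbt == cm@dHbo + cm@dHbr))
  # injected artery-compartment evoked series recovered to < 1e-9 uM
  sel <- as.vector(ph@masks$artery & ph@active)
  tr <- rec@truth$Exp1$evoked$artery
  for (sp in c("dHbt", "dHbr")) {
    inj <- tr[[sp]] - mean(tr[[sp]][1:40])
    got <- rowMeans(slot(cm, sub("d", "d", sp))[, sel])
    expect_lt(max(abs(got - inj)), 1e-9)
  }
})

test_that("air baseline estimation recovers a flat or shifted record", {
  z <- matrix(0, 800, 4)
  att <- new("AttenuationStack", values = list(z, z, z, z),
             wavelengths = imagingWavelengths(), frameRateHz = 8,
             shape = c(2L, 2L), dead = integer())
  cm <- unmixStack(att, ttTable(), ttPaths(), ttOxygen())
  flat <- estimateAirBaseline(cm, ttOxygen(), c(60, 90))
  expect_equal(hbtConc(flat), 100, tolerance = 1e-9)
  expect_equal(flat@so2, 0.70, tolerance = 1e-12)
  expect_identical(flat@condition, "air")
  expect_error(estimateAirBaseline(cm, ttOxygen(), c(60, 60)),
               "positive length")
  expect_error(estimateAirBaseline(cm, ttOxygen(), c(90, 200)),
               "beyond")
})
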