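# Shared fixtures, built lazily and memoised for the whole run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

ttTable <- function() memo("table", function() loadExtinctionTable())

ttOxygen <- function() baselineState(100, 0.70, "oxygen")

# modest photon count: forward/inverse consistency only needs the same
# table on both sides
ttPaths <- function() memo("paths", function()
  pathlengthTable(ttOxygen(), table = ttTable(), nPhotons = 5000,
                  seed = 11))

ttShortProtocol <- function()
  shortProtocol(nShort = 3, nLong = 2, gasLengthS = 240,
                hypercapniaLengthS = 300)

# one analysed chronic session shared by the pipeline / compartment tests
ttChronicRun <- function() memo("chronicRun", function() {
  ph <- makePhantom(c(48L, 48L), seed = 2)
  rec <- simulateSession(ph, ttShortProtocol(), conditionSpec("wt", "chronic"),
                         ttTable(), ttPaths(), seed = 31)
  res <- suppressMessages(runSession(rec, ttTable(), ttPaths()))
  list(phantom = ph, recording = rec, result = res)
})

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# peak fractional ROI Hbt response of a recording analysed under an
# assumed baseline (path lengths recomputed for that baseline)
peakFractionalHbt <- function(rec, assumed, paths, table) {
  ex <- rec@experiments[[1]]
  row <- rec@protocol[rec@protocol$id == names(rec@experiments)[1], ]
  corr <- darkCorrect(ex$intensities, ex$dark)
  att <- computeAttenuation(corr,
                            seq_len(round(row$stim_onset_s * 8)),
                            rec@meta$wavelengths_nm, 8, rec@meta$shape)
  cm <- unmixStack(att, table, paths, assumed)
  frac <- fractionalMovie(cm, "hbt")
  active <- rec@meta$phantom@active
  s <- roiTimeseries(frac, as.vector(active))
  avg <- trialAverage(epochTrials(s, ex$events, row$stim_onset_s,
                                  row$trial_length_s - row$stim_onset_s, 8))
  max(avg$mean) - 1
}
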