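# Generator tests run at reduced sampling rates / trial counts; the full
# study conditions are exercised in the acceptance tests.

quietNoise <- function() noiseConfig(backgroundSd = 0, lineAmplitudeUv = 0,
                                     driftAmplitudeUv = 0, artifactRate = 0)

test_that("all-zero noise with no drive gives an all-zero recording", {
  syn <- synthesizeRecording(NULL, probeGeometry(nChannels = 4),
                             quietNoise(), nTrials = 2, trialLength = 0.5,
                             samplingRate = 2000, seed = 1,
                             hashRate = 0)
  expect_true(all(voltages(syn$recording) == 0))
  expect_equal(syn$truth@driveLabel, "NONE")
})

test_that("full recruitment at one unit per channel yields one spike per pulse", {
  syn <- synthesizeRecording(makeTonic(50, 2), probeGeometry(nChannels = 6),
                             nTrials = 3, samplingRate = 5000, seed = 2,
                             pRecruit = 1, latencyJitterMs = 0,
                             unitsPerChannel = 1)
  counts <- lengths(spikeTimes(syn$truth))
  expect_true(all(counts == 100 * 3))
  # truth spikes lie within the recording span and are sorted
  for (st in spikeTimes(syn$truth)) {
    expect_false(is.unsorted(st))
    expect_true(all(st >= 0 & st <= duration(syn$recording)))
  }
})

test_that("electrical drives synchronize channels, natural drives do not", {
  geom <- probeGeometry(nChannels = 8)
  ton <- synthesizeRecording(makeTonic(10, 2), geom, nTrials = 2,
                             samplingRate = 5000, seed = 3,
                             unitsPerChannel = 1)
  flat <- rateProfileOf(rep(10, 200))   # matched 10 Hz mean rate
  nat <- synthesizeRecording(flat, geom, nTrials = 2, trialLength = 2,
                             samplingRate = 5000, seed = 3)
  sTon <- crossChannelSynchrony(spikeTimes(ton$truth))
  sNat <- crossChannelSynchrony(spikeTimes(nat$truth))
  expect_gt(sTon, 5 * sNat)
  expect_equal(nat$truth@driveLabel, "NATURAL")
})

test_that("line-noise harmonics appear as periodogram peaks", {
  cfg <- noiseConfig(backgroundSd = 1, lineAmplitudeUv = c(20, 10),
                     driftAmplitudeUv = 0, artifactRate = 0)
  syn <- synthesizeRecording(NULL, probeGeometry(nChannels = 2), cfg,
                             nTrials = 1, trialLength = 4,
                             samplingRate = 2000, seed = 4, hashRate = 0)
  x <- voltages(syn$recording)[1, ]
  sp <- spec.pgram(ts(x, frequency = 2000), plot = FALSE, taper = 0)
  for (f0 in c(50, 100)) {
    peak <- sp$freq[which.max(sp$spec * (abs(sp$freq - f0) < 5))]
    expect_lt(abs(peak - f0), 0.5)
  }
})

test_that("embedded artifacts are recorded in truth and trigger blanking", {
  syn <- synthesizeRecording(NULL, probeGeometry(nChannels = 3),
                             noiseConfig(backgroundSd = 5,
                                         lineAmplitudeUv = 0,
                                         driftAmplitudeUv = 0,
                                         artifactRate = 0),
                             nTrials = 1, trialLength = 3,
                             samplingRate = 2000, seed = 5, hashRate = 0)
  before <- voltages(syn$recording)
  out <- embedArtifacts(syn$recording, syn$truth, times = 1,
                        amplitudeSdMultiple = 20, widthMs = 4)
  v <- voltages(out$recording)
  fs <- 2000
  sig <- median(abs(before[1, ])) / 0.6745
  near <- round(1 * fs) + seq(-10, 10)
  expect_gte(max(abs(v[1, near])), 15 * sig)
  expect_equal(nrow(out$truth@artifactWindows), 1)
  expect_equal(out$truth@artifactWindows[1, ], c(1 - 0.012, 1 + 0.012),
               ignore_attr = TRUE)

  # no artifacts: recording unchanged
  same <- embedArtifacts(syn$recording, syn$truth, numeric(0))
  expect_identical(voltages(same$recording), before)

  expect_error(embedArtifacts(syn$recording, syn$truth, times = 99),
               "out of range")
})

test_that("touch drive spans its duration and scales linearly", {
  d <- makeTouchDrive(0.8, seed = 1)
  expect_equal(duration(d), 0.8)
  expect_equal(length(rateValues(d)), 800)
  d2 <- makeTouchDrive(0.8, peakRate = 300, seed = 1)
  expect_equal(sum(rateValues(d2)), 2 * sum(rateValues(d)), tolerance = 1e-9)
  expect_identical(rateValues(makeTouchDrive(0.8, seed = 3)),
                   rateValues(makeTouchDrive(0.8, seed = 3)))
  # the response carries a sharp onset transient (peak early, not at the end)
  expect_lt(which.max(rateValues(d)), 100)
})

test_that("seeded synthesis is reproducible end to end", {
  a <- synthesizeRecording(makeTonic(50, 1), probeGeometry(nChannels = 3),
                           nTrials = 1, samplingRate = 2000, seed = 7)
  b <- synthesizeRecording(makeTonic(50, 1), probeGeometry(nChannels = 3),
                           nTrials = 1, samplingRate = 2000, seed = 7)
  expect_identical(voltages(a$recording), voltages(b$recording))
  expect_identical(spikeTimes(a$truth), spikeTimes(b$truth))
  expect_error(synthesizeRecording("nope", probeGeometry(nChannels = 3)),
               "unknown drive type")
})
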