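test_that("profile smoothing preserves constants, mass and impulse shape", {
  const <- rateProfileOf(rep(7, 50))
  sm <- smoothProfile(const, "gaussian", 0.03)
  expect_lt(max(abs(rateValues(sm) - 7)), 1e-9)

  # single-bin impulse spreads exactly like the discrete gaussian kernel
  imp <- rateProfileOf(c(rep(0, 25), 10, rep(0, 24)))
  width <- 0.03
  sm <- smoothProfile(imp, "gaussian", width)
  half <- ceiling(3 * width / 0.01)
  k <- exp(-((-half:half) * 0.01)^2 / (2 * width^2))
  k <- k / sum(k)
  expected <- rep(0, 50)
  expected[26 + (-half:half)] <- 10 * k  # direct convolution oracle
  expect_lt(max(abs(rateValues(sm) - expected)), 1e-9)

  # interior mass conservation within 1%
  set.seed(11)
  rnd <- rateProfileOf(runif(200, 0, 20))
  sm <- smoothProfile(rnd, "moving_average", 0.05)
  inner <- 20:180
  expect_lt(abs(sum(rateValues(sm)[inner]) - sum(rateValues(rnd)[inner])) /
              sum(rateValues(rnd)[inner]), 0.01)

  expect_error(smoothProfile(const, "gaussian", 0.001), "smaller than one bin")
})

test_that("rate-to-frequency map is affine on [fMin, fMax]", {
  prof <- rateProfileOf(c(0, 25, 50, 100))
  fp <- profileToFrequency(prof, fMin = 0, fMax = 80)
  expect_equal(freqValues(fp), c(0, 20, 40, 80))
  expect_equal(max(freqValues(fp)), 80)    # max bin hits fMax exactly
  expect_equal(freqValues(fp)[3], 40)      # half-max bin -> fMax/2

  const <- rateProfileOf(rep(30, 10))
  expect_equal(freqValues(profileToFrequency(const, 0, 60)), rep(60, 10))

  fp2 <- profileToFrequency(prof, fMin = 10, fMax = 90)
  expect_equal(freqValues(fp2)[1], 10)     # zero rate -> fMin

  expect_error(profileToFrequency(rateProfileOf(rep(0, 5))), "all-zero")
  expect_error(profileToFrequency(prof, 50, 50), "fMax > fMin")
})

test_that("time-rescaled pulse placement reduces to tonic and obeys the
           integral count", {
  fp <- constantFrequencyProfile(50, 2)
  train <- frequencyToPulseTimes(fp, 2)
  tonic <- makeTonic(50, 2)
  expect_equal(length(onsets(train)), 100)
  expect_lt(max(abs(onsets(train) - onsets(tonic))), 1e-9)

  # all pulses inside the active first second
  f <- c(rep(100, 100), rep(0, 100))
  fp2 <- new("FrequencyProfile", timeStep = 0.01, freq = f, fMin = 0,
             fMax = 100)
  t2 <- frequencyToPulseTimes(fp2, 2)
  expect_equal(length(onsets(t2)), 100)
  expect_lt(max(onsets(t2)), 1)

  # pulse count equals ceiling of the quadrature integral for random profiles
  for (s in 1:5) {
    set.seed(s)
    f <- runif(150, 0, 90)
    fpR <- new("FrequencyProfile", timeStep = 0.01, freq = f, fMin = 0,
               fMax = 90)
    tr <- frequencyToPulseTimes(fpR, 1.5)
    expect_equal(length(onsets(tr)), ceiling(sum(f) * 0.01))
  }
})

test_that("tonic trains are regular from t = 0", {
  expect_equal(length(onsets(makeTonic(50, 2))), 100)
  expect_equal(onsets(makeTonic(1, 2)), c(0, 1))
  expect_equal(diff(onsets(makeTonic(50, 2))), rep(0.02, 99))
  expect_identical(makeTonic(50, 2)@encoding, "TONIC")
})

test_that("poisson trains have exponential intervals at the right rate", {
  counts <- vapply(1:300, function(s)
    length(onsets(makePoisson(50, 2, seed = s))), numeric(1))
  se <- sd(counts) / sqrt(300)
  expect_lt(abs(mean(counts) - 100), 3 * se)

  tr <- makePoisson(50, 2, seed = 42)
  iv <- diff(onsets(tr))
  ks <- suppressWarnings(ks.test(iv, "pexp", 1 / mean(iv)))
  expect_lt(unname(ks$statistic), 1.358 / sqrt(length(iv)))

  expect_identical(onsets(makePoisson(50, 2, seed = 9)),
                   onsets(makePoisson(50, 2, seed = 9)))
})

test_that("linear encoder maps pressure to charge affinely", {
  p1 <- rep(1, 2000)
  tr <- makeLinear(p1, 0.001, qMinNc = 10, qMaxNc = 60)
  expect_true(all(abs(chargePerPulse(tr) - 60) < 1e-9))

  pHalf <- rep(0.5, 2000)
  tr2 <- makeLinear(pHalf, 0.001, 10, 60)
  expect_true(all(abs(chargePerPulse(tr2) - 35) < 1e-9))

  # trapezoidal indentation: 0.5 s rise, 1 s hold, 0.5 s release
  t <- seq(0, 2, by = 0.001)[-1]
  press <- pmin(pmin(t / 0.5, 1), pmax((2 - t) / 0.5, 0))
  tr3 <- makeLinear(press, 0.001, 10, 60)
  q <- chargePerPulse(tr3)
  hold <- onsets(tr3) > 0.55 & onsets(tr3) < 1.45
  expect_true(all(abs(q[hold] - 60) < 1e-6))
  expect_gt(cor(q, press[pmin(floor(onsets(tr3) / 0.001) + 1, 2000)]), 0.999)

  expect_error(makeLinear(c(0.2, 1.3), 0.001, 10, 60), "\\[0, 1\\]")

  # zero-pressure epochs are silent
  pz <- c(rep(0, 1000), rep(1, 1000))
  tr4 <- makeLinear(pz, 0.001, 10, 60)
  expect_true(all(onsets(tr4) >= 1))
})

test_that("discrete encoder emits merged 0.5 s bursts per contact event", {
  one <- makeDiscrete(data.frame(time = 1, type = "press"), duration = 3)
  expect_equal(length(onsets(one)), 25)
  expect_true(all(onsets(one) >= 1 & onsets(one) < 1.5))

  two <- makeDiscrete(data.frame(time = c(1, 3),
                                 type = c("press", "release")), duration = 4)
  expect_equal(length(onsets(two)), 50)
  expect_true(!any(onsets(two) > 1.5 & onsets(two) < 3))

  merged <- makeDiscrete(data.frame(time = c(1, 1.2),
                                    type = c("press", "release")),
                         duration = 2)
  expect_equal(length(onsets(merged)), 35)        # one burst [1, 1.7)
  expect_equal(anyDuplicated(onsets(merged)), 0L)

  expect_error(makeDiscrete(data.frame(time = c(2, 1),
                                       type = c("press", "press"))),
               "sorted")
})

test_that("sinusoidal pulse-width modulation hits its bounds on schedule", {
  degen <- makeSinusoidalPw(50, 2, pwMinUs = 300, pwMaxUs = 300)
  expect_true(all(degen@pulseWidthUs == 300))

  # 100 Hz pulses put the quarter-period instants exactly on the pulse grid
  tr <- makeSinusoidalPw(100, 2, pwMinUs = 100, pwMaxUs = 500,
                         modulationFreq = 1)
  pw <- tr@pulseWidthUs
  t <- onsets(tr)
  expect_equal(pw[which(t == 0.25)], 500, tolerance = 1e-6)
  expect_equal(pw[which(t == 0.5)], 300, tolerance = 1e-6)
  expect_equal(pw[which(t == 0.75)], 100, tolerance = 1e-6)
  expect_true(all(pw >= 100 - 1e-9 & pw <= 500 + 1e-9))

  expect_error(makeSinusoidalPw(50, 2, modulationFreq = 0), "positive")
})

test_that("charge validation flags pulses beyond the safety limit", {
  ok <- makeTonic(50, 2, amplitudeUa = 60, pulseWidthUs = 500)
  rep1 <- validateCharge(ok)
  expect_true(rep1@pass)
  expect_equal(unique(chargePerPulse(ok)), 30)

  hot <- makeTonic(50, 2, amplitudeUa = 300, pulseWidthUs = 500)
  rep2 <- validateCharge(hot)
  expect_false(rep2@pass)
  expect_equal(unique(chargePerPulse(hot)), 150)
  expect_equal(rep2@violations, seq_along(onsets(hot)))

  empty <- new("StimTrain", onsets = numeric(0), amplitudeUa = numeric(0),
               pulseWidthUs = numeric(0), encoding = "TONIC", duration = 1)
  expect_true(validateCharge(empty)@pass)
})

test_that("every encoder satisfies the train invariants", {
  press <- rep(0.7, 2000)
  trains <- list(
    makeTonic(50, 2),
    makePoisson(50, 2, seed = 3),
    makeLinear(press, 0.001, 10, 60),
    makeDiscrete(data.frame(time = c(0.2, 1.1), type = c("press", "release")),
                 duration = 2),
    makeSinusoidalPw(50, 2, pwMinUs = 100, pwMaxUs = 500),
    designBiomimeticTrain(nUnits = 40, seed = 2)$train)
  for (tr in trains) {
    expect_false(is.unsorted(onsets(tr)))
    expect_equal(chargePerPulse(tr),
                 tr@amplitudeUa * tr@pulseWidthUs / 1000)
    if (length(onsets(tr)) > 1)
      expect_true(all(diff(onsets(tr)) >
                        2 * tr@pulseWidthUs[-length(onsets(tr))] * 1e-6))
  }
})

test_that("biomimetic pulse rate tracks the smoothed PSTH", {
  d <- designBiomimeticTrain(nUnits = 120, seed = 4, fMin = 0, fMax = 100)
  tr <- d$train
  on <- onsets(tr)
  inst <- 1 / diff(on)                      # instantaneous pulse rate
  mid <- (on[-1] + on[-length(on)]) / 2
  edges <- binEdges(d$psth)
  idx <- findInterval(mid, edges, rightmost.closed = TRUE)
  target <- freqValues(d$freqProfile)
  binRate <- tapply(inst, idx, mean)
  bins <- as.integer(names(binRate))
  keep <- target[bins] > 0
  expect_gt(cor(binRate[keep], target[bins][keep]), 0.95)
})
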