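test_that("population construction honours composition, counts and seed", {
  pop <- buildPopulation("FA1", 50, seed = 1)
  expect_equal(nrow(pop@units), 50)
  expect_true(all(pop@units$class == "FA1"))

  full <- buildPopulation("FULL", 100,
                          c(SA1 = .3, SA2 = .15, FA1 = .4, FA2 = .15),
                          seed = 2)
  counts <- table(full@units$class)
  expect_equal(unname(counts[c("SA1", "SA2", "FA1", "FA2")]),
               c(30, 15, 40, 15), ignore_attr = TRUE)

  again <- buildPopulation("FULL", 100,
                           c(SA1 = .3, SA2 = .15, FA1 = .4, FA2 = .15),
                           seed = 2)
  expect_identical(full@units, again@units)

  expect_error(buildPopulation("SA9", 10), "unknown composition")
  expect_error(buildPopulation("FULL", 10,
                               c(SA1 = .3, SA2 = .3, FA1 = .3, FA2 = .2)),
               "sum to 1")
})

test_that("largest-remainder apportionment is exact for awkward fractions", {
  # brute-force enumeration oracle: counts must sum to n and each count is
  # floor or ceiling of its exact share
  fr <- c(SA1 = 1 / 3, SA2 = 1 / 3, FA1 = 1 / 6, FA2 = 1 / 6)
  for (n in c(7, 10, 99)) {
    pop <- buildPopulation("FULL", n, fr, seed = 3)
    counts <- as.vector(table(factor(pop@units$class,
                                     levels = c("SA1", "SA2", "FA1", "FA2"))))
    expect_equal(sum(counts), n)
    expect_true(all(counts >= floor(n * fr) & counts <= ceiling(n * fr)))
  }
})

test_that("ramp-and-hold stimulus tiles duty cycles with bounded noise", {
  clean <- makeRampAndHold(duration = 2, amplitude = 3, noiseFraction = 0,
                           timeStep = 0.001)
  expect_equal(max(clean@samples), 3)
  expect_equal(length(clean@samples), 2000)
  expect_equal(duration(clean), 2)
  # floor(2 / 0.45) = 4 complete cycles plus a partial one: exactly four
  # full-length off phases (0.3 s each) before the truncated final cycle
  runs <- rle(clean@samples == 0)
  fullOff <- sum(runs$values & runs$lengths >= 250)
  expect_equal(fullOff, 4)

  noisy <- makeRampAndHold(duration = 2, amplitude = 3,
                           noiseFraction = 0.005, timeStep = 0.001, seed = 4)
  expect_true(all(abs(noisy@samples - clean@samples) <= 0.005 * 3 + 1e-12 |
                    clean@samples == 0))       # clipping at zero
  expect_true(all(noisy@samples >= 0))
  expect_lte(max(noisy@samples), 3 * 1.005)

  expect_error(makeRampAndHold(duration = 0.3), "exceed one on/off cycle")
  expect_error(makeRampAndHold(timeStep = -1), "positive")
})

test_that("rate models separate sustained SA from transient FA dynamics", {
  stim <- makeRampAndHold(duration = 2, noiseFraction = 0, timeStep = 0.001)
  dt <- stim@timeStep
  t <- (seq_along(stim@samples) - 1) * dt
  sa <- afferentRates(fixedUnitPopulation("SA1"), stim)[1, ]
  fa <- afferentRates(fixedUnitPopulation("FA1"), stim)[1, ]

  # hold phase of the first cycle (plateau): 0.03-0.12 s
  hold <- t > 0.04 & t < 0.11
  expect_gt(mean(sa[hold]), 5 * mean(fa[hold]))
  expect_gt(mean(sa[hold]), 20)

  # FA1 responds only near the ramps: its rate outside +/- 20 ms of the
  # transients is tiny, and its transient rate dwarfs its hold rate
  transients <- c(0, 0.03, 0.12, 0.15)
  nearRamp <- Reduce(`|`, lapply(transients, function(tr)
    abs(t %% 0.45 - tr) <= 0.02))
  expect_gt(max(fa[nearRamp & t < 0.45]), 5 * max(1e-9, mean(fa[hold])))

  # SA adaptation: second-cycle hold rate below first-cycle hold rate
  hold2 <- t > 0.49 & t < 0.56
  expect_lt(mean(sa[hold2]), mean(sa[hold]))
})

test_that("expected spike count matches the rate-integral oracle", {
  stim <- makeRampAndHold(duration = 2, noiseFraction = 0, timeStep = 0.001)
  pop <- fixedUnitPopulation("SA1", gainStatic = 25, gainDynamic = 0)
  rates <- afferentRates(pop, stim)
  # direct numerical integration of the clipped rate, with the standard
  # dead-time correction r / (1 + r * tau) for the 1 ms refractory period
  r <- rates[1, ]
  oracle <- sum(r / (1 + r * 0.001)) * stim@timeStep
  nRep <- 200
  counts <- vapply(seq_len(nRep), function(s)
    length(simulateResponses(pop, stim, seed = s)@spikes[[1]]), numeric(1))
  se <- sd(counts) / sqrt(nRep)
  expect_lt(abs(mean(counts) - oracle), 3 * se + 0.01 * oracle)
})

test_that("no inter-spike interval ever violates the refractory period", {
  stim <- makeRampAndHold(duration = 2, noiseFraction = 0, timeStep = 0.001)
  pop <- buildPopulation("FULL", 40, seed = 5)
  for (s in 1:5) {
    resp <- simulateResponses(pop, stim, seed = s)
    isis <- unlist(lapply(resp@spikes, diff), use.names = FALSE)
    if (length(isis)) expect_gte(min(isis), 0.001)
  }
})

test_that("zero pressure yields spontaneous firing; amplitude is monotone", {
  flat <- new("PressureStimulus", samples = rep(0, 1000), timeStep = 0.001,
              amplitude = 0, noiseFraction = 0)
  pop <- fixedUnitPopulation("SA2", gainStatic = 20, spontaneous = 10)
  counts <- vapply(1:100, function(s)
    length(simulateResponses(pop, flat, seed = s)@spikes[[1]]), numeric(1))
  expected <- 10 * 1.0
  se <- sd(counts) / sqrt(100)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # doubling the amplitude cannot reduce the expected count (rate-integral
  # oracle on the monotone rate model)
  s1 <- makeRampAndHold(duration = 2, amplitude = 1, noiseFraction = 0)
  s2 <- makeRampAndHold(duration = 2, amplitude = 2, noiseFraction = 0)
  popFull <- buildPopulation("FULL", 20, seed = 6)
  i1 <- rowSums(afferentRates(popFull, s1)) * s1@timeStep
  i2 <- rowSums(afferentRates(popFull, s2)) * s2@timeStep
  expect_true(all(i2 >= i1 - 1e-9))

  expect_error(simulateResponses(
    new("AfferentPopulation",
        units = fixedUnitPopulation("SA1")@units[0, ],
        composition = "SA1", seed = 0L), flat), "empty population")
})

test_that("population PSTH pools unit spikes onto the requested grid", {
  stim <- makeRampAndHold(duration = 2, noiseFraction = 0)
  pop <- buildPopulation("FULL", 30, seed = 7)
  resp <- simulateResponses(pop, stim, seed = 7)
  psth <- populationPsth(resp, 0.01)
  expect_equal(length(rateValues(psth)), 200)
  totalSpikes <- sum(lengths(resp@spikes))
  expect_equal(sum(rateValues(psth)) * 0.01 * 30, totalSpikes)
})
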