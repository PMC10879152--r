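#' Default rate-model parameter distributions per afferent class
#'
#' Each afferent class is described by a small parametric rate model (see
#' \code{\link{afferentRates}}): a static gain on the pressure, a dynamic
#' gain on the pressure velocity, an acceleration gain, an adaptation time
#' constant, a saturation rate and a spontaneous rate.  Unit parameters are
#' drawn log-normally around the class means with the given coefficient of
#' variation, reflecting the natural response variability across afferents
#' of one class.
#'
#' The means are chosen so that, for a unit-amplitude ramp-and-hold
#' indentation, SA units fire tens of spikes/s through the hold phase while
#' FA units respond with brief transients of hundreds of spikes/s at the
#' ramps, the class-typical dynamics of cutaneous mechanoreceptors.
#'
#' @return a named list (one entry per class) of parameter means plus the
#'   log-normal coefficient of variation \code{cv}.
#' @export
afferentClassDefaults <- function() {
  list(
    SA1 = list(gainStatic = 60, gainDynamic = 4, gainAccel = 0,
               tauAdapt = 0.6, saturation = 250, spontaneous = 0.5, cv = 0.25),
    SA2 = list(gainStatic = 25, gainDynamic = 0, gainAccel = 0,
               tauAdapt = 2.0, saturation = 150, spontaneous = 4, cv = 0.25),
    FA1 = list(gainStatic = 0, gainDynamic = 8, gainAccel = 0,
               tauAdapt = 0.2, saturation = 300, spontaneous = 0.1, cv = 0.25),
    FA2 = list(gainStatic = 0, gainDynamic = 0, gainAccel = 0.12,
               tauAdapt = 0.05, saturation = 400, spontaneous = 0.1, cv = 0.25)
  )
}

# Foot-sole afferent composition: FA1-dominated, per microneurographic surveys
# of the human foot sole.
DEFAULT_CLASS_FRACTIONS <- c(SA1 = 0.15, SA2 = 0.15, FA1 = 0.60, FA2 = 0.10)

#' Build a foot-sole afferent population
#'
#' Populates a rectangular foot-sole outline either with a single afferent
#' class or with the full mixed population.  For \code{composition = "FULL"}
#' the requested total is split between classes by largest-remainder
#' apportionment of \code{classFractions}, so e.g. 100 units at fractions
#' (.3, .15, .4, .15) give exactly (30, 15, 40, 15) units.
#'
#' @param composition "SA1", "SA2", "FA1", "FA2" or "FULL".
#' @param nUnits number of units (total for FULL, per the single class
#'   otherwise).
#' @param classFractions named fractions per class for FULL populations;
#'   must sum to 1 (tolerance 1e-9).
#' @param soleSize width and length of the sole outline in mm.
#' @param seed integer seed; the same call with the same seed reproduces the
#'   population exactly.
#' @param classDefaults parameter distributions, see
#'   \code{\link{afferentClassDefaults}}.
#' @return an \linkS4class{AfferentPopulation}.
#' @examples
#' pop <- buildPopulation("FULL", 100, seed = 2)
#' table(pop@units$class)
#' @export
buildPopulation <- function(composition, nUnits,
                            classFractions = DEFAULT_CLASS_FRACTIONS,
                            soleSize = c(100, 260), seed = 1,
                            classDefaults = afferentClassDefaults()) {
  if (!composition %in% c(AFFERENT_CLASSES, "FULL"))
    stop("unknown composition label: ", composition)
  stopifnot(nUnits >= 1)
  if (composition == "FULL") {
    if (!all(AFFERENT_CLASSES %in% names(classFractions)))
      stop("classFractions must name all four classes")
    classFractions <- classFractions[AFFERENT_CLASSES]
    if (abs(sum(classFractions) - 1) > 1e-9)
      stop("classFractions must sum to 1")
    counts <- apportion(nUnits, classFractions)
    classes <- rep(AFFERENT_CLASSES, counts)
  } else {
    classes <- rep(composition, nUnits)
  }
  units <- withSeed(seed, {
    n <- length(classes)
    x <- runif(n, 0, soleSize[1])
    y <- runif(n, 0, soleSize[2])
    draw <- function(cls, field) {
      p <- classDefaults[[cls]]
      mu <- p[[field]]
      if (mu == 0) return(rep(0, sum(classes == cls)))
      sdlog <- sqrt(log(1 + p$cv^2))
      exp(rnorm(sum(classes == cls), log(mu) - sdlog^2 / 2, sdlog))
    }
    cols <- c("gainStatic", "gainDynamic", "gainAccel", "tauAdapt",
              "saturation", "spontaneous")
    out <- data.frame(class = classes, x = x, y = y)
    for (col in cols) {
      v <- numeric(n)
      for (cls in unique(classes)) v[classes == cls] <- draw(cls, col)
      out[[col]] <- v
    }
    out
  })
  new("AfferentPopulation", units = units, composition = composition,
      seed = as.integer(seed))
}

#' Repeating ramp-and-hold pressure stimulus with environmental noise
#'
#' Tiles duty cycles of \code{onPhase} seconds of indentation followed by
#' \code{offPhase} seconds off across the stimulus duration.  Within the on
#' phase the pressure rises linearly for \code{riseFraction * onPhase}
#' seconds, holds at \code{amplitude}, and falls symmetrically.  Additive
#' uniform environmental noise is bounded by
#' \code{noiseFraction * amplitude} and the result is clipped at zero.
#'
#' @param duration total stimulus duration (s); must exceed one duty cycle.
#' @param onPhase,offPhase indentation on/off durations (s).
#' @param amplitude peak pressure (arbitrary units).
#' @param noiseFraction noise bound as a fraction of \code{amplitude}.
#' @param timeStep sample interval (s).
#' @param riseFraction fraction of the on phase spent on each ramp.
#' @param seed seed for the noise draw.
#' @return a \linkS4class{PressureStimulus}.
#' @export
makeRampAndHold <- function(duration = 2, onPhase = 0.15, offPhase = 0.3,
                            amplitude = 1, noiseFraction = 0.005,
                            timeStep = 0.001, riseFraction = 0.2, seed = 1) {
  if (duration <= 0 || timeStep <= 0)
    stop("duration and timeStep must be positive")
  if (duration <= onPhase + offPhase)
    stop("duration must exceed one on/off cycle")
  if (noiseFraction < 0 || noiseFraction > 1)
    stop("noiseFraction must lie in [0, 1]")
  n <- round(duration / timeStep)
  t <- (seq_len(n) - 1) * timeStep
  cycle <- onPhase + offPhase
  tc <- t %% cycle
  rise <- riseFraction * onPhase
  base <- ifelse(tc < rise, tc / rise,
          ifelse(tc < onPhase - rise, 1,
          ifelse(tc < onPhase, (onPhase - tc) / rise, 0))) * amplitude
  samples <- if (noiseFraction > 0) {
    noise <- withSeed(seed, runif(n, -1, 1)) * noiseFraction * amplitude
    pmax(base + noise, 0)
  } else base
  new("PressureStimulus", samples = as.numeric(samples), timeStep = timeStep,
      amplitude = amplitude, noiseFraction = noiseFraction)
}

#' Instantaneous firing rates of a population under a pressure stimulus
#'
#' Evaluates the class rate models on the stimulus grid.  Writing s(t) for
#' the pressure (used directly as the skin stress):
#' \itemize{
#' \item SA1: \code{gainStatic * s * A(t) + gainDynamic * max(ds/dt, 0)},
#'   where the adaptation state A(t) relaxes towards a floor of 0.2 with
#'   time constant \code{tauAdapt} while the skin is indented and recovers
#'   towards 1 (time constant \code{4 * tauAdapt}) while it is not;
#' \item SA2: \code{gainStatic * s * A(t)} only (slow adaptation, sustained);
#' \item FA1: \code{gainDynamic * |ds/dt|} smoothed over 20 ms;
#' \item FA2: \code{gainAccel * |d2s/dt2|} smoothed over 5 ms.
#' }
#' Each rate gets the unit's spontaneous rate added and is clipped to
#' \code{[0, saturation]}.
#'
#' @param population an \linkS4class{AfferentPopulation}.
#' @param stimulus a \linkS4class{PressureStimulus}.
#' @return units x time matrix of rates in spikes/s.
#' @export
afferentRates <- function(population, stimulus) {
  u <- population@units
  if (nrow(u) == 0L) stop("empty population")
  s <- stimulus@samples
  dt <- stimulus@timeStep
  n <- length(s)
  ds <- numDeriv1(s, dt)
  d2s <- numDeriv2(s, dt)
  dsPos <- pmax(ds, 0)
  absDs20 <- movingAverage(abs(ds), round(0.020 / dt))
  absD2s5 <- movingAverage(abs(d2s), round(0.005 / dt))
  on <- s > 0.05 * stimulus@amplitude

  # Adaptation trace for a given time constant: first-order relaxation to 0.2
  # during indentation, recovery to 1 otherwise.  Shared across units of equal
  # tau via memoisation.
  adaptCache <- new.env(parent = emptyenv())
  adaptTrace <- function(tau) {
    key <- sprintf("%.6g", tau)
    if (!is.null(adaptCache[[key]])) return(adaptCache[[key]])
    a <- numeric(n)
    state <- 1
    kOn <- dt / tau
    kOff <- dt / (4 * tau)
    for (i in seq_len(n)) {
      state <- if (on[i]) state + (0.2 - state) * kOn
               else state + (1 - state) * kOff
      a[i] <- state
    }
    adaptCache[[key]] <- a
    a
  }

  rates <- matrix(0, nrow(u), n)
  for (i in seq_len(nrow(u))) {
    r <- switch(u$class[i],
      SA1 = u$gainStatic[i] * s * adaptTrace(u$tauAdapt[i]) +
            u$gainDynamic[i] * dsPos,
      SA2 = u$gainStatic[i] * s * adaptTrace(u$tauAdapt[i]),
      FA1 = u$gainDynamic[i] * absDs20,
      FA2 = u$gainAccel[i] * absD2s5)
    rates[i, ] <- pmin(pmax(r + u$spontaneous[i], 0), u$saturation[i])
  }
  rates
}

#' Simulate spiking responses of an afferent population
#'
#' Draws spikes for every unit as an inhomogeneous Poisson process (thinning
#' of a homogeneous process at the unit's peak rate) with an absolute
#' refractory period.
#'
#' @param population an \linkS4class{AfferentPopulation}.
#' @param stimulus a \linkS4class{PressureStimulus}.
#' @param seed integer seed; identical seeds give identical spike trains.
#' @param refractory absolute refractory period (s), default 1 ms.
#' @param trial trial index recorded in the result.
#' @return a \linkS4class{SpikeTrainSet}.
#' @export
simulateResponses <- function(population, stimulus, seed = 1,
                              refractory = 0.001, trial = 1L) {
  if (nrow(population@units) == 0L) stop("empty population")
  if (duration(stimulus) <= 0) stop("stimulus duration must be positive")
  rates <- afferentRates(population, stimulus)
  dur <- duration(stimulus)
  dt <- stimulus@timeStep
  spikes <- withSeed(seed, {
    lapply(seq_len(nrow(rates)), function(i) {
      thinPoisson(rates[i, ], dt, dur, refractory)
    })
  })
  new("SpikeTrainSet", spikes = spikes,
      unitClass = as.character(population@units$class),
      duration = dur, trial = as.integer(trial))
}

# Inhomogeneous Poisson spike times by thinning, with an absolute refractory
# period applied sequentially (candidates within `refractory` of the last
# accepted spike are discarded).
thinPoisson <- function(rate, dt, dur, refractory) {
  rmax <- max(rate)
  if (rmax <= 0) return(numeric(0))
  nCand <- rpois(1, rmax * dur)
  if (nCand == 0) return(numeric(0))
  cand <- sort(runif(nCand, 0, dur))
  idx <- pmin(floor(cand / dt) + 1L, length(rate))
  keep <- runif(nCand) < rate[idx] / rmax
  cand <- cand[keep]
  if (length(cand) < 2) return(cand)
  out <- numeric(length(cand))
  k <- 1L
  out[1L] <- cand[1L]
  last <- cand[1L]
  for (tm in cand[-1L]) {
    if (tm - last >= refractory) {
      k <- k + 1L
      out[k] <- tm
      last <- tm
    }
  }
  out[seq_len(k)]
}

#' Aggregate a population response into a PSTH
#'
#' Pools the spikes of all units in a \linkS4class{SpikeTrainSet} onto a
#' fixed bin grid; the rate is the mean single-afferent rate (count divided
#' by number of units times bin width), mirroring how population activity is
#' aggregated into a peristimulus time histogram before encoding it as a
#' stimulation frequency profile.
#'
#' @param spikeSet a \linkS4class{SpikeTrainSet}.
#' @param binWidth bin width in seconds.
#' @return a \linkS4class{RateProfile}.
#' @export
populationPsth <- function(spikeSet, binWidth = 0.01) {
  stopifnot(binWidth > 0)
  edges <- seq(0, spikeSet@duration, by = binWidth)
  if (max(edges) < spikeSet@duration - 1e-12)
    edges <- c(edges, max(edges) + binWidth)
  allSpikes <- unlist(spikeSet@spikes, use.names = FALSE)
  counts <- binCount(allSpikes, edges)
  nUnits <- length(spikeSet@spikes)
  new("RateProfile", binEdges = edges,
      rate = counts / (nUnits * binWidth), nTrials = as.integer(nUnits),
      binWidthMethod = "fixed", smoothing = list())
}
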