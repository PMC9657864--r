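#' @include AllClasses.R
NULL

# Raised-cosine ramp from `from` to `to` over [t0, t1]: smooth, with peak
# rate (to - from) * pi / (2 * (t1 - t0)) at the midpoint. Constant outside.
.rc <- function(t, t0, t1, from, to) {
  s <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  from + (to - from) * (1 - cos(pi * s)) / 2
}

# Scenario motion profiles for the two-rod skeleton. Each returns the
# trunk angle from vertical (rad, leaning towards +x), the hip track and
# the impact time (NA for non-falls). Fall ramps are scaled so the trunk's
# peak angular rate equals fallPeakAngularRate; ADL ramps stay below
# adlMaxAngularRate.
.scenarioProfile <- function(scenario, cfg) {
  wFall <- cfg@fallPeakAngularRate
  wAdl <- cfg@adlMaxAngularRate
  hip0 <- c(0.45, 0.62)
  const <- function(v) function(t) rep(v, length(t))
  switch(scenario,
    stand = list(duration = 3, activityId = 7L, impact = NA_real_,
                 theta = const(0), hipX = const(hip0[1]), hipY = const(hip0[2]),
                 z = const(0.5)),
    walk = list(duration = 4, activityId = 6L, impact = NA_real_,
                theta = function(t) 0.045 * sin(2 * pi * 0.9 * t),
                hipX = function(t) hip0[1] + 0.12 * sin(2 * pi * t / 4),
                hipY = function(t) hip0[2] + 0.008 * sin(2 * pi * 1.8 * t),
                z = const(0.5)),
    sit = list(duration = 3.5, activityId = 8L, impact = NA_real_,
               theta = function(t) .rc(t, 1.0, 1.8, 0, 0.2) +
                                   .rc(t, 2.2, 3.0, 0, -0.15),
               hipX = const(hip0[1]),
               hipY = function(t) .rc(t, 1.0, 2.2, hip0[2], hip0[2] + 0.14),
               z = const(0.5)),
    bend_intentional = {
      thetaMax <- 1.0
      Tb <- thetaMax * pi / (2 * 0.9 * wAdl)  # peak rate 0.9 * adl bound
      list(duration = 0.6 + Tb + 0.3 + Tb + 0.3, activityId = 9L,
           impact = NA_real_,
           theta = function(t) .rc(t, 0.6, 0.6 + Tb, 0, thetaMax) +
                               .rc(t, 0.9 + Tb, 0.9 + 2 * Tb, 0, -thetaMax),
           hipX = const(hip0[1]), hipY = const(hip0[2]), z = const(0.5))
    },
    fall_forward = {
      thetaMax <- 1.92  # past horizontal: nose ends below hip level
      Tf <- thetaMax * pi / (2 * wFall)
      # short pre-fall lead-in: the retained trial is about one window, so
      # the high-rate ramp and the R > 1 crossing lie inside the windows
      # the classifier sees
      list(duration = 0.2 + Tf + 0.4, activityId = 1L, impact = 0.2 + Tf,
           theta = function(t) .rc(t, 0.2, 0.2 + Tf, 0, thetaMax),
           hipX = const(hip0[1]),
           hipY = function(t) .rc(t, 0.2, 0.2 + Tf, hip0[2], hip0[2] + 0.08),
           z = const(0.5))
    },
    fall_sideward = {
      thetaMax <- 1.75
      Tf <- thetaMax * pi / (2 * wFall)
      list(duration = 0.2 + Tf + 0.4, activityId = 5L, impact = 0.2 + Tf,
           theta = function(t) .rc(t, 0.2, 0.2 + Tf, 0, thetaMax),
           hipX = function(t) .rc(t, 0.2, 0.2 + Tf, hip0[1], hip0[1] - 0.05),
           hipY = function(t) .rc(t, 0.2, 0.2 + Tf, hip0[2], hip0[2] + 0.06),
           z = function(t) .rc(t, 0.2, 0.2 + Tf, 0.5, 0.25))
    },
    near_fall_recovered = {
      thetaMax <- 1.2  # short of horizontal: nose never passes the hip
      Tu <- thetaMax * pi / (2 * 0.6 * wFall)   # stumble, between ADL and fall
      Td <- (thetaMax - 0.1) * pi / (2 * 0.9 * wAdl)
      list(duration = 0.4 + Tu + 0.2 + Td + 0.3, activityId = 12L,
           impact = NA_real_,
           theta = function(t) .rc(t, 0.4, 0.4 + Tu, 0, thetaMax) +
                               .rc(t, 0.6 + Tu, 0.6 + Tu + Td, 0,
                                   -(thetaMax - 0.1)),
           hipX = const(hip0[1]), hipY = const(hip0[2]), z = const(0.5))
    },
    .stopf("unknown scenario '%s' (expected one of: %s)", scenario,
           paste(.SCENARIOS, collapse = ", ")))
}

#' Scenario names understood by the simulator
#'
#' @return Character vector of the seven scenario names (two falls, five
#'   not-falls including the recovered near-fall).
#' @export
scenarioNames <- function() .SCENARIOS

#' Simulate one trial of skeleton key-point motion
#'
#' Generates nose / left-shoulder / left-hip trajectories from a two-rod
#' chain (hip to shoulder of `trunkLength`, shoulder to nose of
#' `neckLength`) whose trunk angle follows a smooth scenario-specific
#' profile, plus seeded per-frame Gaussian coordinate jitter standing in
#' for pose-estimation error. Falls rotate the trunk from vertical past
#' horizontal with peak angular rate `fallPeakAngularRate`, driving the
#' nose below hip height (the height ratio R crosses 1); frames from the
#' simulated impact onwards are flagged `post_impact`. ADL scenarios keep
#' trunk rates within `adlMaxAngularRate` and R below 1; the recovered
#' near-fall rises at an intermediate rate and returns upright. When
#' `noiseSd > 0`, frame intervals also jitter by 2\% around `1/fps`.
#'
#' @param scenario one of [scenarioNames()].
#' @param cfg a [SimulationConfig-class].
#' @param subjectId,trialId identifiers for the generated sequence.
#' @param seed optional seed; by default the trial consumes the caller's
#'   RNG stream (as [simulateDataset()] does).
#' @return A [KeypointSequence-class].
#' @export
simulateTrial <- function(scenario, cfg = simulationConfig(),
                          subjectId = "S01", trialId = NULL, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  prof <- .scenarioProfile(scenario, cfg)
  if (is.null(trialId)) trialId <- paste0(scenario, "_T001")
  gen <- function() {
    n <- max(2L, floor(prof$duration * cfg@fps) + 1L)
    dt <- rep(1 / cfg@fps, n - 1L)
    if (cfg@noiseSd > 0)
      dt <- pmax(dt * (1 + 0.02 * stats::rnorm(n - 1L)), 0.2 / cfg@fps)
    t <- c(0, cumsum(dt))
    theta <- prof$theta(t)
    hipX <- prof$hipX(t); hipY <- prof$hipY(t)
    shX <- hipX + cfg@trunkLength * sin(theta)
    shY <- hipY - cfg@trunkLength * cos(theta)
    nX <- shX + cfg@neckLength * sin(theta)
    nY <- shY - cfg@neckLength * cos(theta)
    z <- prof$z(t)
    fr <- data.frame(t = t, activity_id = prof$activityId,
                     excluded = FALSE,
                     post_impact = if (is.na(prof$impact)) FALSE
                                   else t >= prof$impact,
                     N_x = nX, N_y = nY, N_z = z,
                     LSh_x = shX, LSh_y = shY, LSh_z = z,
                     LH_x = hipX, LH_y = hipY, LH_z = z)
    if (cfg@noiseSd > 0) {
      coordCols <- .KP_COORD_COLS
      jitter <- matrix(stats::rnorm(n * length(coordCols), 0, cfg@noiseSd),
                       n, length(coordCols))
      fr[coordCols] <- fr[coordCols] + jitter
    }
    # post-impact frames are also marked excluded: they carry no pre-fall
    # information and the filtered stream must end at the impact
    fr$excluded <- fr$excluded | fr$post_impact
    KeypointSequence(fr, subjectId = subjectId, trialId = trialId,
                     nominalFps = cfg@fps)
  }
  if (is.null(seed)) gen() else .withSeed(seed, gen())
}

#' Simulate a labelled multi-trial key-point dataset
#'
#' Generates `nTrialsPerScenario` trials for every scenario in the mix,
#' interleaved round-robin (trial k of every scenario before trial k + 1)
#' so that an unshuffled temporal split sees both classes on each side —
#' as when subjects perform each activity in turn. Subjects cycle through
#' 17 identifiers, mirroring a multi-subject recording campaign.
#'
#' @param cfg a [SimulationConfig-class]; `cfg@seed` drives all
#'   randomness.
#' @return List with `sequences` (list of [KeypointSequence-class]) and
#'   `activityMap` (see [defaultActivityMap()]).
#' @examples
#' d <- simulateDataset(simulationConfig(nTrialsPerScenario = 1,
#'                                       scenarios = c("stand", "fall_forward")))
#' length(d$sequences)
#' @export
simulateDataset <- function(cfg = simulationConfig()) {
  stopifnot(is(cfg, "SimulationConfig"))
  .withSeed(cfg@seed, {
    seqs <- list()
    for (k in seq_len(cfg@nTrialsPerScenario)) {
      subj <- sprintf("S%02d", (k - 1L) %% 17L + 1L)
      for (sc in cfg@scenarios) {
        seqs[[length(seqs) + 1L]] <-
          simulateTrial(sc, cfg, subjectId = subj,
                        trialId = sprintf("T%03d_%s", k, sc))
      }
    }
    list(sequences = seqs, activityMap = defaultActivityMap())
  })
}
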