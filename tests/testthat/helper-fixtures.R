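# Shared fixtures: tiny keypoint/feature tables built in code.

# A well-formed keypoint frame table with simple deterministic motion.
makeFrames <- function(n = 10, t = seq(0, by = 0.05, length.out = n),
                       activity = 7L) {
  data.frame(t = t, activity_id = rep(activity, n),
             excluded = rep(FALSE, n), post_impact = rep(FALSE, n),
             N_x = 0.45 + 0.01 * seq_len(n), N_y = 0.20 + 0.002 * seq_len(n),
             N_z = rep(0.5, n),
             LSh_x = rep(0.45, n), LSh_y = rep(0.34, n), LSh_z = rep(0.5, n),
             LH_x = rep(0.45, n), LH_y = rep(0.62, n), LH_z = rep(0.5, n))
}

makeSeq <- function(n = 10, subject = "S01", trial = "T001", ...)
  KeypointSequence(makeFrames(n, ...), subjectId = subject, trialId = trial)

# Feature table with controllable per-trial row counts and labels;
# values are arbitrary but finite and distinct.
makeFeatureTable <- function(rowsPerTrial, labels,
                             subjects = rep("S01", length(rowsPerTrial))) {
  stopifnot(length(rowsPerTrial) == length(labels))
  out <- NULL
  for (i in seq_along(rowsPerTrial)) {
    n <- rowsPerTrial[i]
    df <- data.frame(t = seq(0, by = 0.05, length.out = n),
                     subject_id = subjects[i],
                     trial_id = sprintf("T%03d", i),
                     activity_id = if (labels[i] == "fall") 1L else 7L,
                     label = labels[i],
                     N_x = runif(n), N_y = runif(n),
                     A_N = runif(n), A_LSh = runif(n), A_LH = runif(n),
                     dw_N = rnorm(n), dw_LSh = rnorm(n), dw_LH = rnorm(n),
                     R = runif(n, 0.2, 1.3), stringsAsFactors = FALSE)
    out <- rbind(out, df)
  }
  out
}

# Small, fast simulation settings used across tests.
testSimConfig <- function(...) {
  simulationConfig(nTrialsPerScenario = 2, noiseSd = 0, seed = 11, ...)
}

noiselessTrial <- function(scenario, ...) {
  simulateTrial(scenario, simulationConfig(noiseSd = 0), seed = 5, ...)
}
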