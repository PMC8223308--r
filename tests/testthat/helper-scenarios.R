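# Scenario fixtures used across test files. Probability labels read
# arm 1 / arm 0; equal scale means middle-part SDs (13.34, 14.63).

scenario_80_15_5 <- function(n_obs = 100, equal_scale = TRUE) {
  sds <- if (equal_scale) c(sd1 = 13.34, sd0 = 14.63)
         else c(sd1 = 12, sd0 = 16)
  scenario_config(
    n_obs = n_obs,
    probs0 = c(0.60, 0.30, 0.10), probs1 = c(0.80, 0.15, 0.05),
    mid_sd0 = sds[["sd0"]], mid_sd1 = sds[["sd1"]],
    label = sprintf("80:15:5/60:30:10, %s scale",
                    if (equal_scale) "equal" else "unequal"))
}

scenario_50_40_10 <- function(n_obs = 100, equal_scale = TRUE) {
  sds <- if (equal_scale) c(sd1 = 13.34, sd0 = 14.63)
         else c(sd1 = 12, sd0 = 16)
  scenario_config(
    n_obs = n_obs,
    probs0 = c(0.30, 0.55, 0.15), probs1 = c(0.50, 0.40, 0.10),
    mid_sd0 = sds[["sd0"]], mid_sd1 = sds[["sd1"]],
    label = sprintf("50:40:10/30:55:15, %s scale",
                    if (equal_scale) "equal" else "unequal"))
}

# A moderately sized, well-mixed dataset reused by estimator tests.
fixture_trial <- function(n_obs = 200, seed = 42) {
  simulate_trial(scenario_50_40_10(n_obs = n_obs), seed = seed)
}
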