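# shared fixtures and independent oracles, built in code

default_starts <- function(cfg = staircase_config()) {
  cfg$max_disparity * rep_len(c(1, -1), cfg$games_per_subject)
}

# endpoints of a full three-game session for one observer
run_three_games <- function(observer, seed = 1L, cfg = staircase_config()) {
  starts <- default_starts(cfg)
  vapply(seq_len(cfg$games_per_subject), function(g) {
    run_brightness_game(observer, cfg, seed = seed + g,
                        start_disparity = starts[g], game_index = g)$endpoint
  }, numeric(1))
}

# specificity (% of normal observers scoring balanced) at a decision noise,
# over common random seeds
specificity_at_noise <- function(noise, n_seeds = 200, cfg = staircase_config()) {
  balanced <- vapply(seq_len(n_seeds), function(s) {
    obs <- observer_normal(decision_noise = noise)
    eps <- run_three_games(obs, seed = 10L * s, cfg = cfg)
    classify_brightness(eps, cfg)$label == "balanced"
  }, logical(1))
  100 * mean(balanced)
}

# closed-form oracle for the acuity protocol: smallest ladder line whose
# logMAR is at or above the effective threshold; NA when even the largest
# line is below threshold (below-floor)
smallest_line_at_or_above <- function(threshold, ladder = chart_ladder()) {
  sizes <- unclass(ladder)
  ok <- sizes[snellen_to_logmar(sizes) >= threshold - 1e-9]
  if (length(ok) == 0) NA_real_ else min(ok)
}

# brute-force two-pass Bland-Altman oracle, written independently of the
# implementation (explicit loops, no mean()/sd())
ba_oracle <- function(first, second, multiplier = 2) {
  n <- length(first)
  tot <- 0
  for (i in seq_len(n)) tot <- tot + (first[i] - second[i])
  d <- tot / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + ((first[i] - second[i]) - d)^2
  s <- sqrt(ss / (n - 1))
  list(d = d, sd = s, lower = d - multiplier * s, upper = d + multiplier * s)
}
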