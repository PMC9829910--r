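test_that("staircase config enforces its grid invariants", {
  expect_error(staircase_config(step = 0.3, max_disparity = 1.7), "multiple")
  expect_error(staircase_config(start_disparity = 2.1), "exceed")
  expect_error(staircase_config(required_crossings = 1), "re-cross")
  expect_error(staircase_config(step = 0), "not TRUE")
})

test_that("a response moves the disparity one step against the chosen eye", {
  cfg <- staircase_config()
  st <- new_staircase(cfg, start_disparity = 0.3)
  st <- staircase_step(st, "OD")
  expect_equal(st$unit * cfg$step, 0)
  expect_equal(length(st$resp_eye), 1L)
  st <- staircase_step(st, "OS")          # reversal: crossing between 0.3 and 0
  expect_equal(length(st$crossing_units), 1L)
  expect_equal(st$crossing_units * cfg$step, 0.15)
  expect_false(st$finished)
  st <- staircase_step(st, "OD")          # second reversal finishes the game
  expect_equal(length(st$crossing_units), 2L)
  expect_true(st$finished)
  expect_error(staircase_step(st, "OD"), "finished")
})

test_that("disparities are clamped to the grid and stay on it", {
  cfg <- staircase_config()
  st <- new_staircase(cfg, start_disparity = 1.8)
  st <- staircase_step(st, "OS")          # would exceed +1.8
  expect_equal(st$unit, cfg$max_units)
  g <- run_brightness_game(observer_amblyope(delta = 0.3), cfg, seed = 1)
  expect_true(all(abs(g$trace$disparity / cfg$step -
                        round(g$trace$disparity / cfg$step)) < 1e-9))
  expect_true(all(abs(g$trace$disparity) <= cfg$max_disparity + 1e-9))
})

test_that("noiseless observers recover their deficit exactly over the whole grid", {
  cfg <- staircase_config()
  for (du in -6:6) {
    obs <- observer_profile(
      brightness_attenuation = c(OD = max(0, -du) * 0.3, OS = max(0, du) * 0.3)
    )
    for (su in -6:6) {
      g <- run_brightness_game(obs, cfg, start_disparity = su * 0.3)
      expect_equal(g$endpoint, du * 0.3, tolerance = 1e-12)
      expect_false(g$ceiling && abs(du) < 6)
    }
  }
})

test_that("mirroring the observer negates the endpoint", {
  cfg <- staircase_config()
  for (d in seq(0, 1.8, by = 0.3)) {
    e_os <- run_brightness_game(
      observer_profile(brightness_attenuation = c(OD = 0, OS = d)), cfg)$endpoint
    e_od <- run_brightness_game(
      observer_profile(brightness_attenuation = c(OD = d, OS = 0)), cfg)$endpoint
    expect_equal(e_os, -e_od, tolerance = 1e-12)
  }
})

test_that("every game terminates within the trial budget", {
  cfg <- staircase_config()
  budget <- 2 * (2 * cfg$max_units + 1) * cfg$required_crossings
  expect_equal(budget, 52)
  # adversarial sequences driven directly through the state machine
  adversaries <- list(
    function(i, unit) "OD",                          # never reverses
    function(i, unit) if (i %% 2 == 0) "OD" else "OS",  # thrashes every trial
    function(i, unit) if (unit > -6) "OD" else "OS"  # reverses only at the rail
  )
  for (adv in adversaries) {
    st <- new_staircase(cfg, 1.8)
    i <- 0
    while (!st$finished) {
      i <- i + 1
      st <- staircase_step(st, adv(i, st$unit))
      expect_lte(st$trial, budget)
    }
  }
  # stochastic responses, many seeds
  for (s in 1:25) {
    obs <- observer_normal(decision_noise = 2)
    g <- run_brightness_game(obs, cfg, seed = s)
    expect_lte(g$trials, budget)
  }
})

test_that("a never-reversing observer hits the ceiling at the grid extreme", {
  # attenuation far beyond the grid: always picks the same eye
  obs <- observer_profile(brightness_attenuation = c(OD = 0, OS = 5))
  g <- run_brightness_game(obs, staircase_config())
  expect_true(g$ceiling)
  expect_equal(abs(g$endpoint), 1.8)
})

test_that("expected endpoint magnitude grows with the deficit under noise", {
  # decision noise within the operating range (below the 0.3 step): at
  # larger noise the grid snapping pulls one-step deficits to zero and the
  # ordering between 0 and 0.3 is lost (see the methods vignette)
  cfg <- staircase_config()
  mean_abs <- vapply(c(0, 0.3, 0.6, 0.9), function(d) {
    obs <- observer_profile(brightness_attenuation = c(OD = 0, OS = d),
                            decision_noise = 0.15)
    mean(vapply(1:200, function(s) {
      abs(run_brightness_game(obs, cfg, seed = 1000 + s)$endpoint)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_abs) > 0))
})

test_that("two-of-three net-zero classification follows the study's rule", {
  cfg <- staircase_config()
  expect_identical(classify_brightness(c(0, 0, 0), cfg)$label, "balanced")
  # persistent one-sided deficit screens positive
  imb <- classify_brightness(c(0.3, 0.3, 0.3), cfg)
  expect_identical(imb$label, "imbalanced")
  expect_equal(imb$net_imbalance, 0.3)
  # the treated amblyope's alternating preference counts as balanced
  expect_identical(classify_brightness(c(0.3, -0.3, 0), cfg)$label, "balanced")
  expect_identical(classify_brightness(c(0.3, 0, 0), cfg)$label, "balanced")
  mix <- classify_brightness(c(0.6, 0.6, 0.3), cfg)
  expect_identical(mix$label, "imbalanced")
  expect_equal(mix$net_imbalance, 0.6)
  expect_identical(classify_brightness(c(-0.3, -0.6, 0), cfg)$label,
                   "imbalanced")
  expect_equal(classify_brightness(c(-0.3, -0.6, 0), cfg)$net_imbalance, -0.6)
  expect_error(classify_brightness(c(0, 0), cfg), "expected 3")
})

test_that("the net-sum reading of the rule is available behind the config", {
  cfg <- staircase_config(balance_rule = "net-sum")
  expect_identical(classify_brightness(c(0.3, -0.3, 0), cfg)$label, "balanced")
  expect_identical(classify_brightness(c(0.3, 0, 0), cfg)$label, "imbalanced")
})

test_that("games are reproducible given the seed", {
  obs <- observer_normal(decision_noise = 0.2)
  g1 <- run_brightness_game(obs, seed = 7)
  g2 <- run_brightness_game(obs, seed = 7)
  expect_identical(g1$trace, g2$trace)
  expect_identical(g1$endpoint, g2$endpoint)
})
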