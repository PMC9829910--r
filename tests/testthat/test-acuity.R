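test_that("three correct responses advance to the next smaller line", {
  st <- acuity_start(60)
  for (i in 1:3) st <- acuity_step(st, TRUE, TRUE)
  expect_equal(st$size, 50)
  expect_equal(st$n_correct, 0L)
  expect_equal(st$completed, 60)
  expect_false(st$second_chance)
})

test_that("one error opens a second chance; a second error ends the run", {
  st <- acuity_start(40)
  st <- acuity_step(st, TRUE, FALSE)          # first error at the line
  expect_true(st$second_chance)
  expect_equal(st$second_remaining, 3L)
  expect_false(st$ended)
  st <- acuity_step(st, TRUE, TRUE)           # a correct pair consumes one
  expect_equal(st$second_remaining, 2L)
  st <- acuity_step(st, FALSE, TRUE)          # second error terminates
  expect_true(st$ended)
  expect_equal(st$end_size, 40)
  expect_error(acuity_step(st, TRUE, TRUE), "ended")
})

test_that("three correct within the second chance still advance the line", {
  st <- acuity_start(40)
  st <- acuity_step(st, TRUE, TRUE)           # 1 correct
  st <- acuity_step(st, TRUE, FALSE)          # error -> second chance
  st <- acuity_step(st, TRUE, TRUE)           # 2
  st <- acuity_step(st, FALSE, FALSE)         # 3 -> advance
  expect_equal(st$completed, 40)
  expect_equal(st$size, 30)
  expect_false(st$second_chance)
})

test_that("completing the smallest line ends the run at 20/20", {
  st <- acuity_start(25)
  for (i in 1:6) st <- acuity_step(st, TRUE, TRUE)
  expect_true(st$ended)
  expect_equal(st$completed, c(25, 20))
})

test_that("recorded acuity equals the smallest line at or above threshold", {
  # closed-form oracle across the whole threshold range, several seeds
  ladder <- chart_ladder()
  for (thr in seq(-0.05, 1.45, by = 0.1)) {
    obs <- observer_profile(neural_logmar = c(OD = thr, OS = thr))
    want <- smallest_line_at_or_above(thr, ladder)
    for (s in c(1, 17)) {
      got <- run_acuity_test(obs, "OD", seed = s)$acuity
      if (is.na(want)) {
        expect_true(got$below_floor)
      } else {
        expect_false(got$below_floor)
        expect_equal(got$denominator, want)
      }
    }
  }
})

test_that("failure at the starting size restarts once from the largest line", {
  # threshold 20/200: every size below 200 fails, so the 20/60 start
  # completes nothing and the session restarts at 20/400
  obs <- observer_profile(neural_logmar = c(OD = 1.0, OS = 1.0))
  run <- run_acuity_test(obs, "OD", start_size = 60, seed = 3)
  expect_true(run$restarted)
  expect_equal(sort(unique(run$trials$pass)), c(1, 2))
  expect_equal(run$acuity$denominator, 200)
  # an observer failing even 20/400 is recorded below floor
  deep <- observer_profile(neural_logmar = c(OD = 1.4, OS = 1.4))
  res <- run_acuity_test(deep, "OD", seed = 3)
  expect_true(res$acuity$below_floor)
})

test_that("the pinhole retest triggers at 20/30 or worse and only then", {
  # refractive blur: unaided 20/40, normalises through the pinhole
  refr <- run_eye_protocol(observer_refractive(0.3), "OD", seed = 2)
  expect_true(refr$pinhole_required)
  expect_equal(refr$unaided$denominator, 40)
  expect_equal(refr$pinhole$denominator, 20)
  # neural (amblyopic) loss: no pinhole improvement
  amb <- run_eye_protocol(observer_amblyope(neural = 0.3), "OS", seed = 2)
  expect_true(amb$pinhole_required)
  expect_equal(amb$unaided$denominator, 40)
  expect_equal(amb$pinhole$denominator, 40)
  # 20/25 is better than the cutoff: no pinhole administered
  near <- observer_profile(neural_logmar = c(OD = 0.09, OS = 0.09))
  out <- run_eye_protocol(near, "OD", seed = 2)
  expect_equal(out$unaided$denominator, 25)
  expect_false(out$pinhole_required)
  expect_null(out$pinhole)
})

test_that("the pinhole never worsens the modelled threshold or the record", {
  cases <- expand.grid(neural = c(0, 0.2, 0.5), refractive = c(0, 0.3, 0.6))
  for (i in seq_len(nrow(cases))) {
    obs <- observer_profile(
      neural_logmar = c(OD = cases$neural[i], OS = cases$neural[i]),
      refractive_logmar = c(OD = cases$refractive[i], OS = cases$refractive[i])
    )
    out <- run_eye_protocol(obs, "OD", seed = i)
    if (out$pinhole_required && !out$pinhole$below_floor &&
        !out$unaided$below_floor) {
      expect_lte(out$pinhole$logmar, out$unaided$logmar)
    }
  }
})

test_that("runs are seed-reproducible with chance-level guessing", {
  obs <- observer_profile(neural_logmar = c(OD = 0.3, OS = 0.3),
                          acuity_guess_rate = 0.5)
  r1 <- run_acuity_test(obs, "OD", seed = 11)
  r2 <- run_acuity_test(obs, "OD", seed = 11)
  expect_identical(r1$trials, r2$trials)
})

test_that("match/mismatch pairs are drawn at 50/50", {
  obs <- observer_profile(neural_logmar = c(OD = 0.5, OS = 0.5),
                          acuity_guess_rate = 0.5)
  matches <- unlist(lapply(1:300, function(s) {
    run_acuity_test(obs, "OD", seed = s)$trials$pair_is_match
  }))
  expect_gt(length(matches), 1000)
  expect_equal(mean(matches), 0.5, tolerance = 0.05)
})

test_that("every run terminates within the line-budget bound", {
  # worst case: 6 pairs per line (3 correct + error + up to 3 second-chance
  # pairs overlap), twice through the ladder with the restart
  ladder <- chart_ladder()
  bound <- 2 * length(unclass(ladder)) * 7
  for (thr in c(0, 0.5, 1.0, 1.5)) {
    obs <- observer_profile(neural_logmar = c(OD = thr, OS = thr),
                            acuity_guess_rate = 0.5)
    for (s in 1:5) {
      run <- run_acuity_test(obs, "OD", seed = s)
      expect_lte(nrow(run$trials), bound)
    }
  }
})
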