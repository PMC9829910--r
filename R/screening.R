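#' Screening-session configuration
#'
#' Bundles the protocol parameters of a full screening session. The three
#' brightness games alternate their starting side (+max, -max, +max) to
#' cancel starting-side bias.
#'
#' @param staircase A [staircase_config()].
#' @param ladder A [chart_ladder()].
#' @param plates A plate set, or `NULL` to load the packaged set lazily.
#' @param start_size Acuity starting line (default 60).
#' @param pinhole_cutoff Pinhole-retest rule, "20/30 or worse" (default 30).
#' @param referral_cutoff Acuity referral rule: refer when the best measured
#'   acuity is strictly worse than this line (default 30).
#' @param defect_threshold Colour-defect threshold (errors per axis).
#' @param game_starts Signed start disparities of the games; recycled to
#'   `games_per_subject`.
#' @param tests Which protocols to run, a subset of
#'   `c("brightness", "acuity", "color")`.
#' @return A `screening_config` object.
#' @export
screening_config <- function(staircase = staircase_config(),
                             ladder = chart_ladder(),
                             plates = NULL,
                             start_size = 60,
                             pinhole_cutoff = 30,
                             referral_cutoff = 30,
                             defect_threshold = 2,
                             game_starts = NULL,
                             tests = c("brightness", "acuity", "color")) {
  stopifnot(inherits(staircase, "staircase_config"),
            inherits(ladder, "chart_ladder"))
  tests <- match.arg(tests, c("brightness", "acuity", "color"),
                     several.ok = TRUE)
  if (is.null(game_starts)) {
    game_starts <- staircase$max_disparity *
      rep_len(c(1, -1), staircase$games_per_subject)
  }
  game_starts <- rep_len(game_starts, staircase$games_per_subject)
  structure(
    list(staircase = staircase, ladder = ladder, plates = plates,
         start_size = start_size, pinhole_cutoff = pinhole_cutoff,
         referral_cutoff = referral_cutoff,
         defect_threshold = defect_threshold,
         game_starts = game_starts, tests = tests),
    class = "screening_config"
  )
}

config_plates <- function(config) config$plates %||% hrr_plates()

#' Screen one simulated subject
#'
#' Runs the full session: three brightness-disparity games, both eyes'
#' acuity protocol with the pinhole-retest rule, and both eyes' colour test.
#' The subject is referred when any of three independent abnormal results
#' occurs: a brightness imbalance, a best measured (pinhole when
#' administered) acuity strictly worse than 20/30 in either eye, or a
#' monocular colour defect.
#'
#' @param observer An [observer_profile()].
#' @param config A [screening_config()].
#' @param seed Integer seed; every protocol run derives its own sub-seed
#'   from it so a session is fully reproducible.
#' @param subject_id Identifier stored in the record.
#' @param truth_label True condition label; defaults to the observer's
#'   archetype label.
#' @return A `subject_record`: `subject_id`, `truth_label`, `brightness`
#'   (classification, with `games`), `acuity` (per-eye outcomes), `color`
#'   (per-eye results and, when both eyes qualify, the classification),
#'   `referred`, `referral_reasons`, `seed`.
#' @examples
#' rec <- screen_subject(observer_amblyope(), seed = 7)
#' rec$referred; rec$referral_reasons
#' @export
screen_subject <- function(observer, config = screening_config(), seed = 1L,
                           subject_id = "S1", truth_label = observer$label) {
  stopifnot(inherits(observer, "observer_profile"),
            inherits(config, "screening_config"))
  seed <- as.integer(seed)
  reasons <- character(0)

  brightness <- NULL
  if ("brightness" %in% config$tests) {
    games <- lapply(seq_len(config$staircase$games_per_subject), function(g) {
      run_brightness_game(observer, config$staircase, seed = seed + g,
                          start_disparity = config$game_starts[g],
                          game_index = g)
    })
    brightness <- classify_brightness(games, config$staircase)
    brightness$games <- games
    if (brightness$label == "imbalanced") {
      reasons <- c(reasons, "brightness-imbalance")
    }
  }

  acuity <- NULL
  if ("acuity" %in% config$tests) {
    acuity <- list(
      OD = run_eye_protocol(observer, "OD", config$start_size, config$ladder,
                            seed = seed + 11L,
                            pinhole_cutoff = config$pinhole_cutoff),
      OS = run_eye_protocol(observer, "OS", config$start_size, config$ladder,
                            seed = seed + 13L,
                            pinhole_cutoff = config$pinhole_cutoff)
    )
    for (eye in c("OD", "OS")) {
      if (acuity_worse_than(best_acuity(acuity[[eye]]),
                            config$referral_cutoff, strict = TRUE)) {
        reasons <- c(reasons, paste0("acuity-", eye))
      }
    }
  }

  color <- NULL
  if ("color" %in% config$tests) {
    plates <- config_plates(config)
    od <- run_color_test(observer, "OD", plates, seed = seed + 21L,
                         defect_threshold = config$defect_threshold)
    os <- run_color_test(observer, "OS", plates, seed = seed + 22L,
                         defect_threshold = config$defect_threshold)
    classification <- if (od$qualified && os$qualified) {
      classify_color(od, os)
    } else NULL
    color <- list(od = od, os = os, classification = classification)
    if (!is.null(classification) && classification$category == "monocular") {
      reasons <- c(reasons, "monocular-colour-defect")
    }
  }

  structure(
    list(
      subject_id = as.character(subject_id),
      truth_label = as.character(truth_label),
      brightness = brightness,
      acuity = acuity,
      color = color,
      referred = length(reasons) > 0L,
      referral_reasons = reasons,
      seed = seed
    ),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject %s (%s): %s%s>\n", x$subject_id, x$truth_label,
              if (x$referred) "REFERRED" else "not referred",
              if (x$referred) paste0(" [", paste(x$referral_reasons,
                                                 collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Generate a simulated cohort of observer profiles
#'
#' Expands archetype counts into a deterministic list of observer profiles.
#' The amblyope entries cycle their interocular brightness attenuation
#' through `amblyope_deltas` (default 0.3 then 0.6 log units, the two
#' endpoint magnitudes the study reports) with a matching neural acuity
#' loss.
#'
#' @param spec Named counts, e.g. `list(normal = 202, "unilateral-amblyope"
#'   = 2)`; names from `normal`, `unilateral-amblyope`, `refractive`,
#'   `treated-amblyope`, `color-defect`.
#' @param seed Integer seed (profiles are currently deterministic given the
#'   spec; the seed scopes any stochastic parameter draws).
#' @param decision_noise,acuity_guess_rate Applied to every profile.
#' @param amblyope_deltas Brightness attenuations cycled over amblyopes.
#' @param amblyope_neural Neural acuity loss (logMAR) of amblyopes.
#' @return A list of [observer_profile()]s, in spec order.
#' @examples
#' cohort <- simulate_cohort(list(normal = 3, "unilateral-amblyope" = 1))
#' vapply(cohort, function(o) o$label, "")
#' @export
simulate_cohort <- function(spec = list(normal = 202,
                                        "unilateral-amblyope" = 2),
                            seed = 1L, decision_noise = 0,
                            acuity_guess_rate = 0,
                            amblyope_deltas = c(0.3, 0.6),
                            amblyope_neural = 0.3) {
  counts <- unlist(spec)
  if (length(counts) == 0L || sum(counts) < 1) {
    stop("cohort spec must request at least one subject", call. = FALSE)
  }
  if (any(counts < 0)) stop("archetype counts must be >= 0", call. = FALSE)
  known <- c("normal", "unilateral-amblyope", "refractive",
             "treated-amblyope", "color-defect")
  if (!all(names(counts) %in% known)) {
    stop("unknown archetype(s): ",
         paste(setdiff(names(counts), known), collapse = ", "), call. = FALSE)
  }
  run_seeded(seed, function() {
    profiles <- list()
    n_amb <- 0L
    for (arch in names(counts)) {
      for (i in seq_len(counts[[arch]])) {
        p <- switch(arch,
          "normal" = observer_normal(decision_noise, acuity_guess_rate),
          "unilateral-amblyope" = {
            n_amb <- n_amb + 1L
            d <- amblyope_deltas[((n_amb - 1L) %% length(amblyope_deltas)) + 1L]
            observer_amblyope(delta = d, neural = amblyope_neural,
                              decision_noise = decision_noise,
                              acuity_guess_rate = acuity_guess_rate)
          },
          "refractive" = observer_refractive(
            decision_noise = decision_noise,
            acuity_guess_rate = acuity_guess_rate),
          "treated-amblyope" = observer_treated_amblyope(
            decision_noise = decision_noise,
            acuity_guess_rate = acuity_guess_rate),
          "color-defect" = observer_color_defect(
            decision_noise = decision_noise,
            acuity_guess_rate = acuity_guess_rate)
        )
        profiles[[length(profiles) + 1L]] <- p
      }
    }
    profiles
  })
}

#' Screen a whole cohort
#'
#' @param profiles A list of [observer_profile()]s (see
#'   [simulate_cohort()]).
#' @param config A [screening_config()].
#' @param seed Integer seed; subject `i` is screened with seed
#'   `seed + 100 * i`.
#' @return A list of `subject_record`s.
#' @export
run_cohort <- function(profiles, config = screening_config(), seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  seed <- as.integer(seed)
  lapply(seq_along(profiles), function(i) {
    screen_subject(profiles[[i]], config, seed = seed + 100L * i,
                   subject_id = sprintf("S%03d", i))
  })
}

#' One-row-per-subject cohort summary table
#'
#' @param records A list of `subject_record`s.
#' @return A data.frame with the subject id, truth label, the three game
#'   endpoints and brightness label, per-eye acuities in logMAR (`NA` when
#'   below floor or not tested), colour labels, and the referral decision.
#' @export
cohort_table <- function(records) {
  num_or_na <- function(va) {
    if (is.null(va) || va$below_floor) NA_real_ else va$logmar
  }
  rows <- lapply(records, function(r) {
    ep <- if (!is.null(r$brightness)) r$brightness$endpoints else rep(NA_real_, 3)
    data.frame(
      subject_id = r$subject_id,
      truth_label = r$truth_label,
      endpoint_1 = ep[1], endpoint_2 = ep[2], endpoint_3 = ep[3],
      brightness = if (!is.null(r$brightness)) r$brightness$label else NA,
      net_imbalance = if (!is.null(r$brightness)) r$brightness$net_imbalance else NA,
      unaided_od = if (!is.null(r$acuity)) num_or_na(r$acuity$OD$unaided) else NA,
      unaided_os = if (!is.null(r$acuity)) num_or_na(r$acuity$OS$unaided) else NA,
      pinhole_od = if (!is.null(r$acuity)) num_or_na(r$acuity$OD$pinhole) else NA,
      pinhole_os = if (!is.null(r$acuity)) num_or_na(r$acuity$OS$pinhole) else NA,
      color_od = if (!is.null(r$color)) r$color$od$label else NA,
      color_os = if (!is.null(r$color)) r$color$os$label else NA,
      referred = r$referred,
      referral_reasons = paste(r$referral_reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Diagnostic performance of a screening rule
#'
#' Builds the confusion matrix of a positive rule against the truth labels
#' and reports sensitivity, specificity and prevalence as percentages
#' (rounded with [round_percent()], integer percent by default, the
#' precision screening studies print).
#'
#' @param records A list of `subject_record`s.
#' @param target_condition Truth label counted as condition-positive
#'   (default `"unilateral-amblyope"`).
#' @param rule Which abnormal result counts as screen-positive:
#'   `"brightness"` (imbalance only), `"acuity"`, `"color"`, `"any"`
#'   (referred for any reason), or `"none"` (never positive; baseline).
#' @param decimals Decimal places for the reported percentages.
#' @return A `screening_metrics` object with the confusion-matrix counts,
#'   `sensitivity`, `specificity` and `prevalence`.
#' @examples
#' profiles <- simulate_cohort(list(normal = 5, "unilateral-amblyope" = 1))
#' recs <- run_cohort(profiles, screening_config(tests = "brightness"))
#' evaluate_screening(recs, rule = "brightness")
#' @export
evaluate_screening <- function(records,
                               target_condition = "unilateral-amblyope",
                               rule = c("brightness", "acuity", "color",
                                        "any", "none"),
                               decimals = 0) {
  rule <- match.arg(rule)
  stopifnot(length(records) >= 2L)
  truth <- vapply(records, function(r) r$truth_label == target_condition,
                  logical(1))
  if (!any(truth)) {
    stop("no subject carries the target condition; sensitivity undefined",
         call. = FALSE)
  }
  if (all(truth)) {
    stop("every subject carries the target condition; specificity undefined",
         call. = FALSE)
  }
  positive <- vapply(records, function(r) {
    switch(rule,
      brightness = !is.null(r$brightness) &&
        r$brightness$label == "imbalanced",
      acuity = any(startsWith(r$referral_reasons, "acuity")),
      color = "monocular-colour-defect" %in% r$referral_reasons,
      any = isTRUE(r$referred),
      none = FALSE
    )
  }, logical(1))
  tp <- sum(positive & truth)
  fp <- sum(positive & !truth)
  tn <- sum(!positive & !truth)
  fn <- sum(!positive & truth)
  structure(
    list(
      true_positives = tp, false_positives = fp,
      true_negatives = tn, false_negatives = fn,
      sensitivity = round_percent(tp, tp + fn, decimals),
      specificity = round_percent(tn, tn + fp, decimals),
      prevalence = round_percent(sum(truth), length(truth), decimals),
      n = length(records),
      target_condition = target_condition,
      rule = rule
    ),
    class = "screening_metrics"
  )
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("<screening of %d subjects for %s, rule '%s'>\n", x$n,
              x$target_condition, x$rule))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$true_positives,
              x$false_positives, x$true_negatives, x$false_negatives))
  cat(sprintf("  sensitivity %g%%, specificity %g%%, prevalence %g%%\n",
              x$sensitivity, x$specificity, x$prevalence))
  invisible(x)
}
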