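#' Start a tumbling-E acuity run
#'
#' One run presents same/different pairs of equally sized tumbling Es at the
#' current chart line. Three correct responses advance to the next smaller
#' line; the first incorrect response at a line opens a second chance of up
#' to three fresh pairs at that size, and any further incorrect response
#' ends the run there.
#'
#' @param start_size Snellen denominator of the starting line (must be on
#'   the ladder; typically 60).
#' @param ladder A [chart_ladder()].
#' @return An `acuity_run` state.
#' @seealso [acuity_step()], [run_acuity_test()]
#' @export
acuity_start <- function(start_size = 60, ladder = chart_ladder()) {
  idx <- which(abs(unclass(ladder) - start_size) < 1e-9)
  if (length(idx) != 1L) stop("start_size must be a ladder line", call. = FALSE)
  structure(
    list(
      ladder = ladder,
      idx = idx,
      size = unclass(ladder)[idx],
      n_correct = 0L,
      second_chance = FALSE,
      second_remaining = 0L,
      t_size = numeric(0),
      t_match = logical(0),
      t_response = logical(0),
      t_correct = logical(0),
      completed = numeric(0),
      ended = FALSE,
      end_size = NA_real_
    ),
    class = "acuity_run"
  )
}

#' Advance an acuity run by one presented pair
#'
#' @param state An `acuity_run` from [acuity_start()].
#' @param pair_is_match Whether the presented E pair truly matches (drawn
#'   before the response).
#' @param response_yes The subject's YES/NO response (`TRUE` = "same").
#' @return The updated state; `ended` becomes `TRUE` when the run
#'   terminates, with `completed` holding every line passed (3 correct).
#' @export
acuity_step <- function(state, pair_is_match, response_yes) {
  stopifnot(inherits(state, "acuity_run"),
            is.logical(pair_is_match), is.logical(response_yes))
  if (state$ended) stop("acuity run already ended", call. = FALSE)
  correct <- pair_is_match == response_yes
  state$t_size <- c(state$t_size, state$size)
  state$t_match <- c(state$t_match, pair_is_match)
  state$t_response <- c(state$t_response, response_yes)
  state$t_correct <- c(state$t_correct, correct)
  if (state$second_chance) {
    state$second_remaining <- state$second_remaining - 1L
  }
  if (correct) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= 3L) {
      state$completed <- c(state$completed, state$size)
      if (state$idx == length(state$ladder)) {
        state$ended <- TRUE
        state$end_size <- state$size
      } else {
        state$idx <- state$idx + 1L
        state$size <- unclass(state$ladder)[state$idx]
        state$n_correct <- 0L
        state$second_chance <- FALSE
        state$second_remaining <- 0L
      }
    } else if (state$second_chance && state$second_remaining <= 0L) {
      # defensive: second chance exhausted without reaching three correct
      state$ended <- TRUE
      state$end_size <- state$size
    }
  } else if (!state$second_chance) {
    state$second_chance <- TRUE
    state$second_remaining <- 3L
  } else {
    state$ended <- TRUE
    state$end_size <- state$size
  }
  state
}

acuity_trials_df <- function(state, pinhole = FALSE, pass = 1L) {
  if (length(state$t_size) == 0L) {
    return(data.frame(pass = integer(0), size = numeric(0),
                      pair_is_match = logical(0), response_yes = logical(0),
                      correct = logical(0), pinhole = logical(0)))
  }
  data.frame(
    pass = rep(as.integer(pass), length(state$t_size)),
    size = state$t_size,
    pair_is_match = state$t_match,
    response_yes = state$t_response,
    correct = state$t_correct,
    pinhole = rep(isTRUE(pinhole), length(state$t_size))
  )
}

#' Run a full single-eye acuity test
#'
#' Drives [acuity_step()] with an observer's responses, with match/mismatch
#' pairs drawn 50/50 from the seeded generator. If the run from `start_size`
#' terminates without completing any line, the test restarts once from the
#' largest line (20/400) and results pool. The recorded acuity is the
#' smallest line with three correct responses across the session; failing to
#' complete the largest line yields a below-floor record ("less than
#' 20/400").
#'
#' @param observer An [observer_profile()].
#' @param eye `"OD"` or `"OS"`.
#' @param start_size Starting Snellen line (default 60).
#' @param pinhole Test through the pinhole disc?
#' @param ladder A [chart_ladder()].
#' @param seed Integer seed, or `NULL` for the current RNG state.
#' @return An `acuity_test` object: `acuity` (a [visual_acuity()]),
#'   `trials` (data.frame), `restarted`.
#' @examples
#' run_acuity_test(observer_amblyope(neural = 0.3), "OS", seed = 1)$acuity
#' @export
run_acuity_test <- function(observer, eye, start_size = 60, pinhole = FALSE,
                            ladder = chart_ladder(), seed = NULL) {
  stopifnot(inherits(observer, "observer_profile"))
  check_eye(eye)
  res <- run_seeded(seed, function() {
    run_pass <- function(size0) {
      st <- acuity_start(size0, ladder)
      while (!st$ended) {
        m <- stats::runif(1) < 0.5
        r <- acuity_choice(observer, eye, st$size, pinhole, m)
        st <- acuity_step(st, m, r)
      }
      st
    }
    st1 <- run_pass(start_size)
    trials <- acuity_trials_df(st1, pinhole, pass = 1L)
    completed <- st1$completed
    restarted <- FALSE
    floor_size <- unclass(ladder)[1]
    if (length(completed) == 0L && abs(start_size - floor_size) > 1e-9) {
      restarted <- TRUE
      st2 <- run_pass(floor_size)
      trials <- rbind(trials, acuity_trials_df(st2, pinhole, pass = 2L))
      rownames(trials) <- NULL
      completed <- c(completed, st2$completed)
    }
    list(completed = completed, trials = trials, restarted = restarted)
  })
  acuity <- if (length(res$completed) == 0L) {
    visual_acuity(unclass(ladder)[1], below_floor = TRUE)
  } else {
    visual_acuity(min(res$completed))
  }
  structure(
    list(acuity = acuity, trials = res$trials, restarted = res$restarted),
    class = "acuity_test"
  )
}

#' @export
print.acuity_test <- function(x, ...) {
  cat(sprintf("<acuity test: %s, %d trials%s>\n", format(x$acuity),
              nrow(x$trials), if (x$restarted) ", restarted at floor" else ""))
  invisible(x)
}

#' Per-eye acuity protocol with the pinhole-retest rule
#'
#' Runs the unaided acuity test and, whenever the result is 20/30 or worse
#' (including below-floor), repeats the test through the pinhole disc for
#' that eye. Eyes measuring better than 20/30 unaided are not retested and
#' carry no pinhole field.
#'
#' @inheritParams run_acuity_test
#' @param pinhole_cutoff Snellen denominator at or beyond which the pinhole
#'   retest is administered (default 30, "20/30 or worse").
#' @return An `acuity_outcome`: `eye`, `unaided` ([visual_acuity()]),
#'   `pinhole` ([visual_acuity()] or `NULL`), `pinhole_required`, and the
#'   two underlying test objects in `runs`.
#' @examples
#' out <- run_eye_protocol(observer_refractive(0.3), "OD", seed = 1)
#' out$unaided; out$pinhole
#' @export
run_eye_protocol <- function(observer, eye, start_size = 60,
                             ladder = chart_ladder(), seed = NULL,
                             pinhole_cutoff = 30) {
  unaided_run <- run_acuity_test(observer, eye, start_size, pinhole = FALSE,
                                 ladder = ladder, seed = seed)
  required <- acuity_worse_than(unaided_run$acuity, pinhole_cutoff)
  pinhole_run <- NULL
  if (required) {
    pinhole_run <- run_acuity_test(observer, eye, start_size, pinhole = TRUE,
                                   ladder = ladder,
                                   seed = if (is.null(seed)) NULL else seed + 1L)
  }
  structure(
    list(
      eye = eye,
      unaided = unaided_run$acuity,
      pinhole = if (required) pinhole_run$acuity else NULL,
      pinhole_required = required,
      runs = list(unaided = unaided_run, pinhole = pinhole_run)
    ),
    class = "acuity_outcome"
  )
}

#' @export
print.acuity_outcome <- function(x, ...) {
  cat(sprintf("<%s acuity: unaided %s%s>\n", x$eye, format(x$unaided),
              if (x$pinhole_required) sprintf(", pinhole %s", format(x$pinhole))
              else ""))
  invisible(x)
}

# best measured acuity of an outcome (pinhole when administered)
best_acuity <- function(outcome) {
  stopifnot(inherits(outcome, "acuity_outcome"))
  if (outcome$pinhole_required) outcome$pinhole else outcome$unaided
}
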