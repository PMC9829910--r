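#' Configuration of the brightness-disparity staircase
#'
#' The game presents two rivalrous spaceships whose physical brightness
#' differs by a signed disparity on a fixed log-unit grid (positive =
#' right-eye/bottom spaceship brighter). Each tap moves the disparity one
#' step against the chosen eye; the game ends once the perceived-equality
#' point has been crossed and re-crossed (`required_crossings` response
#' reversals).
#'
#' @param step Grid step in log units (default 0.3).
#' @param max_disparity Largest presentable |disparity| (default 1.8); must
#'   be an integer multiple of `step`.
#' @param start_disparity Signed starting disparity (default +1.8,
#'   right-eye-brighter).
#' @param required_crossings Number of equality crossings that end a game
#'   (default 2, i.e. crossed and re-crossed).
#' @param games_per_subject Number of games per screening session (3).
#' @param games_required_net_zero Zero-endpoint games required for a normal
#'   score (2 of 3).
#' @param balance_rule How "net zero imbalance in two of three games" is
#'   read: `"sign-discordance"` (default; balanced when at least
#'   `games_required_net_zero` endpoints are zero *or* the nonzero endpoints
#'   disagree in sign, the reading consistent with a treated amblyope with
#'   alternating preference scoring normal) or `"net-sum"` (balanced when
#'   the signed endpoints sum to zero).
#' @return A `staircase_config` object.
#' @export
staircase_config <- function(step = 0.3, max_disparity = 1.8,
                             start_disparity = 1.8, required_crossings = 2,
                             games_per_subject = 3,
                             games_required_net_zero = 2,
                             balance_rule = c("sign-discordance", "net-sum")) {
  balance_rule <- match.arg(balance_rule)
  stopifnot(step > 0, max_disparity > 0)
  max_units <- max_disparity / step
  if (abs(max_units - round(max_units)) > 1e-9) {
    stop("max_disparity must be an integer multiple of step", call. = FALSE)
  }
  if (abs(start_disparity) > max_disparity + 1e-9) {
    stop("|start_disparity| must not exceed max_disparity", call. = FALSE)
  }
  if (required_crossings < 2) {
    stop("required_crossings must be >= 2 (cross and re-cross)", call. = FALSE)
  }
  stopifnot(games_per_subject >= 1,
            games_required_net_zero >= 1,
            games_required_net_zero <= games_per_subject)
  structure(
    list(
      step = step,
      max_disparity = max_disparity,
      max_units = as.integer(round(max_units)),
      start_disparity = start_disparity,
      required_crossings = as.integer(required_crossings),
      games_per_subject = as.integer(games_per_subject),
      games_required_net_zero = as.integer(games_required_net_zero),
      balance_rule = balance_rule
    ),
    class = "staircase_config"
  )
}

# trial budget guaranteeing termination under arbitrary response sequences
staircase_trial_budget <- function(config) {
  2L * (2L * config$max_units + 1L) * config$required_crossings
}

#' Start a new staircase game
#'
#' @param config A [staircase_config()].
#' @param start_disparity Signed starting disparity (log units); defaults to
#'   the configured start.
#' @return A `staircase_state`: fields `current_disparity`, `responses`
#'   (vectors of disparities and chosen eyes), `crossings` (midpoints, in
#'   log units, of the disparity pairs at which responses reversed) and
#'   `finished`.
#' @export
new_staircase <- function(config = staircase_config(),
                          start_disparity = config$start_disparity) {
  u0 <- start_disparity / config$step
  if (abs(u0 - round(u0)) > 1e-9) {
    stop("start_disparity must lie on the step grid", call. = FALSE)
  }
  u0 <- as.integer(round(u0))
  if (abs(u0) > config$max_units) {
    stop("start_disparity outside the grid", call. = FALSE)
  }
  structure(
    list(
      config = config,
      unit = u0,                 # disparity in integer step units
      trial = 0L,
      resp_units = integer(0),   # disparity (units) at each response
      resp_eye = character(0),
      crossing_units = numeric(0),  # midpoint (units) of each reversal pair
      finished = FALSE,
      budget = staircase_trial_budget(config)
    ),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("<staircase: disparity %+.2f, %d trials, %d/%d crossings%s>\n",
              x$unit * x$config$step, x$trial, length(x$crossing_units),
              x$config$required_crossings,
              if (x$finished) ", finished" else ""))
  invisible(x)
}

#' Advance the staircase by one response
#'
#' The subject tapped `chosen_eye`'s spaceship as brighter at the state's
#' current disparity. The disparity then moves one step against that eye's
#' advantage (a right-eye/OD choice decreases it, a left-eye/OS choice
#' increases it), clamped to the grid. A crossing is recorded whenever
#' consecutive responses select opposite eyes — the perceived-equality point
#' lies between those two disparities, and the midpoint is stored. The game
#' finishes after `required_crossings` crossings, or when the trial budget
#' is exhausted.
#'
#' @param state A `staircase_state` from [new_staircase()].
#' @param chosen_eye `"OD"` or `"OS"`.
#' @return The updated state.
#' @export
staircase_step <- function(state, chosen_eye) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$finished) stop("staircase game already finished", call. = FALSE)
  check_eye(chosen_eye)
  cfg <- state$config
  u <- state$unit
  n <- length(state$resp_eye)
  state$trial <- state$trial + 1L
  state$resp_units <- c(state$resp_units, u)
  state$resp_eye <- c(state$resp_eye, chosen_eye)
  if (n > 0L && state$resp_eye[n] != chosen_eye) {
    state$crossing_units <- c(state$crossing_units,
                              (state$resp_units[n] + u) / 2)
  }
  # move against the chosen eye's advantage
  u <- u + if (chosen_eye == "OD") -1L else 1L
  state$unit <- max(-cfg$max_units, min(cfg$max_units, u))
  if (length(state$crossing_units) >= cfg$required_crossings ||
      state$trial >= state$budget) {
    state$finished <- TRUE
  }
  state
}

# snap a value in step units to the integer grid, ties toward zero
snap_units <- function(u) {
  lo <- floor(u)
  hi <- ceiling(u)
  if (abs(u - lo) < abs(hi - u) - 1e-9) return(lo)
  if (abs(hi - u) < abs(u - lo) - 1e-9) return(hi)
  if (abs(lo) <= abs(hi)) lo else hi
}

#' Play one brightness-disparity game
#'
#' Drives [staircase_step()] with an observer's [brightness_choice()]s until
#' the game finishes, then scores the endpoint: the mean of the crossing
#' midpoints, snapped to the step grid (ties toward zero) and reported with
#' the left-eye-deficit sign convention — a positive endpoint is the
#' right-eye brightness advantage at perceived equality, i.e. an "OS
#' disparity" of that many log units. A noiseless observer with grid-valued
#' interocular attenuation recovers it exactly, from any start level.
#'
#' If the observer never reverses, the game stops at the trial budget with
#' the endpoint clamped to the grid extreme and `ceiling = TRUE`.
#'
#' @param observer An [observer_profile()].
#' @param config A [staircase_config()].
#' @param seed Integer seed scoping all randomness of the game, or `NULL`
#'   to use the current RNG state (noiseless observers are deterministic
#'   either way).
#' @param start_disparity Signed starting disparity (log units).
#' @param game_index 1-based index of the game within the session; selects
#'   the entry of the observer's `preference_cycle`, if any.
#' @return A `brightness_game` object: `endpoint` (log units, OS-deficit
#'   positive), `trials`, `crossings`, `trace` (data.frame of disparity and
#'   chosen eye per trial), `ceiling`, `start_disparity`.
#' @examples
#' run_brightness_game(observer_amblyope(delta = 0.3))$endpoint  # 0.3
#' @export
run_brightness_game <- function(observer, config = staircase_config(),
                                seed = NULL,
                                start_disparity = config$start_disparity,
                                game_index = 1L) {
  stopifnot(inherits(observer, "observer_profile"))
  bias <- 0
  if (!is.null(observer$preference_cycle)) {
    k <- ((game_index - 1L) %% length(observer$preference_cycle)) + 1L
    bias <- observer$preference_cycle[k]
  }
  state <- run_seeded(seed, function() {
    st <- new_staircase(config, start_disparity)
    last <- NULL
    while (!st$finished) {
      eye <- brightness_choice(observer, st$unit * config$step,
                               bias = bias, last_eye = last)
      st <- staircase_step(st, eye)
      last <- eye
    }
    st
  })
  n_cross <- length(state$crossing_units)
  ceiling_flag <- n_cross < config$required_crossings
  endpoint_units <- if (ceiling_flag) {
    # trial budget exhausted before the required crossings: the staircase is
    # pinned at (or oscillating against) a grid extreme; report the clamp
    -state$unit
  } else {
    -snap_units(mean(state$crossing_units))
  }
  structure(
    list(
      endpoint = endpoint_units * config$step + 0,  # + 0 normalises -0
      trials = state$trial,
      crossings = state$crossing_units * config$step,
      trace = data.frame(
        trial = seq_along(state$resp_units),
        disparity = state$resp_units * config$step,
        chosen_eye = state$resp_eye,
        stringsAsFactors = FALSE
      ),
      ceiling = ceiling_flag,
      start_disparity = start_disparity
    ),
    class = "brightness_game"
  )
}

#' @export
print.brightness_game <- function(x, ...) {
  cat(sprintf("<brightness game: endpoint %+.2f log units (%s), %d trials%s>\n",
              x$endpoint,
              if (abs(x$endpoint) < 1e-9) "balanced"
              else if (x$endpoint > 0) "OS deficit" else "OD deficit",
              x$trials, if (x$ceiling) ", ceiling" else ""))
  invisible(x)
}

#' Classify a subject's three-game brightness result
#'
#' A subject scores `"balanced"` (normal) when at least
#' `games_required_net_zero` games end at a zero endpoint, or — under the
#' default `"sign-discordance"` rule — when the nonzero endpoints disagree
#' in sign (alternating ocular preference, as seen in treated amblyopes).
#' Otherwise the score is `"imbalanced"` and `net_imbalance` is the
#' largest-magnitude endpoint among the concordant nonzero games.
#'
#' @param results A list of `brightness_game` objects (or a numeric vector
#'   of endpoints) of length `games_per_subject`.
#' @param config A [staircase_config()].
#' @return A `brightness_classification`: `endpoints`, `label`
#'   (`"balanced"`/`"imbalanced"`), `net_imbalance` (log units, OS-deficit
#'   positive; 0 when balanced).
#' @examples
#' classify_brightness(c(0.3, 0.3, 0.3))$label   # "imbalanced"
#' classify_brightness(c(0.3, -0.3, 0))$label    # "balanced"
#' @export
classify_brightness <- function(results, config = staircase_config()) {
  endpoints <- if (is.numeric(results)) {
    as.numeric(results)
  } else {
    vapply(results, function(r) {
      stopifnot(inherits(r, "brightness_game"))
      r$endpoint
    }, numeric(1))
  }
  if (length(endpoints) != config$games_per_subject) {
    stop(sprintf("expected %d game results, got %d",
                 config$games_per_subject, length(endpoints)), call. = FALSE)
  }
  tol <- 1e-9
  zero <- abs(endpoints) < tol
  nonzero <- endpoints[!zero]
  balanced <- if (config$balance_rule == "net-sum") {
    abs(sum(endpoints)) < tol
  } else {
    sum(zero) >= config$games_required_net_zero ||
      (any(nonzero > 0) && any(nonzero < 0))
  }
  net <- 0
  if (!balanced && length(nonzero) > 0) {
    major_sign <- sign(sum(sign(nonzero)))
    if (major_sign == 0) major_sign <- sign(nonzero[which.max(abs(nonzero))])
    same <- nonzero[sign(nonzero) == major_sign]
    net <- same[which.max(abs(same))]
  }
  structure(
    list(
      endpoints = endpoints,
      label = if (balanced) "balanced" else "imbalanced",
      net_imbalance = net,
      rule = config$balance_rule
    ),
    class = "brightness_classification"
  )
}

#' @export
print.brightness_classification <- function(x, ...) {
  cat(sprintf("<brightness: %s; endpoints %s; net %+.2f log units>\n",
              x$label, paste(sprintf("%+.1f", x$endpoints), collapse = ", "),
              x$net_imbalance))
  invisible(x)
}
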