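#' Simulated observer profiles
#'
#' An `observer_profile` is the generative model of one simulated subject.
#' It answers all three screening protocols:
#'
#' * **Brightness**: each eye's percept is attenuated additively in
#'   log-luminance by `brightness_attenuation` (log units, >= 0). The signed
#'   interocular deficit is `attenuation[OS] - attenuation[OD]`; a positive
#'   value means the left eye perceives dimmer, the pattern of unilateral
#'   left amblyopia.
#' * **Acuity**: each eye's threshold splits into `neural_logmar` (not
#'   correctable by a pinhole; amblyopic loss) plus `refractive_logmar`
#'   (optical blur, removed by the pinhole). The effective threshold is
#'   `neural + refractive` unaided and `neural` through the pinhole.
#' * **Colour**: `color_axis` per eye (`"none"`, `"red-green"`, `"tritan"`);
#'   the observer misses shape plates on its defect axis with probability
#'   `color_miss_prob` and answers all other plates correctly.
#'
#' `decision_noise` is the logistic scale (log units) of brightness choices;
#' 0 means noiseless/deterministic. `acuity_guess_rate` is the probability of
#' answering a sub-threshold acuity trial correctly (0 = always wrong,
#' deterministic; 0.5 = two-alternative chance performance).
#' `preference_cycle` models alternating ocular preference in treated
#' amblyopes: a vector of per-game offsets (log units, OS-deficit sign)
#' added to the interocular deficit, cycled over the three games.
#'
#' @param brightness_attenuation,neural_logmar,refractive_logmar Per-eye
#'   non-negative values; either a single number (both eyes) or a named
#'   vector `c(OD = ..., OS = ...)`.
#' @param color_axis Per-eye axis; single string or named character vector.
#' @param decision_noise Non-negative logistic scale for brightness choices.
#' @param acuity_guess_rate Probability in `[0, 1]` of a correct response on
#'   sub-threshold acuity trials.
#' @param color_miss_prob Probability in `[0, 1]` of missing a shape plate on
#'   the defect axis.
#' @param fails_demonstration If `TRUE` the observer cannot complete the
#'   colour demonstration plates (does not qualify).
#' @param preference_cycle Optional numeric vector of per-game brightness
#'   offsets (log units), or `NULL`.
#' @param label Archetype label used as the truth label in screening
#'   evaluation.
#' @return An `observer_profile` object.
#' @seealso [observer_normal()], [observer_amblyope()],
#'   [observer_refractive()], [observer_treated_amblyope()],
#'   [observer_color_defect()]
#' @export
observer_profile <- function(brightness_attenuation = c(OD = 0, OS = 0),
                             neural_logmar = c(OD = 0, OS = 0),
                             refractive_logmar = c(OD = 0, OS = 0),
                             color_axis = c(OD = "none", OS = "none"),
                             decision_noise = 0,
                             acuity_guess_rate = 0,
                             color_miss_prob = 1,
                             fails_demonstration = FALSE,
                             preference_cycle = NULL,
                             label = "normal") {
  att <- as_per_eye(brightness_attenuation)
  neu <- as_per_eye(neural_logmar)
  ref <- as_per_eye(refractive_logmar)
  axis <- as_per_eye_chr(color_axis)
  if (any(att < 0) || any(ref < 0)) {
    stop("attenuations and refractive components must be >= 0", call. = FALSE)
  }
  if (!all(axis %in% c("none", "red-green", "tritan"))) {
    stop("color_axis must be 'none', 'red-green' or 'tritan'", call. = FALSE)
  }
  stopifnot(decision_noise >= 0, acuity_guess_rate >= 0, acuity_guess_rate <= 1,
            color_miss_prob >= 0, color_miss_prob <= 1)
  if (!is.null(preference_cycle)) stopifnot(is.numeric(preference_cycle))
  structure(
    list(
      brightness_attenuation = att,
      neural_logmar = neu,
      refractive_logmar = ref,
      color_axis = axis,
      decision_noise = as.numeric(decision_noise),
      acuity_guess_rate = as.numeric(acuity_guess_rate),
      color_miss_prob = as.numeric(color_miss_prob),
      fails_demonstration = isTRUE(fails_demonstration),
      preference_cycle = preference_cycle,
      label = as.character(label)
    ),
    class = "observer_profile"
  )
}

as_per_eye <- function(x) {
  if (length(x) == 1L && is.null(names(x))) x <- c(OD = x, OS = x)
  if (!all(c("OD", "OS") %in% names(x))) {
    stop("per-eye values need names OD and OS", call. = FALSE)
  }
  as.numeric(x[c("OD", "OS")]) -> v
  names(v) <- c("OD", "OS")
  v
}

as_per_eye_chr <- function(x) {
  if (length(x) == 1L && is.null(names(x))) x <- c(OD = x, OS = x)
  if (!all(c("OD", "OS") %in% names(x))) {
    stop("per-eye values need names OD and OS", call. = FALSE)
  }
  v <- as.character(x[c("OD", "OS")])
  names(v) <- c("OD", "OS")
  v
}

check_eye <- function(eye) {
  if (!is.character(eye) || length(eye) != 1L || !eye %in% c("OD", "OS")) {
    stop("eye must be 'OD' (right) or 'OS' (left)", call. = FALSE)
  }
  eye
}

other_eye <- function(eye) if (eye == "OD") "OS" else "OD"

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf("<observer_profile: %s>\n", x$label))
  cat(sprintf("  brightness attenuation (log units): OD %.2f, OS %.2f\n",
              x$brightness_attenuation["OD"], x$brightness_attenuation["OS"]))
  cat(sprintf("  acuity threshold (logMAR, neural + refractive): OD %.2f + %.2f, OS %.2f + %.2f\n",
              x$neural_logmar["OD"], x$refractive_logmar["OD"],
              x$neural_logmar["OS"], x$refractive_logmar["OS"]))
  cat(sprintf("  colour axis: OD %s, OS %s; decision noise %.3g\n",
              x$color_axis["OD"], x$color_axis["OS"], x$decision_noise))
  invisible(x)
}

# ---- archetypes -----------------------------------------------------------

#' Observer archetypes
#'
#' Convenience constructors for the subject types the screening study
#' distinguishes.
#'
#' * `observer_normal()`: balanced brightness, 20/20 thresholds, normal
#'   colour vision.
#' * `observer_amblyope()`: unilateral amblyopia of the left eye by default —
#'   interocular brightness attenuation `delta` (log units), a neural
#'   (pinhole-resistant) acuity loss, and optionally an acquired tritan
#'   defect in the amblyopic eye.
#' * `observer_refractive()`: purely optical blur; acuity normalises through
#'   the pinhole and brightness is balanced.
#' * `observer_treated_amblyope()`: successfully treated amblyope with
#'   normal acuity and alternating ocular preference across games
#'   (endpoint pattern 0.3 OS / 0.3 OD / 0.0).
#' * `observer_color_defect()`: bilateral identical (hereditary) colour
#'   defect, otherwise normal.
#'
#' @param delta Interocular brightness attenuation of the affected eye
#'   (log units).
#' @param neural Neural (pinhole-resistant) acuity loss of the affected eye
#'   (logMAR).
#' @param eye Affected eye, `"OS"` (default) or `"OD"`.
#' @param color_axis Acquired colour-defect axis of the amblyopic eye
#'   (`"none"` to disable).
#' @param refractive Refractive blur (logMAR), both eyes.
#' @param axis Hereditary defect axis for `observer_color_defect()`.
#' @param cycle Per-game preference offsets for the treated amblyope.
#' @param decision_noise,acuity_guess_rate Passed to [observer_profile()].
#' @return An [observer_profile()].
#' @name archetypes
NULL

#' @rdname archetypes
#' @export
observer_normal <- function(decision_noise = 0, acuity_guess_rate = 0) {
  observer_profile(decision_noise = decision_noise,
                   acuity_guess_rate = acuity_guess_rate, label = "normal")
}

#' @rdname archetypes
#' @export
observer_amblyope <- function(delta = 0.6, neural = 0.3, eye = "OS",
                              color_axis = "tritan",
                              decision_noise = 0, acuity_guess_rate = 0) {
  check_eye(eye)
  att <- c(OD = 0, OS = 0); att[eye] <- delta
  neu <- c(OD = 0, OS = 0); neu[eye] <- neural
  ax <- c(OD = "none", OS = "none"); ax[eye] <- color_axis
  observer_profile(
    brightness_attenuation = att, neural_logmar = neu, color_axis = ax,
    decision_noise = decision_noise, acuity_guess_rate = acuity_guess_rate,
    label = "unilateral-amblyope"
  )
}

#' @rdname archetypes
#' @export
observer_refractive <- function(refractive = 0.3, decision_noise = 0,
                                acuity_guess_rate = 0) {
  observer_profile(refractive_logmar = c(OD = refractive, OS = refractive),
                   decision_noise = decision_noise,
                   acuity_guess_rate = acuity_guess_rate,
                   label = "refractive")
}

#' @rdname archetypes
#' @export
observer_treated_amblyope <- function(cycle = c(0.3, -0.3, 0),
                                      decision_noise = 0,
                                      acuity_guess_rate = 0) {
  observer_profile(preference_cycle = cycle, decision_noise = decision_noise,
                   acuity_guess_rate = acuity_guess_rate,
                   label = "treated-amblyope")
}

#' @rdname archetypes
#' @export
observer_color_defect <- function(axis = "red-green", decision_noise = 0,
                                  acuity_guess_rate = 0) {
  observer_profile(color_axis = c(OD = axis, OS = axis),
                   decision_noise = decision_noise,
                   acuity_guess_rate = acuity_guess_rate,
                   label = "color-defect")
}

# ---- response models ------------------------------------------------------

#' Brightness choice of a simulated observer
#'
#' Given a physical disparity (log units, positive = right-eye/bottom
#' spaceship brighter), the perceived right-minus-left difference is
#' `disparity + (attenuation[OS] - attenuation[OD]) + bias`. A noiseless
#' observer taps the eye whose spaceship is perceived brighter and, at exact
#' perceived equality, repeats its previous choice (perceptual hysteresis;
#' right/OD when there is no history). With `decision_noise > 0` the right
#' eye is chosen with probability `plogis(perceived / decision_noise)`,
#' consuming the current RNG stream.
#'
#' @param observer An [observer_profile()].
#' @param disparity Physical brightness disparity (log units, signed).
#' @param bias Additional perceived offset (log units, OS-deficit sign);
#'   used for per-game alternating preference.
#' @param last_eye The eye chosen on the previous trial, or `NULL`.
#' @return `"OD"` or `"OS"`.
#' @export
brightness_choice <- function(observer, disparity, bias = 0, last_eye = NULL) {
  stopifnot(inherits(observer, "observer_profile"))
  if (!is.null(last_eye)) check_eye(last_eye)
  att <- observer$brightness_attenuation
  perceived <- disparity + (att["OS"] - att["OD"]) + bias
  names(perceived) <- NULL
  if (observer$decision_noise > 0) {
    p_right <- stats::plogis(perceived / observer$decision_noise)
    return(if (stats::runif(1) < p_right) "OD" else "OS")
  }
  tol <- 1e-9
  if (perceived > tol) "OD"
  else if (perceived < -tol) "OS"
  else (last_eye %||% "OD")
}

#' Acuity response of a simulated observer
#'
#' The observer answers a same/different tumbling-E pair correctly whenever
#' the letter's logMAR is at or above its effective threshold
#' (`neural + refractive`, the refractive part removed when `pinhole` is
#' `TRUE`). Below threshold it answers correctly with probability
#' `acuity_guess_rate` (0 by default, i.e. reliably wrong; 0.5 models
#' two-alternative guessing and consumes the RNG stream).
#'
#' @param observer An [observer_profile()].
#' @param eye `"OD"` or `"OS"`.
#' @param size Snellen denominator of the presented letters.
#' @param pinhole Is the trial viewed through the pinhole?
#' @param pair_is_match Whether the presented pair truly matches.
#' @return The YES/NO response as a logical (`TRUE` = "same").
#' @export
acuity_choice <- function(observer, eye, size, pinhole, pair_is_match) {
  stopifnot(inherits(observer, "observer_profile"))
  check_eye(eye)
  thr <- observer$neural_logmar[eye] +
    if (pinhole) 0 else observer$refractive_logmar[eye]
  correct <- snellen_to_logmar(size) >= thr - 1e-9
  if (!correct && observer$acuity_guess_rate > 0) {
    correct <- stats::runif(1) < observer$acuity_guess_rate
  }
  if (correct) pair_is_match else !pair_is_match
}

#' Colour-plate response of a simulated observer
#'
#' Demonstration plates are always answered correctly unless the profile has
#' `fails_demonstration`. On test plates the observer errs (reports
#' "no-shape") only on shape plates whose axis matches the eye's configured
#' defect axis, with probability `color_miss_prob` (RNG consumed when the
#' probability is strictly between 0 and 1).
#'
#' @param observer An [observer_profile()].
#' @param eye `"OD"` or `"OS"`.
#' @param plate One row of a plate set (see [hrr_plates()]): a list or
#'   one-row data.frame with fields `kind`, `target`, `axis`.
#' @return The response, `"shape"` or `"no-shape"`.
#' @export
color_choice <- function(observer, eye, plate) {
  stopifnot(inherits(observer, "observer_profile"))
  check_eye(eye)
  kind <- as.character(plate$kind)
  target <- as.character(plate$target)
  if (kind == "demonstration") {
    if (observer$fails_demonstration) {
      return(if (target == "shape") "no-shape" else "shape")
    }
    return(target)
  }
  if (target == "shape" && as.character(plate$axis) == observer$color_axis[eye]) {
    miss <- if (observer$color_miss_prob >= 1) TRUE
            else if (observer$color_miss_prob <= 0) FALSE
            else stats::runif(1) < observer$color_miss_prob
    if (miss) return("no-shape")
  }
  target
}

# ---- JSON (de)serialisation ----------------------------------------------

#' Read observer profiles from a JSON archetype library
#'
#' The package ships a library of the subject types the screening study
#' distinguishes (`system.file("extdata", "archetypes.json", package =
#' "rivalscreen")`); any file with the same structure can be read.
#'
#' @param path Path to an archetype JSON file; defaults to the packaged
#'   library.
#' @return A named list of [observer_profile()]s, keyed by label.
#' @export
load_archetypes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "archetypes.json",
                                package = "rivalscreen", mustWork = TRUE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- doc$archetypes %||% doc
  profiles <- lapply(entries, observer_from_list)
  names(profiles) <- vapply(profiles, function(p) p$label, "")
  profiles
}

#' @rdname load_archetypes
#' @param l A list with `observer_profile` fields (per-eye values as named
#'   lists).
#' @export
observer_from_list <- function(l) {
  per_eye <- function(x, default) {
    if (is.null(x)) return(default)
    v <- c(OD = x$OD %||% x[["OD"]], OS = x$OS %||% x[["OS"]])
    unlist(v)
  }
  observer_profile(
    brightness_attenuation = per_eye(l$brightness_attenuation, c(OD = 0, OS = 0)),
    neural_logmar = per_eye(l$neural_logmar, c(OD = 0, OS = 0)),
    refractive_logmar = per_eye(l$refractive_logmar, c(OD = 0, OS = 0)),
    color_axis = if (is.null(l$color_axis)) c(OD = "none", OS = "none")
      else c(OD = l$color_axis$OD, OS = l$color_axis$OS),
    decision_noise = l$decision_noise %||% 0,
    acuity_guess_rate = l$acuity_guess_rate %||% 0,
    color_miss_prob = l$color_miss_prob %||% 1,
    fails_demonstration = isTRUE(l$fails_demonstration),
    preference_cycle = if (is.null(l$preference_cycle)) NULL
      else as.numeric(unlist(l$preference_cycle)),
    label = l$label %||% "normal"
  )
}
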