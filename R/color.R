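#' The packaged AO-HRR-style plate set
#'
#' A digital stand-in for the Hardy-Rand-Rittler plate book, shipped as a
#' plain JSON fixture: demonstration plates (which every subject must answer
#' correctly to qualify) followed by test plates carrying a colour axis —
#' red-green (protan/deutan) or tritan (blue-yellow). The default set has 4
#' demonstration plates (3 with a shape, 1 blank) and 20 test plates (14
#' red-green, 6 tritan), the typical structure of the AO-HRR book; the real
#' plate artwork is out of scope and the counts are configurable through
#' [make_plate_set()].
#'
#' @return A data.frame with columns `plate_id`, `kind`
#'   (`"demonstration"`/`"test"`), `target` (`"shape"`/`"no-shape"`), `axis`
#'   (`"none"`/`"red-green"`/`"tritan"`).
#' @export
hrr_plates <- function() {
  path <- system.file("extdata", "hrr_plates.json", package = "rivalscreen",
                      mustWork = TRUE)
  df <- jsonlite::fromJSON(path)
  validate_plates(df)
}

#' Build a synthetic plate set
#'
#' @param n_demonstration Demonstration plates (the last one is blank when
#'   `n_demonstration > 1`).
#' @param n_red_green,n_tritan Test plates per axis.
#' @return A plate data.frame as in [hrr_plates()].
#' @export
make_plate_set <- function(n_demonstration = 4, n_red_green = 14,
                           n_tritan = 6) {
  stopifnot(n_demonstration >= 1, n_red_green + n_tritan >= 1)
  demo_target <- rep("shape", n_demonstration)
  if (n_demonstration > 1) demo_target[n_demonstration] <- "no-shape"
  df <- data.frame(
    plate_id = c(sprintf("D%02d", seq_len(n_demonstration)),
                 sprintf("T%02d", seq_len(n_red_green + n_tritan))),
    kind = c(rep("demonstration", n_demonstration),
             rep("test", n_red_green + n_tritan)),
    target = c(demo_target, rep("shape", n_red_green + n_tritan)),
    axis = c(rep("none", n_demonstration),
             rep("red-green", n_red_green), rep("tritan", n_tritan)),
    stringsAsFactors = FALSE
  )
  validate_plates(df)
}

validate_plates <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("plate_id", "kind", "target", "axis") %in% names(df)))
  if (!all(df$kind %in% c("demonstration", "test")) ||
      !all(df$target %in% c("shape", "no-shape")) ||
      !all(df$axis %in% c("none", "red-green", "tritan"))) {
    stop("malformed plate set", call. = FALSE)
  }
  if (any(df$kind == "demonstration" & df$axis != "none")) {
    stop("demonstration plates must carry no axis", call. = FALSE)
  }
  if (sum(df$kind == "demonstration") < 1 || sum(df$kind == "test") < 1) {
    stop("plate set needs at least one demonstration and one test plate",
         call. = FALSE)
  }
  df
}

axis_label <- function(axis) {
  switch(axis, "red-green" = "red-green", "tritan" = "blue-yellow",
         stop("no label for axis ", axis, call. = FALSE))
}

#' Run the colour-vision test for one eye
#'
#' Demonstration plates are presented first, in book order; any error there
#' disqualifies the eye (`qualified = FALSE`, no test plates shown,
#' label `"unclassified"`). Otherwise the test plates are presented in a
#' seeded pseudo-random order and errors tallied per colour axis. An axis
#' with at least `defect_threshold` errors marks a defect; the label is the
#' axis with the most errors (`"red-green"` or `"blue-yellow"`), `"normal"`
#' when no axis reaches threshold, and `"unclassified"` on an exact tie
#' between axes at threshold.
#'
#' @param observer An [observer_profile()].
#' @param eye `"OD"` or `"OS"`.
#' @param plates A plate set (see [hrr_plates()]).
#' @param seed Integer seed for the plate shuffle (and any stochastic
#'   misses), or `NULL`.
#' @param defect_threshold Errors on one axis that mark a defect (default 2).
#' @return A `color_eye_result`: `eye`, `qualified`, `errors_by_axis`
#'   (named counts), `label`, `responses` (per-plate data.frame).
#' @examples
#' run_color_test(observer_color_defect("tritan"), "OS",
#'                plates = make_plate_set(), seed = 1)$label
#' @export
run_color_test <- function(observer, eye, plates = hrr_plates(), seed = NULL,
                           defect_threshold = 2) {
  stopifnot(inherits(observer, "observer_profile"))
  check_eye(eye)
  plates <- validate_plates(plates)
  demo <- plates[plates$kind == "demonstration", , drop = FALSE]
  test <- plates[plates$kind == "test", , drop = FALSE]
  res <- run_seeded(seed, function() {
    order_test <- sample.int(nrow(test))
    shown <- demo
    responses <- character(nrow(demo))
    for (i in seq_len(nrow(demo))) {
      responses[i] <- color_choice(observer, eye, demo[i, ])
    }
    qualified <- all(responses == demo$target)
    if (qualified) {
      test_shown <- test[order_test, , drop = FALSE]
      test_resp <- character(nrow(test_shown))
      for (i in seq_len(nrow(test_shown))) {
        test_resp[i] <- color_choice(observer, eye, test_shown[i, ])
      }
      shown <- rbind(shown, test_shown)
      responses <- c(responses, test_resp)
    }
    list(shown = shown, responses = responses, qualified = qualified)
  })
  shown <- res$shown
  rownames(shown) <- NULL
  shown$response <- res$responses
  shown$correct <- shown$response == shown$target
  errors <- c("red-green" = 0L, "tritan" = 0L)
  if (res$qualified) {
    for (ax in names(errors)) {
      errors[ax] <- sum(!shown$correct & shown$axis == ax)
    }
  }
  label <- if (!res$qualified) {
    "unclassified"
  } else {
    over <- errors[errors >= defect_threshold]
    if (length(over) == 0L) "normal"
    else if (length(over) == 1L || errors["red-green"] != errors["tritan"]) {
      axis_label(names(errors)[which.max(errors)])
    } else "unclassified"
  }
  structure(
    list(eye = eye, qualified = res$qualified, errors_by_axis = errors,
         label = label, responses = shown, defect_threshold = defect_threshold),
    class = "color_eye_result"
  )
}

#' @export
print.color_eye_result <- function(x, ...) {
  cat(sprintf("<%s colour vision: %s%s (errors: red-green %d, tritan %d)>\n",
              x$eye, x$label,
              if (!x$qualified) " (failed demonstration plates)" else "",
              x$errors_by_axis["red-green"], x$errors_by_axis["tritan"]))
  invisible(x)
}

#' Classify a subject's two-eye colour result
#'
#' Bilateral identical defects suggest a hereditary (congenital) origin; a
#' defect in only one eye suggests an acquired/ocular cause (in the study,
#' the amblyopic eye's blue-yellow defect).
#'
#' @param od,os `color_eye_result`s for the right and left eye.
#' @return A `color_classification`: `od`, `os`, `category` (`"normal"`,
#'   `"bilateral-identical"` = hereditary, `"monocular"` = acquired, or
#'   `"bilateral-discordant"` for two differing defects), and
#'   `affected_eye` (for monocular defects).
#' @examples
#' # classify_color(run_color_test(...), run_color_test(...))
#' @export
classify_color <- function(od, os) {
  stopifnot(inherits(od, "color_eye_result"), inherits(os, "color_eye_result"))
  if (od$eye != "OD" || os$eye != "OS") {
    stop("classify_color expects the OD result first, then OS", call. = FALSE)
  }
  if (!od$qualified || !os$qualified) {
    stop("eye failed the demonstration plates; retest before classifying",
         call. = FALSE)
  }
  d_od <- od$label != "normal"
  d_os <- os$label != "normal"
  category <- if (!d_od && !d_os) "normal"
  else if (d_od && d_os) {
    if (od$label == os$label) "bilateral-identical" else "bilateral-discordant"
  } else "monocular"
  affected <- if (category == "monocular") {
    if (d_od) "OD" else "OS"
  } else NA_character_
  structure(
    list(od = od, os = os, category = category, affected_eye = affected),
    class = "color_classification"
  )
}

#' @export
print.color_classification <- function(x, ...) {
  cat(sprintf("<colour classification: %s (OD %s, OS %s)%s>\n", x$category,
              x$od$label, x$os$label,
              if (!is.na(x$affected_eye)) paste0(", affected ", x$affected_eye)
              else ""))
  invisible(x)
}
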