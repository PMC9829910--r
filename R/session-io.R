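SESSION_SCHEMA_VERSION <- "1"

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

rows_to_df <- function(rows, template) {
  if (length(rows) == 0L) return(template)
  cols <- lapply(names(template), function(nm) {
    v <- vapply(rows, function(r) r[[nm]], template[[nm]][0][NA])
    v
  })
  names(cols) <- names(template)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

va_to_list <- function(va) {
  if (is.null(va)) return(NULL)
  list(denominator = va$denominator, logmar = va$logmar,
       below_floor = va$below_floor)
}

va_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  visual_acuity(l$denominator, isTRUE(l$below_floor))
}

#' Serialise a subject record to a plain list
#'
#' The list maps one-to-one onto the session JSON schema (see
#' [write_session()]); [session_from_list()] inverts it.
#'
#' @param record A `subject_record`.
#' @return A nested list of scalars, arrays and row lists.
#' @export
session_to_list <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  brightness <- NULL
  if (!is.null(record$brightness)) {
    b <- record$brightness
    brightness <- list(
      label = b$label,
      net_imbalance = b$net_imbalance,
      rule = b$rule,
      endpoints = as.list(b$endpoints),
      games = lapply(b$games, function(g) list(
        endpoint = g$endpoint,
        trials = g$trials,
        ceiling = g$ceiling,
        start_disparity = g$start_disparity,
        crossings = as.list(g$crossings),
        trace = df_to_rows(g$trace)
      ))
    )
  }
  acuity <- NULL
  if (!is.null(record$acuity)) {
    out_to_list <- function(o) list(
      eye = o$eye,
      pinhole_required = o$pinhole_required,
      unaided = va_to_list(o$unaided),
      pinhole = va_to_list(o$pinhole),
      runs = list(
        unaided = list(restarted = o$runs$unaided$restarted,
                       trials = df_to_rows(o$runs$unaided$trials)),
        pinhole = if (is.null(o$runs$pinhole)) NULL else
          list(restarted = o$runs$pinhole$restarted,
               trials = df_to_rows(o$runs$pinhole$trials))
      )
    )
    acuity <- list(OD = out_to_list(record$acuity$OD),
                   OS = out_to_list(record$acuity$OS))
  }
  color <- NULL
  if (!is.null(record$color)) {
    eye_to_list <- function(e) list(
      eye = e$eye,
      qualified = e$qualified,
      errors_by_axis = as.list(e$errors_by_axis),
      label = e$label,
      defect_threshold = e$defect_threshold,
      responses = df_to_rows(e$responses)
    )
    color <- list(
      od = eye_to_list(record$color$od),
      os = eye_to_list(record$color$os),
      category = if (is.null(record$color$classification)) NULL
        else record$color$classification$category,
      affected_eye = if (is.null(record$color$classification) ||
                         is.na(record$color$classification$affected_eye)) NULL
        else record$color$classification$affected_eye
    )
  }
  list(
    schema_version = SESSION_SCHEMA_VERSION,
    subject_id = record$subject_id,
    truth_label = record$truth_label,
    seed = record$seed,
    referred = record$referred,
    referral_reasons = as.list(record$referral_reasons),
    brightness = brightness,
    acuity = acuity,
    color = color
  )
}

#' Rebuild a subject record from its session list
#'
#' @param l A list as produced by [session_to_list()] or read back from a
#'   session JSON file.
#' @return A `subject_record`.
#' @export
session_from_list <- function(l) {
  if (!identical(as.character(l$schema_version), SESSION_SCHEMA_VERSION)) {
    stop(sprintf("unsupported session schema version '%s' (expected '%s')",
                 l$schema_version, SESSION_SCHEMA_VERSION), call. = FALSE)
  }
  trace_template <- data.frame(trial = integer(0), disparity = numeric(0),
                               chosen_eye = character(0),
                               stringsAsFactors = FALSE)
  acuity_template <- data.frame(pass = integer(0), size = numeric(0),
                                pair_is_match = logical(0),
                                response_yes = logical(0),
                                correct = logical(0), pinhole = logical(0))
  color_template <- data.frame(plate_id = character(0), kind = character(0),
                               target = character(0), axis = character(0),
                               response = character(0), correct = logical(0),
                               stringsAsFactors = FALSE)
  brightness <- NULL
  if (!is.null(l$brightness)) {
    b <- l$brightness
    games <- lapply(b$games, function(g) {
      structure(list(
        endpoint = as.numeric(g$endpoint),
        trials = as.integer(g$trials),
        crossings = as.numeric(unlist(g$crossings)),
        trace = rows_to_df(g$trace, trace_template),
        ceiling = isTRUE(g$ceiling),
        start_disparity = as.numeric(g$start_disparity)
      ), class = "brightness_game")
    })
    brightness <- structure(list(
      endpoints = as.numeric(unlist(b$endpoints)),
      label = b$label,
      net_imbalance = as.numeric(b$net_imbalance),
      rule = b$rule,
      games = games
    ), class = "brightness_classification")
  }
  acuity <- NULL
  if (!is.null(l$acuity)) {
    out_from_list <- function(o) {
      runs <- list(
        unaided = structure(list(
          acuity = va_from_list(o$unaided),
          trials = rows_to_df(o$runs$unaided$trials, acuity_template),
          restarted = isTRUE(o$runs$unaided$restarted)
        ), class = "acuity_test"),
        pinhole = if (is.null(o$runs$pinhole)) NULL else structure(list(
          acuity = va_from_list(o$pinhole),
          trials = rows_to_df(o$runs$pinhole$trials, acuity_template),
          restarted = isTRUE(o$runs$pinhole$restarted)
        ), class = "acuity_test")
      )
      structure(list(
        eye = o$eye,
        unaided = va_from_list(o$unaided),
        pinhole = va_from_list(o$pinhole),
        pinhole_required = isTRUE(o$pinhole_required),
        runs = runs
      ), class = "acuity_outcome")
    }
    acuity <- list(OD = out_from_list(l$acuity$OD),
                   OS = out_from_list(l$acuity$OS))
  }
  color <- NULL
  if (!is.null(l$color)) {
    eye_from_list <- function(e) {
      errs <- vapply(e$errors_by_axis, as.integer, integer(1))
      structure(list(
        eye = e$eye, qualified = isTRUE(e$qualified),
        errors_by_axis = errs, label = e$label,
        responses = rows_to_df(e$responses, color_template),
        defect_threshold = as.numeric(e$defect_threshold)
      ), class = "color_eye_result")
    }
    od <- eye_from_list(l$color$od)
    os <- eye_from_list(l$color$os)
    classification <- NULL
    if (!is.null(l$color$category)) {
      classification <- structure(list(
        od = od, os = os, category = l$color$category,
        affected_eye = l$color$affected_eye %||% NA_character_
      ), class = "color_classification")
    }
    color <- list(od = od, os = os, classification = classification)
  }
  structure(list(
    subject_id = l$subject_id,
    truth_label = l$truth_label,
    brightness = brightness,
    acuity = acuity,
    color = color,
    referred = isTRUE(l$referred),
    referral_reasons = as.character(unlist(l$referral_reasons)),
    seed = as.integer(l$seed)
  ), class = "subject_record")
}

#' Write a screening session to a JSON file
#'
#' Sessions are written in a canonical form (fixed key order, 10 significant
#' digits) so that write -> read -> write is byte-identical, which makes
#' session files diffable and cacheable. The schema version is embedded and
#' checked on read.
#'
#' @param record A `subject_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(record, path) {
  l <- session_to_list(record)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a screening session from a JSON file
#'
#' @param path A file written by [write_session()].
#' @return A `subject_record`.
#' @export
read_session <- function(path) {
  l <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  session_from_list(l)
}
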