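#' Time-activity curves
#'
#' A time-activity curve (TAC) holds one mean count-rate value per frame of a
#' [frame_schedule()], in counts per second per pixel (a rate, so frames of
#' different duration are directly comparable). The `roi_role` records what
#' the curve represents: a heart ROI, a mediastinal ROI, the tissue curve
#' (heart minus fitted mediastinum; may be negative), or a plasma input
#' function.
#'
#' @param schedule a [frame_schedule()]
#' @param values numeric vector, one value per frame (cps/pixel)
#' @param roi_role one of `"heart"`, `"mediastinum"`, `"tissue"`,
#'   `"plasma_input"`
#' @param decay_corrected logical flag; `TRUE` if physical decay has already
#'   been removed
#' @return an object of class `tac`
#' @export
tac <- function(schedule, values,
                roi_role = c("heart", "mediastinum", "tissue", "plasma_input"),
                decay_corrected = TRUE) {
  roi_role <- match.arg(roi_role)
  if (!inherits(schedule, "frame_schedule")) stop("schedule must be a frame_schedule")
  if (length(values) != nrow(schedule)) {
    stop("length(values) must equal the number of frames (",
         length(values), " vs ", nrow(schedule), ")")
  }
  if (any(!is.finite(values))) stop("TAC values must be finite")
  if (roi_role %in% c("mediastinum", "plasma_input") && any(values < 0)) {
    stop(roi_role, " curves must be non-negative")
  }
  structure(list(schedule = schedule, values = as.numeric(values),
                 roi_role = roi_role,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac:%s> %d frames, range [%.4g, %.4g] cps/pixel, decay_corrected=%s\n",
              x$roi_role, nrow(x$schedule), min(x$values), max(x$values),
              x$decay_corrected))
  invisible(x)
}

#' Decay correction of a measured TAC
#'
#' Removes physical decay by multiplying each frame value by
#' `2^(t_mid / half_life)` with `t_mid` the frame midpoint. The inverse
#' operation, [apply_decay()], imposes decay on a decay-free curve (used by
#' the simulator and in round-trip tests).
#'
#' @param x a [tac()] with `decay_corrected = FALSE`
#' @param half_life_min physical half-life in minutes (default iodine-123,
#'   [I123_HALF_LIFE_MIN])
#' @return the corrected [tac()] with `decay_corrected = TRUE`
#' @export
decay_correct <- function(x, half_life_min = I123_HALF_LIFE_MIN) {
  stopifnot(inherits(x, "tac"))
  if (half_life_min <= 0) stop("half_life_min must be positive")
  if (x$decay_corrected) stop("TAC is already decay-corrected")
  f <- 2^(frame_mid_min(x$schedule) / half_life_min)
  tac(x$schedule, x$values * f, x$roi_role, decay_corrected = TRUE)
}

#' @rdname decay_correct
#' @export
apply_decay <- function(x, half_life_min = I123_HALF_LIFE_MIN) {
  stopifnot(inherits(x, "tac"))
  if (half_life_min <= 0) stop("half_life_min must be positive")
  if (!x$decay_corrected) stop("TAC already carries physical decay")
  f <- 2^(-frame_mid_min(x$schedule) / half_life_min)
  tac(x$schedule, x$values * f, x$roi_role, decay_corrected = FALSE)
}

#' Read and write TAC tables
#'
#' The TAC CSV dialect has one row per frame and columns `patient_id, roi,
#' frame_index, start_s, duration_s, value_cps_per_pixel, decay_corrected`.
#' `read_tac_table()` returns a named list of [tac()] objects (names
#' `"<patient_id>.<roi>"`); curves of one patient share a schedule. Values
#' are written at full precision so that a write/read cycle is lossless.
#'
#' @param path file path
#' @return for `read_tac_table`, a named list of [tac()] objects with a
#'   `patient_id` attribute on each element
#' @export
read_tac_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "roi", "frame_index", "start_s", "duration_s",
            "value_cps_per_pixel", "decay_corrected")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad_role <- which(!df$roi %in% c("heart", "mediastinum", "tissue", "plasma_input"))
  if (length(bad_role)) {
    stop("unrecognised or missing roi at rows ",
         paste(utils::head(bad_role, 5), collapse = ", "))
  }
  out <- list()
  for (pid in unique(df$patient_id)) {
    for (roi in unique(df$roi[df$patient_id == pid])) {
      rows <- which(df$patient_id == pid & df$roi == roi)
      sub <- df[rows, ][order(df$frame_index[rows]), ]
      sched <- tryCatch(
        frame_schedule(sub$start_s, sub$duration_s),
        error = function(e) {
          stop("invalid schedule for patient ", pid, " roi ", roi,
               " (file rows ", paste(utils::head(rows, 5), collapse = ", "),
               "): ", conditionMessage(e))
        })
      cur <- tac(sched, sub$value_cps_per_pixel, roi,
                 decay_corrected = all(as.logical(sub$decay_corrected)))
      attr(cur, "patient_id") <- pid
      out[[paste(pid, roi, sep = ".")]] <- cur
    }
  }
  out
}

#' @param curves named list of [tac()] objects; names or `patient_id`
#'   attributes supply patient ids
#' @param patient_ids optional character vector overriding patient ids,
#'   recycled over `curves`
#' @rdname read_tac_table
#' @export
write_tac_table <- function(curves, path, patient_ids = NULL) {
  if (inherits(curves, "tac")) curves <- list(curves)
  rows <- lapply(seq_along(curves), function(i) {
    cur <- curves[[i]]
    stopifnot(inherits(cur, "tac"))
    pid <- if (!is.null(patient_ids)) {
      patient_ids[[(i - 1L) %% length(patient_ids) + 1L]]
    } else {
      attr(cur, "patient_id") %||% sub("\\.[^.]*$", "", names(curves)[i] %||% paste0("p", i))
    }
    data.frame(patient_id = pid, roi = cur$roi_role,
               frame_index = seq_len(nrow(cur$schedule)),
               start_s = cur$schedule$start_s,
               duration_s = cur$schedule$duration_s,
               value_cps_per_pixel = cur$values,
               decay_corrected = cur$decay_corrected)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
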