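#' Build a dynamic PET frame schedule
#'
#' A frame schedule is the ordered sequence of acquisition frames of a
#' dynamic scan. Frames are contiguous (each starts where the previous one
#' ends) and the first frame starts at 0 s.
#'
#' @param spec list of `c(count, duration_s)` pairs, e.g.
#'   `list(c(8, 15), c(3, 60))` for eight 15 s frames followed by three
#'   60 s frames.
#'
#' @return A `frame_schedule`: a data frame with columns `start_s` and
#'   `duration_s`, one row per frame.
#'
#' @examples
#' sched <- make_schedule(list(c(1, 30), c(4, 60), c(3, 120), c(3, 180), c(15, 300)))
#' nrow(sched)          # 26 frames
#' sum(sched$duration_s) / 60
#' @export
make_schedule <- function(spec) {
  if (!is.list(spec) || length(spec) == 0L)
    stop("invalid schedule specification: need a non-empty list of (count, duration_s) pairs")
  durs <- unlist(lapply(spec, function(p) {
    if (length(p) != 2L || !is.numeric(p))
      stop("invalid schedule specification: each element must be c(count, duration_s)")
    count <- p[[1]]; dur <- p[[2]]
    if (is.na(count) || count < 1 || count != round(count))
      stop("invalid schedule specification: counts must be positive integers")
    if (is.na(dur) || dur <= 0)
      stop("invalid schedule specification: durations must be > 0")
    rep(dur, count)
  }))
  new_frame_schedule(durs)
}

new_frame_schedule <- function(durations_s) {
  start_s <- cumsum(c(0, durations_s[-length(durations_s)]))
  structure(
    data.frame(start_s = start_s, duration_s = durations_s),
    class = c("frame_schedule", "data.frame")
  )
}

#' Named frame-schedule presets
#'
#' Two presets are shipped, matching the two acquisition protocols the
#' cohort simulator emulates: `"study1_26f"` (30 s background frame, 4 x
#' 60 s, 3 x 120 s, 3 x 180 s, 15 x 300 s; 26 frames, 94.5 min) and
#' `"study2_32f"` (8 x 15 s, 3 x 60 s, 5 x 120 s, 16 x 300 s; 32 frames,
#' 95 min).
#'
#' @param name preset name, one of `"study1_26f"`, `"study2_32f"`.
#' @return A [make_schedule()] `frame_schedule`.
#' @export
schedule_preset <- function(name = c("study1_26f", "study2_32f")) {
  name <- match.arg(name)
  spec <- switch(name,
    study1_26f = list(c(1, 30), c(4, 60), c(3, 120), c(3, 180), c(15, 300)),
    study2_32f = list(c(8, 15), c(3, 60), c(5, 120), c(16, 300))
  )
  make_schedule(spec)
}

validate_schedule <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) {
    if (is.data.frame(schedule) &&
        all(c("start_s", "duration_s") %in% names(schedule))) {
      schedule <- structure(schedule[c("start_s", "duration_s")],
                            class = c("frame_schedule", "data.frame"))
    } else {
      stop("not a frame schedule")
    }
  }
  if (nrow(schedule) == 0L) stop("schedule has no frames")
  if (any(schedule$duration_s <= 0)) stop("schedule durations must be > 0")
  if (schedule$start_s[1] < 0) stop("first frame must start at or after 0")
  ends <- schedule$start_s + schedule$duration_s
  if (nrow(schedule) > 1L &&
      any(abs(schedule$start_s[-1] - ends[-nrow(schedule)]) > 1e-9))
    stop("schedule frames must be contiguous and non-overlapping")
  schedule
}

#' Frame timing helpers
#'
#' @param schedule a `frame_schedule`.
#' @return `frame_mid_min()` the frame mid-times, `frame_end_min()` the
#'   frame end times, both in minutes.
#' @export
frame_mid_min <- function(schedule) {
  schedule <- validate_schedule(schedule)
  (schedule$start_s + schedule$duration_s / 2) / 60
}

#' @rdname frame_mid_min
#' @export
frame_end_min <- function(schedule) {
  schedule <- validate_schedule(schedule)
  (schedule$start_s + schedule$duration_s) / 60
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.6g min total\n",
              nrow(x), sum(x$duration_s) / 60))
  rle_d <- rle(x$duration_s)
  cat("  ", paste(sprintf("%d x %gs", rle_d$lengths, rle_d$values),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a frame-schedule specification from YAML
#'
#' The YAML file holds a list of `{count, duration_s}` mappings (see
#' `inst/extdata/schedules.yaml` for the two shipped presets).
#'
#' @param path YAML file path.
#' @param name optional top-level key naming one schedule among several.
#' @return A `frame_schedule`.
#' @export
read_schedule_yaml <- function(path, name = NULL) {
  obj <- yaml::read_yaml(path)
  if (!is.null(name)) {
    if (is.null(obj[[name]])) stop("no schedule named '", name, "' in ", path)
    obj <- obj[[name]]
  }
  make_schedule(lapply(obj, function(e) c(e$count, e$duration_s)))
}
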