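#' Read and write time-activity curve CSV files
#'
#' The TAC file format: one region per file, comma-separated, '.' decimal,
#' UTF-8, required header `frame_start_s, frame_duration_s,
#' activity_kbq_ml`. Times are stored in seconds on disk and converted to
#' minutes only inside computations. Frame contiguity is enforced on load.
#'
#' @param path file path.
#' @param region_label region name; defaults to the file name without
#'   extension.
#' @return [read_tac_csv()] returns a [new_tac()]; [write_tac_csv()]
#'   returns `path` invisibly.
#' @export
read_tac_csv <- function(path, region_label = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_duration_s", "activity_kbq_ml")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (col in need) {
    if (!is.numeric(df[[col]]))
      stop("format error in ", path, ": column ", col, " is not numeric")
  }
  sched <- tryCatch(
    validate_schedule(data.frame(start_s = df$frame_start_s,
                                 duration_s = df$frame_duration_s)),
    error = function(e) stop("format error in ", path, ": ", conditionMessage(e))
  )
  if (is.null(region_label))
    region_label <- sub("\\.[^.]*$", "", basename(path))
  new_tac(sched, df$activity_kbq_ml, region_label)
}

#' @param tac a [new_tac()] object.
#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(tac, path) {
  stopifnot(inherits(tac, "tac"))
  utils::write.csv(
    data.frame(frame_start_s = tac$schedule$start_s,
               frame_duration_s = tac$schedule$duration_s,
               activity_kbq_ml = tac$activity),
    path, row.names = FALSE)
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' Columns: `subject_id`, `arm` (`test_retest` or `challenge`),
#' `dose_label`, `ki_scan1`, `ki_scan2`, `ki_true_scan1` (may be NA for
#' real data), `interval_days`. Duplicate subject ids, unknown arm labels
#' and non-positive Ki values are rejected.
#'
#' @param path file path.
#' @return [read_cohort_csv()] returns a validated data frame;
#'   [write_cohort_csv()] returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "dose_label", "ki_scan1", "ki_scan2",
            "ki_true_scan1", "interval_days")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("format error in ", path, ": duplicate subject_id ",
         df$subject_id[duplicated(df$subject_id)][1])
  bad_arm <- setdiff(unique(df$arm), c("test_retest", "challenge"))
  if (length(bad_arm))
    stop("format error in ", path, ": unknown arm label '", bad_arm[1], "'")
  for (col in c("ki_scan1", "ki_scan2")) {
    if (any(!is.finite(df[[col]])) || any(df[[col]] <= 0))
      stop("validation error in ", path, ": ", col, " must be positive")
  }
  df[need]
}

#' @param cohort a cohort data frame.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  need <- c("subject_id", "arm", "dose_label", "ki_scan1", "ki_scan2",
            "ki_true_scan1", "interval_days")
  stopifnot(all(need %in% names(cohort)))
  utils::write.csv(cohort[need], path, row.names = FALSE)
  invisible(path)
}

#' Serialize an analysis or battery report to JSON
#'
#' Reports are plain nested lists of numbers and strings; they round-trip
#' losslessly through JSON (`digits = NA` writes full precision).
#'
#' @param report a report list (e.g. an `rtm_report` or the result of
#'   [run_pipeline()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attributes(x)) && !is.null(names(x))) return(as.list(x))
  unclass(x)
}
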