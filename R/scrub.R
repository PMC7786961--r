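#' Motion scrubbing of ROI time series
#'
#' Censors frames whose framewise displacement exceeds `fd_thresh` (mm) or
#' whose DVARS exceeds `dvars_thresh` (percent), plus an optional block of
#' initial frames. The comparison is strict (`>`): frames sitting exactly at
#' a threshold are kept. Retained frames keep their original temporal order.
#'
#' @param ts a `subject_ts` (see [generate_cohort()]): list with `data`
#'   (frames x nodes), `fd`, `dvars`, `tr_seconds`, `subject_id`.
#' @param fd_thresh FD censoring threshold in mm.
#' @param dvars_thresh DVARS censoring threshold in percent.
#' @param drop_initial number of leading frames to drop unconditionally
#'   (for pipelines starting from raw exports that still contain dummy
#'   volumes; preprocessed series should use the default 0).
#' @return list with `ts` (the scrubbed `subject_ts`) and `mask`
#'   (list `keep` logical per original frame, `n_kept`).
#' @examples
#' ts <- list(subject_id = "s1", data = matrix(rnorm(30), 10, 3),
#'            tr_seconds = 2, fd = rep(0.1, 10), dvars = rep(0.1, 10))
#' class(ts) <- "subject_ts"
#' scrub_frames(ts)$mask$n_kept
#' @export
scrub_frames <- function(ts, fd_thresh = 0.5, dvars_thresh = 0.5,
                         drop_initial = 0L) {
  n <- nrow(ts$data)
  if (length(ts$fd) != n || length(ts$dvars) != n)
    stop_fctopo("fd/dvars length must equal frame count (%d)", n)
  if (fd_thresh <= 0 || dvars_thresh <= 0)
    stop_fctopo("censoring thresholds must be positive")
  if (drop_initial >= n)
    stop_fctopo("drop_initial (%d) must be below the frame count (%d)",
                drop_initial, n)
  keep <- !(seq_len(n) <= drop_initial | ts$fd > fd_thresh |
              ts$dvars > dvars_thresh)
  if (!any(keep))
    stop_fctopo("all frames of subject %s removed by scrubbing",
                ts$subject_id %||% "<unnamed>")
  out <- ts
  out$data <- ts$data[keep, , drop = FALSE]
  out$fd <- ts$fd[keep]
  out$dvars <- ts$dvars[keep]
  list(ts = out, mask = list(keep = keep, n_kept = sum(keep)))
}

#' Minimum-duration inclusion rule
#'
#' A subject is retained for analysis when the scrubbed data still span at
#' least `min_minutes` of acquisition (boundary inclusive).
#'
#' @param mask frame mask from [scrub_frames()] (list with `n_kept`).
#' @param tr_seconds repetition time in seconds.
#' @param min_minutes minimum retained duration in minutes.
#' @return logical: does the subject meet the inclusion rule?
#' @examples
#' check_inclusion(list(n_kept = 120), tr_seconds = 2)  # exactly 4 min: TRUE
#' @export
check_inclusion <- function(mask, tr_seconds, min_minutes = 4) {
  if (tr_seconds <= 0) stop_fctopo("tr_seconds must be positive")
  mask$n_kept * tr_seconds >= min_minutes * 60
}

#' Per-cohort scrubbing and inclusion report
#'
#' @param ts_list list of `subject_ts`.
#' @param fd_thresh,dvars_thresh,drop_initial see [scrub_frames()].
#' @param min_minutes see [check_inclusion()].
#' @return list with `timeseries` (scrubbed list, included subjects only) and
#'   `report` (data.frame: subject_id, n_frames, n_kept, minutes, included).
#' @export
scrub_cohort <- function(ts_list, fd_thresh = 0.5, dvars_thresh = 0.5,
                         drop_initial = 0L, min_minutes = 4) {
  scrubbed <- lapply(ts_list, scrub_frames, fd_thresh = fd_thresh,
                     dvars_thresh = dvars_thresh, drop_initial = drop_initial)
  report <- do.call(rbind, lapply(scrubbed, function(s) data.frame(
    subject_id = s$ts$subject_id,
    n_frames = length(s$mask$keep),
    n_kept = s$mask$n_kept,
    minutes = s$mask$n_kept * s$ts$tr_seconds / 60,
    included = check_inclusion(s$mask, s$ts$tr_seconds, min_minutes),
    stringsAsFactors = FALSE)))
  list(timeseries = lapply(scrubbed[report$included], `[[`, "ts"),
       report = report)
}
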