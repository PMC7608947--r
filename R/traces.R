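# Domain containers: kinematic traces, spike trains, sessions.

#' Kinematic whisker trace
#'
#' Time-regular samples of whisker position (micrometers) and optionally
#' curvature (1/mm) for one whisker under one texture condition. The time
#' base is seconds; sample indices are 0-based and intervals half-open.
#'
#' @param position Numeric vector of position samples (um), finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param whisker A [whisker_id()] or canonical whisker name.
#' @param condition Texture grade label, or a list with `grade` and
#'   `diameter_um` (see [texture_grade()]). May be `NULL` for unlabeled data.
#' @param curvature Optional numeric vector of curvature samples (1/mm), same
#'   length as `position`.
#' @param revolution_period Nominal wheel revolution period in seconds.
#' @param id Optional trace identifier; defaults to `<whisker>_<grade>`.
#' @return An object of class `kinematic_trace`.
#' @export
kinematic_trace <- function(position, sample_rate, whisker, condition = NULL,
                            curvature = NULL, revolution_period = 3,
                            id = NULL) {
  whisker <- whisker_id(whisker)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    wp_abort("sample_rate must be a single positive number")
  position <- as.numeric(position)
  if (length(position) == 0L)
    wp_abort(sprintf("trace for whisker %s has no position samples", whisker$name))
  if (!all(is.finite(position)))
    wp_abort(sprintf("trace for whisker %s contains non-finite position samples",
                     whisker$name))
  if (!is.null(curvature)) {
    curvature <- as.numeric(curvature)
    if (length(curvature) != length(position))
      wp_abort(sprintf(
        "trace for whisker %s: curvature length (%d) does not match position length (%d)",
        whisker$name, length(curvature), length(position)))
    if (!all(is.finite(curvature)))
      wp_abort(sprintf("trace for whisker %s contains non-finite curvature samples",
                       whisker$name))
  }
  cond <- if (is.null(condition)) NULL else texture_grade(condition)
  if (is.null(id))
    id <- paste0(whisker$name, if (!is.null(cond)) paste0("_", cond$grade))
  structure(
    list(position = position, curvature = curvature,
         sample_rate = sample_rate, whisker = whisker, condition = cond,
         revolution_period = revolution_period, id = id),
    class = "kinematic_trace")
}

#' @export
print.kinematic_trace <- function(x, ...) {
  cat(sprintf("<kinematic_trace %s: %s, %.3g s at %g Hz%s%s>\n",
              x$id, x$whisker$name,
              length(x$position) / x$sample_rate, x$sample_rate,
              if (!is.null(x$curvature)) ", +curvature" else "",
              if (!is.null(attr(x, "collision_times")))
                sprintf(", %d edge collisions", length(attr(x, "collision_times")))
              else ""))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A `kinematic_trace`.
#' @export
trace_duration <- function(trace) length(trace$position) / trace$sample_rate

#' Ground-truth edge collision times of a trace
#'
#' Returns the collision times (seconds) attached by [gen_edge_trace()] or
#' restored by [read_session()], or `NULL` for texture-only traces.
#' @param trace A `kinematic_trace`.
#' @export
collision_times <- function(trace) attr(trace, "collision_times")

#' Spike train of a single unit
#'
#' @param times Spike times in seconds, sorted ascending.
#' @param unit_id Unit identifier.
#' @param whisker Principal whisker ([whisker_id()] or name).
#' @param adaptation_class `"RA"`, `"SA"` or `"unknown"`.
#' @param t_max Optional recording span; spike times must lie in `[0, t_max]`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id, whisker,
                        adaptation_class = c("unknown", "RA", "SA"),
                        t_max = NULL) {
  adaptation_class <- match.arg(adaptation_class)
  whisker <- whisker_id(whisker)
  times <- as.numeric(times)
  if (anyNA(times) || (length(times) && !all(is.finite(times))))
    wp_abort(sprintf("unit %s: spike times must be finite", unit_id))
  if (is.unsorted(times))
    wp_abort(sprintf("unit %s: spike times must be nondecreasing", unit_id))
  if (length(times) && times[1L] < 0)
    wp_abort(sprintf("unit %s: negative spike time", unit_id))
  if (!is.null(t_max) && length(times) && times[length(times)] > t_max)
    wp_abort(sprintf("unit %s: spike time %.4f s exceeds recording span %.4f s",
                     unit_id, times[length(times)], t_max))
  structure(list(times = times, unit_id = as.character(unit_id),
                 whisker = whisker, adaptation_class = adaptation_class,
                 t_max = t_max),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s (%s, %s): %d spikes%s>\n",
              x$unit_id, x$whisker$name, x$adaptation_class, length(x$times),
              if (!is.null(x$t_max)) sprintf(" over %.3g s", x$t_max) else ""))
  invisible(x)
}

#' Recording session
#'
#' A bundle of kinematic traces and spike trains, optionally carrying the
#' generator's ground-truth manifest (for synthetic sessions).
#'
#' @param traces List of [kinematic_trace()] objects with unique ids.
#' @param trains List of [spike_train()] objects.
#' @param truth Optional list with elements `manifest` (data.frame) and
#'   `collisions` (data.frame of trace_id, t_s).
#' @return An object of class `whisker_session`.
#' @export
whisker_session <- function(traces = list(), trains = list(), truth = NULL) {
  ids <- vapply(traces, function(tr) tr$id, character(1))
  if (anyDuplicated(ids))
    wp_abort(sprintf("duplicate trace ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(traces) <- ids
  # one physical unit can span several traces (one per texture); keep names
  # unique for indexing
  names(trains) <- make.unique(
    vapply(trains, function(tr) tr$unit_id, character(1)))
  structure(list(traces = traces, trains = trains, truth = truth),
            class = "whisker_session")
}

#' @export
print.whisker_session <- function(x, ...) {
  cat(sprintf("<whisker_session: %d traces, %d spike trains%s>\n",
              length(x$traces), length(x$trains),
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}
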