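# Edge/texture epoch separation, trial segmentation, PSTHs.
#
# Index convention: epochs are half-open [start, end) in 0-based sample
# indices; t_start/t_end give the same bounds in seconds.

#' Detect edge epochs by the excursion criterion
#'
#' Separates a continuous trace into `pre_edge`, `edge` and `texture` epochs.
#' Samples whose smoothed absolute deviation from the trace mean exceeds
#' `k` standard deviations seed edge epochs; crossings closer than
#' `merge_gap` (which spans the resonant ringing) join one epoch; each epoch
#' is extended forward by a fixed `margin` once the envelope has re-entered
#' the band. A `guard` band is excised on both sides of every edge epoch,
#' and a `pre_edge` epoch of fixed duration precedes each edge. Everything
#' else is labeled `texture`. Detection is invariant to constant offsets and
#' equivariant to amplitude scaling.
#'
#' @param trace A [kinematic_trace()] at least 1 s long.
#' @param k Criterion in SD multiples (the mean +- 3 SD rule).
#' @param smooth Envelope moving-average window (s) applied to `|x - mean|`
#'   before thresholding; suppresses sub-window noise peaks while leaving
#'   the long collision excursions intact.
#' @param merge_gap Crossings closer than this (s) belong to one epoch.
#' @param margin Fixed forward extension after the envelope settles (s).
#' @param guard Guard band excised around each edge epoch (s).
#' @param pre_edge Duration of the pre-edge epoch (s).
#' @param robust Use median/MAD instead of mean/SD for the criterion
#'   statistics.
#' @return An `epoch_set`: data.frame with columns `start`, `end` (0-based,
#'   half-open), `t_start`, `t_end`, `label`; detection parameters are
#'   attached as attributes.
#' @export
detect_edge_epochs <- function(trace, k = 3, smooth = 0.005, merge_gap = 0.05,
                               margin = 0.02, guard = 0.05, pre_edge = 0.5,
                               robust = FALSE) {
  fs <- trace$sample_rate
  x <- trace$position
  n <- length(x)
  if (n / fs < 1) wp_abort("edge detection needs a trace of at least 1 s")
  m <- if (robust) stats::median(x) else mean(x)
  s <- if (robust) stats::mad(x) else stats::sd(x)
  params <- list(k = k, smooth = smooth, merge_gap = merge_gap,
                 margin = margin, guard = guard, pre_edge = pre_edge,
                 robust = robust, center = m, scale = s)
  lab <- rep.int("texture", n)
  if (s == 0) {
    warning("zero-variance trace: no edge epochs detected")
    es <- labels_to_epochs(lab, fs)
    return(as_epoch_set(es, trace$id, params))
  }
  env <- moving_average(abs(x - m), max(1L, as.integer(round(smooth * fs))))
  exceed <- which(env > k * s)
  if (length(exceed) == 0L) {
    es <- labels_to_epochs(lab, fs)
    return(as_epoch_set(es, trace$id, params))
  }
  gap_n <- as.integer(round(merge_gap * fs))
  brk <- which(diff(exceed) > gap_n)
  first <- exceed[c(1L, brk + 1L)]
  last <- exceed[c(brk, length(exceed))]
  margin_n <- as.integer(round(margin * fs))
  starts <- first
  ends <- pmin(last + margin_n, n)
  # merge epochs that touch after the margin extension
  if (length(starts) > 1L) {
    keep_s <- starts[1L]; ks <- keep_s; ke <- ends[1L]
    ms <- integer(0); me <- integer(0)
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] <= ke) ke <- max(ke, ends[i])
      else { ms <- c(ms, ks); me <- c(me, ke); ks <- starts[i]; ke <- ends[i] }
    }
    starts <- c(ms, ks); ends <- c(me, ke)
  }
  guard_n <- as.integer(round(guard * fs))
  pre_n <- as.integer(round(pre_edge * fs))
  # paint labels with increasing priority: pre_edge < guard < edge
  for (i in seq_along(starts)) {
    p1 <- max(1L, starts[i] - guard_n - pre_n)
    p2 <- starts[i] - guard_n - 1L
    if (p2 >= p1) lab[p1:p2] <- "pre_edge"
  }
  for (i in seq_along(starts)) {
    g1 <- max(1L, starts[i] - guard_n); g2 <- starts[i] - 1L
    if (g2 >= g1) lab[g1:g2] <- "guard"
    g3 <- ends[i] + 1L; g4 <- min(n, ends[i] + guard_n)
    if (g4 >= g3) lab[g3:g4] <- "guard"
  }
  for (i in seq_along(starts)) lab[starts[i]:ends[i]] <- "edge"
  as_epoch_set(labels_to_epochs(lab, fs), trace$id, params)
}

# Run-length encode a per-sample label vector into half-open 0-based epochs.
labels_to_epochs <- function(lab, fs) {
  r <- rle(lab)
  end1 <- cumsum(r$lengths)          # 1-based inclusive ends
  start0 <- c(0L, end1[-length(end1)])
  data.frame(start = start0, end = end1,
             t_start = start0 / fs, t_end = end1 / fs,
             label = r$values, stringsAsFactors = FALSE)
}

as_epoch_set <- function(df, trace_id, params) {
  structure(df, class = c("epoch_set", "data.frame"),
            trace_id = trace_id, params = params)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set for trace %s: %d edge, %d texture, %d pre_edge epochs>\n",
              attr(x, "trace_id") %||% "?",
              sum(x$label == "edge"), sum(x$label == "texture"),
              sum(x$label == "pre_edge")))
  NextMethod()
}

#' Slice a trace channel by a half-open 0-based epoch
#'
#' @param trace A [kinematic_trace()].
#' @param start,end 0-based half-open sample bounds.
#' @param channel `"position"` or `"curvature"`.
#' @export
epoch_slice <- function(trace, start, end, channel = "position") {
  ch <- trace[[channel]]
  if (is.null(ch)) wp_abort(sprintf("trace %s has no %s channel", trace$id, channel))
  ch[(start + 1L):end]
}

#' Cut texture epochs into fixed trials
#'
#' Tiles non-overlapping contiguous windows within the texture epochs only;
#' partial tail windows are dropped, so trials never overlap an edge, guard
#' or pre-edge sample.
#'
#' @param trace A [kinematic_trace()].
#' @param epochs An `epoch_set` from [detect_edge_epochs()].
#' @param window Trial duration (s), > 0.
#' @return data.frame with columns `trial`, `start`, `end`, `t_start`,
#'   `t_end` (same index conventions as epochs).
#' @export
segment_trials <- function(trace, epochs, window = 0.5) {
  if (window <= 0) wp_abort("trial window must be > 0")
  fs <- trace$sample_rate
  win_n <- as.integer(round(window * fs))
  tex <- epochs[epochs$label == "texture", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tex))) {
    len <- tex$end[i] - tex$start[i]
    k <- len %/% win_n
    if (k < 1L) next
    st <- tex$start[i] + (seq_len(k) - 1L) * win_n
    out[[length(out) + 1L]] <- data.frame(start = st, end = st + win_n)
  }
  if (length(out) == 0L)
    return(data.frame(trial = integer(0), start = integer(0), end = integer(0),
                      t_start = numeric(0), t_end = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  data.frame(trial = seq_len(nrow(df)), start = df$start, end = df$end,
             t_start = df$start / fs, t_end = df$end / fs)
}

#' Peri-stimulus time histogram
#'
#' Per-bin firing probability: the fraction of alignment events with at
#' least one spike in the bin.
#'
#' @param trains A [spike_train()] or list of them.
#' @param align_times Alignment event times (s). For a list of trains,
#'   either one shared vector or a list of per-train vectors; (train, event)
#'   pairs are pooled.
#' @param window Length-2 window around each event (s), half-open.
#' @param bin Bin width (s), default 1 ms.
#' @return A `psth` object: list with `breaks`, `t` (bin left edges), `prob`,
#'   `n_events`, `bin`.
#' @export
build_psth <- function(trains, align_times, window = c(-0.05, 0.15),
                       bin = 0.001) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (is.numeric(align_times)) align_times <- rep(list(align_times),
                                                  length(trains))
  if (length(align_times) != length(trains))
    wp_abort("align_times must match the number of spike trains")
  n_ev_total <- sum(lengths(align_times))
  if (n_ev_total == 0L) wp_abort("at least one alignment event is required")
  nb <- as.integer(round((window[2L] - window[1L]) / bin))
  breaks <- window[1L] + bin * (0:nb)
  hit <- numeric(nb)
  for (j in seq_along(trains)) {
    st <- trains[[j]]$times
    for (t0 in align_times[[j]]) {
      rel <- st[st >= t0 + window[1L] & st < t0 + window[2L]] - t0
      if (length(rel) == 0L) next
      b <- unique(pmin(as.integer(floor((rel - window[1L]) / bin)) + 1L, nb))
      hit[b] <- hit[b] + 1
    }
  }
  structure(list(breaks = breaks, t = breaks[-length(breaks)],
                 prob = hit / n_ev_total, n_events = n_ev_total, bin = bin),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth: %d bins of %g s, %d events, peak probability %.3f>\n",
              length(x$prob), x$bin, x$n_events, max(x$prob)))
  invisible(x)
}

#' Export an epoch set as interval text
#'
#' Writes the 3-column (start, end, label) interval representation, a
#' BED-like plain-text format.
#'
#' @param epochs An `epoch_set`.
#' @param path Output file.
#' @export
write_epochs <- function(epochs, path) {
  data.table::fwrite(as.data.frame(epochs)[, c("start", "end", "label")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
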