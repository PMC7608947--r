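# Per-trial vibration features, windowed firing rates, pad maps.

#' Position standard deviation of a trial
#'
#' Sample SD (n-1 denominator) of the position samples in a trial; the
#' magnitude proxy for stick-slip events.
#'
#' @param x Numeric samples (um), length >= 2.
#' @return SD in um.
#' @export
position_sd <- function(x) {
  if (length(x) < 2L) wp_abort("position_sd needs at least 2 samples")
  stats::sd(x)
}

#' Curvature standard deviation of a trial
#'
#' @param x Curvature samples (1/mm), length >= 2.
#' @return SD in 1/mm.
#' @export
curvature_sd <- function(x) {
  if (length(x) < 2L) wp_abort("curvature_sd needs at least 2 samples")
  stats::sd(x)
}

# Welch PSD: averaged modified periodograms, Hann window, 50% overlap,
# one-sided density such that the integral over frequency recovers the
# signal variance (Parseval).
welch_psd <- function(x, fs, seg_len = 0.256, overlap = 0.5) {
  n <- length(x)
  L <- min(as.integer(round(seg_len * fs)), n)
  if (L < 8L) wp_abort("trial too short for spectral estimation")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- hann(L)
  scale <- fs * sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    P <- (Mod(X)^2) / scale
    # double everything except DC and (for even L) Nyquist
    dbl <- 2:(nf - if (L %% 2L == 0L) 1L else 0L)
    P[dbl] <- 2 * P[dbl]
    acc <- acc + P
  }
  list(freq = (seq_len(nf) - 1L) * fs / L, psd = acc / length(starts))
}

#' Band power of a trial
#'
#' Power spectral density by averaged modified periodograms (Hann window,
#' 50% overlap), integrated over the requested band by the trapezoid rule.
#' For a unit-amplitude in-band sinusoid this returns the signal variance
#' (0.5) up to estimator leakage.
#'
#' @param x Position samples (um).
#' @param sample_rate Sampling rate (Hz).
#' @param band Length-2 band edges (Hz), default 5-250 Hz.
#' @param seg_len Welch segment length (s).
#' @param overlap Segment overlap fraction.
#' @return Band power in um^2.
#' @export
band_power <- function(x, sample_rate, band = c(5, 250), seg_len = 0.256,
                       overlap = 0.5) {
  if (band[2L] >= sample_rate / 2)
    wp_abort("band must lie below the Nyquist frequency")
  if (length(x) / sample_rate < 2 / band[1L])
    wp_abort("trial shorter than twice the low-cut period")
  if (all(x == x[1L])) return(0)
  sp <- welch_psd(x, sample_rate, seg_len, overlap)
  sel <- sp$freq >= band[1L] & sp$freq <= band[2L]
  if (sum(sel) < 2L) wp_abort("band contains fewer than 2 spectral bins")
  trapz(sp$freq[sel], sp$psd[sel])
}

#' Windowed firing rate
#'
#' `Fr = n_spikes / T` over a half-open interval: exact rational arithmetic,
#' no estimator choices.
#'
#' @param spikes A [spike_train()] or numeric spike times (s).
#' @param interval Length-2 interval `[start, end)` in seconds.
#' @param T Window length (s); defaults to the interval duration. The
#'   interval must be at least `T` long; the count is taken over
#'   `[start, start + T)`.
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(spikes, interval, T = NULL) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  dur <- interval[2L] - interval[1L]
  T <- T %||% dur
  if (dur < T - 1e-12)
    wp_abort(sprintf("interval (%.4g s) is shorter than T = %.4g s", dur, T))
  sum(times >= interval[1L] & times < interval[1L] + T) / T
}

# Firing-rate trials for one train: texture rates tile T-windows inside
# texture epochs; edge rates take the first T of each edge epoch (the edge
# response onset).
rate_trials <- function(train, epochs, label = c("texture", "edge"),
                        T = if (match.arg(label) == "texture") 0.05 else 0.01) {
  label <- match.arg(label)
  fs_ep <- epochs[epochs$label == label, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fs_ep))) {
    t0 <- fs_ep$t_start[i]; t1 <- fs_ep$t_end[i]
    if (label == "edge") {
      if (t1 - t0 < T) next
      starts <- t0
    } else {
      k <- floor((t1 - t0) / T)
      if (k < 1L) next
      starts <- t0 + (seq_len(k) - 1L) * T
    }
    out[[length(out) + 1L]] <- starts
  }
  starts <- unlist(out) %||% numeric(0)
  data.frame(trial = seq_along(starts), t_start = starts,
             rate = vapply(starts, function(s)
               firing_rate(train, c(s, s + T)), numeric(1)))
}

#' Edge/texture firing-rate ratio
#'
#' Raw ratio between the mean edge-window rate and the mean texture-window
#' rate of one unit.
#'
#' @param edge_rates Edge-window firing rates (Hz).
#' @param texture_rates Texture-window firing rates (Hz).
#' @return Dimensionless ratio; `NA` (with a warning) when the texture rate
#'   is zero.
#' @export
edge_texture_ratio <- function(edge_rates, texture_rates) {
  mt <- mean(texture_rates)
  if (!is.finite(mt) || mt == 0) {
    warning("zero mean texture rate: edge/texture ratio undefined")
    return(NA_real_)
  }
  mean(edge_rates) / mt
}

#' Normalize ratios (or any positive scores) across a comparison group
#'
#' Divides by the observed maximum; undefined (`NA`) entries are excluded
#' from the reference and propagate as `NA`.
#'
#' @param x Numeric vector.
#' @return `x / max(x, na.rm = TRUE)`.
#' @export
normalize_to_max <- function(x) {
  m <- suppressWarnings(max(x, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) wp_abort("no positive finite value to normalize to")
  x / m
}

#' Build a normalized pad map
#'
#' Per texture, each whisker's mean feature value is divided by the maximum
#' across whiskers; the normalized values are then averaged over textures
#' per whisker and rescaled so the map maximum is exactly 1.
#'
#' @param features Long feature table (columns `whisker`, `arc`, `row`,
#'   `condition`, `feature`, `value`), as built by [compute_features()].
#' @param feature Feature name to map (default `"position_sd"`).
#' @param textures Texture grades to include; default all present.
#' @return A `pad_map` data.frame (`whisker`, `arc`, `row`, `value`) with
#'   `max(value) == 1`.
#' @export
build_pad_map <- function(features, feature = "position_sd", textures = NULL) {
  ft <- features[features$feature == feature, , drop = FALSE]
  if (!is.null(textures)) ft <- ft[ft$condition %in% textures, , drop = FALSE]
  if (nrow(ft) == 0L) wp_abort(sprintf("no '%s' values to map", feature))
  dt <- data.table::as.data.table(ft)
  means <- dt[, list(value = mean(value)), by = c("whisker", "arc", "row", "condition")]
  whiskers <- unique(means[, c("whisker", "arc", "row")])
  conds <- unique(means$condition)
  full <- nrow(means) == nrow(whiskers) * length(conds)
  if (!full)
    warning("missing whisker x texture cells excluded from the pad map")
  means[, norm := value / max(value), by = "condition"]
  map <- means[, list(value = mean(norm)), by = c("whisker", "arc", "row")]
  map[, value := value / max(value)]
  out <- as.data.frame(map[order(map$arc, map$row)])
  class(out) <- c("pad_map", "data.frame")
  out
}

#' Compute the per-trial feature table of a session
#'
#' Runs edge detection and trial segmentation on every trace, then computes
#' vibration features on 500-ms texture trials (position SD, 5-250 Hz band
#' power, curvature SD) and windowed firing rates (texture windows
#' `T_texture`, edge windows `T_edge`) for the spike train recorded on each
#' trace.
#'
#' @param session A [whisker_session()].
#' @param features Which features to compute.
#' @param trial_window Vibration trial duration (s).
#' @param T_texture,T_edge Firing-rate window lengths (s).
#' @param band Band-power edges (Hz).
#' @param k Edge-detection criterion (SD multiples).
#' @param detect_args Extra arguments passed to [detect_edge_epochs()].
#' @param decimate_to Optional target rate (Hz) for anti-aliased decimation
#'   of vibration channels before feature computation.
#' @return Long data.frame: `trace_id`, `whisker`, `arc`, `row`, `condition`,
#'   `diameter_um`, `trial`, `feature`, `value`, `unit_id`.
#' @export
compute_features <- function(session,
                             features = c("position_sd", "band_power",
                                          "curvature_sd",
                                          "firing_rate_texture",
                                          "firing_rate_edge"),
                             trial_window = 0.5, T_texture = 0.05,
                             T_edge = 0.01, band = c(5, 250), k = 3,
                             detect_args = list(), decimate_to = NULL) {
  features <- match.arg(features, several.ok = TRUE)
  trains_by_trace <- list()
  for (st in session$trains) {
    tid <- attr(st, "trace_id")
    if (!is.null(tid)) trains_by_trace[[tid]] <- st
  }
  out <- list()
  emit <- function(tr, trial, feature, value, unit = NA_character_) {
    data.frame(trace_id = tr$id, whisker = tr$whisker$name,
               arc = tr$whisker$arc, row = tr$whisker$row,
               condition = if (is.null(tr$condition)) NA_character_
                           else tr$condition$grade,
               diameter_um = if (is.null(tr$condition)) NA_real_
                             else tr$condition$diameter_um,
               trial = trial, feature = feature, value = value,
               unit_id = unit, stringsAsFactors = FALSE)
  }
  for (tr in session$traces) {
    epochs <- do.call(detect_edge_epochs, c(list(tr, k = k), detect_args))
    tr_an <- tr
    if (!is.null(decimate_to) && decimate_to < tr$sample_rate)
      tr_an <- decimate_trace(tr, decimate_to)
    ep_an <- if (identical(tr_an, tr)) epochs else
      rescale_epochs(epochs, tr$sample_rate, tr_an$sample_rate,
                     length(tr_an$position))
    trials <- segment_trials(tr_an, ep_an, window = trial_window)
    if (nrow(trials) > 0L) {
      if ("position_sd" %in% features) {
        v <- vapply(seq_len(nrow(trials)), function(i)
          position_sd(epoch_slice(tr_an, trials$start[i], trials$end[i])),
          numeric(1))
        out[[length(out) + 1L]] <- emit(tr, trials$trial, "position_sd", v)
      }
      if ("band_power" %in% features) {
        v <- vapply(seq_len(nrow(trials)), function(i)
          band_power(epoch_slice(tr_an, trials$start[i], trials$end[i]),
                     tr_an$sample_rate, band = band), numeric(1))
        out[[length(out) + 1L]] <- emit(tr, trials$trial, "band_power", v)
      }
      if ("curvature_sd" %in% features && !is.null(tr_an$curvature)) {
        v <- vapply(seq_len(nrow(trials)), function(i)
          curvature_sd(epoch_slice(tr_an, trials$start[i], trials$end[i],
                                   "curvature")), numeric(1))
        out[[length(out) + 1L]] <- emit(tr, trials$trial, "curvature_sd", v)
      }
    }
    st <- trains_by_trace[[tr$id]]
    if (!is.null(st)) {
      if ("firing_rate_texture" %in% features) {
        rt <- rate_trials(st, epochs, "texture", T = T_texture)
        if (nrow(rt) > 0L)
          out[[length(out) + 1L]] <- emit(tr, rt$trial, "firing_rate_texture",
                                          rt$rate, st$unit_id)
      }
      if ("firing_rate_edge" %in% features) {
        re <- rate_trials(st, epochs, "edge", T = T_edge)
        if (nrow(re) > 0L)
          out[[length(out) + 1L]] <- emit(tr, re$trial, "firing_rate_edge",
                                          re$rate, st$unit_id)
      }
    }
  }
  if (length(out) == 0L)
    wp_abort("no features could be computed for this session")
  do.call(rbind, out)
}

#' Anti-aliased decimation of a trace
#'
#' Low-pass filters (8th-order Chebyshev via [signal::decimate()]) and
#' downsamples the vibration channels by an integer factor.
#'
#' @param trace A [kinematic_trace()].
#' @param target_rate Target sampling rate (Hz); must divide the current
#'   rate.
#' @return A decimated [kinematic_trace()].
#' @export
decimate_trace <- function(trace, target_rate) {
  q <- trace$sample_rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    wp_abort("target_rate must divide the trace sample rate")
  q <- as.integer(round(q))
  if (q == 1L) return(trace)
  pos <- signal::decimate(trace$position, q)
  curv <- if (!is.null(trace$curvature)) signal::decimate(trace$curvature, q)
  kinematic_trace(pos, target_rate, trace$whisker, condition = trace$condition,
                  curvature = curv, revolution_period = trace$revolution_period,
                  id = trace$id)
}

# Map an epoch set onto a different sampling rate (same time bounds).
rescale_epochs <- function(epochs, fs_old, fs_new, n_new) {
  df <- as.data.frame(epochs)
  df$start <- pmin(as.integer(round(df$start / fs_old * fs_new)), n_new)
  df$end <- pmin(as.integer(round(df$end / fs_old * fs_new)), n_new)
  df <- df[df$end > df$start, , drop = FALSE]
  df$t_start <- df$start / fs_new
  df$t_end <- df$end / fs_new
  as_epoch_set(df, attr(epochs, "trace_id"), attr(epochs, "params"))
}
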