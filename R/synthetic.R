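# Synthetic vibration traces and spike trains with known ground truth.

# Compound-Poisson stick-slip component. Events arrive at slip_rate; each is
# a biphasic excursion (stick phase, fraction p of the event, then a faster
# opposing slip phase scaled so the event integrates to zero).
gen_slip_component <- function(n, fs, a0, model) {
  duration <- n / fs
  n_ev <- stats::rpois(1L, model$slip_rate * duration)
  slip <- numeric(n)
  if (n_ev == 0L || a0 <= 0) return(slip)
  start <- floor(stats::runif(n_ev, 0, n - 1)) + 1L
  dur_s <- stats::runif(n_ev, model$slip_dur_range[1L], model$slip_dur_range[2L])
  len <- pmax(2L, as.integer(round(dur_s * fs)))
  s <- model$slip_jitter_sdlog
  amp <- a0 * stats::rlnorm(n_ev, meanlog = -s^2 / 2, sdlog = s)
  ev <- rep.int(seq_len(n_ev), len)
  off <- sequence(len)
  u <- (off - 0.5) / len[ev]
  p <- model$slip_asym
  r <- p / (1 - p)
  k <- numeric(length(u))
  stick <- u < p
  k[stick] <- sin(pi * u[stick] / p)
  k[!stick] <- -r * sin(pi * (u[!stick] - p) / (1 - p))
  idx <- start[ev] + off - 1L
  keep <- idx <= n
  acc <- data.table::data.table(i = idx[keep], v = amp[ev][keep] * k[keep])
  acc <- acc[, list(v = sum(v)), by = "i"]
  slip[acc$i] <- slip[acc$i] + acc$v
  slip
}

# Band-limited Gaussian baseline noise. The zero-phase low-pass is scaled by
# its theoretical white-noise variance gain (sum of squares of the combined
# forward-backward impulse response), not the empirical trace SD, so traces
# remain independent draws with the stated SD in expectation.
.noise_gain_cache <- new.env(parent = emptyenv())

gen_baseline_noise <- function(n, fs, model) {
  if (model$baseline_noise_sd == 0) return(numeric(n))
  x <- stats::rnorm(n)
  co <- model$baseline_noise_cutoff %||% Inf
  if (is.finite(co) && co < fs / 2) {
    bf <- signal::butter(2, co / (fs / 2), type = "low")
    key <- paste(fs, co)
    gain <- .noise_gain_cache[[key]]
    if (is.null(gain)) {
      h <- signal::filter(bf, c(1, numeric(4095)))
      gain <- sqrt(sum(stats::convolve(h, h, type = "open")^2))
      .noise_gain_cache[[key]] <- gain
    }
    x <- signal::filtfilt(bf, x) / gain
  }
  x * model$baseline_noise_sd
}

gen_curvature <- function(position, fs, model) {
  wc <- min(model$curvature_cutoff / (fs / 2), 0.95)
  bf <- signal::butter(2, wc, type = "low")
  lp <- signal::filtfilt(bf, position)
  lp * model$curvature_gain +
    stats::rnorm(length(position), 0, model$curvature_noise_sd)
}

#' Generate a texture-only vibration trace
#'
#' Position = Gaussian baseline noise + compound stick-slip shot noise with
#' event amplitude proportional to `mean particle diameter x arc gain`;
#' curvature (optional) is a low-pass-filtered, scaled copy of position plus
#' independent noise. The closed-form SD of the process is
#' [texture_trace_sd()].
#'
#' @param grade Texture grade (label or custom list).
#' @param whisker Whisker identity.
#' @param duration Trace duration (s), > 0.
#' @param model A [pad_model()].
#' @param seed Seed (defaults to `model$seed`); `NA` to use the current RNG
#'   stream.
#' @param curvature Generate the curvature channel.
#' @return A [kinematic_trace()]; the slip component is attached as attribute
#'   `"slip_component"` for downstream spike generation.
#' @export
gen_texture_trace <- function(grade, whisker, duration, model = pad_model(),
                              seed = NULL, curvature = TRUE) {
  if (duration <= 0) wp_abort("duration must be > 0")
  w <- whisker_id(whisker)
  if (!as.character(w$arc) %in% names(model$arc_gain))
    wp_abort(sprintf("no arc gain defined for arc %d", w$arc))
  seed <- seed %||% model$seed
  if (!is.null(seed) && is.na(seed)) seed <- NULL
  with_seed_opt(seed, {
    fs <- model$sample_rate
    n <- as.integer(round(duration * fs))
    cond <- texture_grade(grade)
    a0 <- model$slip_amp_per_um * cond$diameter_um *
      model$arc_gain[[as.character(w$arc)]]
    base <- gen_baseline_noise(n, fs, model)
    slip <- gen_slip_component(n, fs, a0, model)
    pos <- base + slip
    curv <- if (curvature) gen_curvature(pos, fs, model) else NULL
    tr <- kinematic_trace(pos, fs, w, condition = cond, curvature = curv,
                          revolution_period = model$revolution_period)
    attr(tr, "slip_component") <- slip
    attr(tr, "texture_sd") <- stats::sd(pos)
    tr
  })
}

#' Generate an edge-bearing vibration trace
#'
#' As [gen_texture_trace()], plus one edge collision per wheel revolution: a
#' half-sine excursion of amplitude `edge_amp_sd_multiple` times the texture
#' SD lasting `edge_pulse_width`, followed by an exponentially damped
#' sinusoidal ring (arc-dependent frequency, envelope time constant
#' `ring_decay_tau`). Ground-truth collision onset times are attached and
#' retrievable with [collision_times()].
#'
#' @inheritParams gen_texture_trace
#' @return A [kinematic_trace()] with attributes `"collision_times"` (s),
#'   `"slip_component"` and `"edge_component"`.
#' @export
gen_edge_trace <- function(grade, whisker, duration, model = pad_model(),
                           seed = NULL, curvature = TRUE) {
  if (duration < model$revolution_period)
    wp_abort("duration must cover at least one wheel revolution")
  seed <- seed %||% model$seed
  if (!is.null(seed) && is.na(seed)) seed <- NULL
  w <- whisker_id(whisker)
  with_seed_opt(seed, {
    base_tr <- gen_texture_trace(grade, w, duration, model, seed = NA,
                                 curvature = FALSE)
    fs <- model$sample_rate
    n <- length(base_tr$position)
    sd_tex <- stats::sd(base_tr$position)
    period <- model$revolution_period
    t_coll <- seq(period / 2, duration - model$edge_pulse_width, by = period)
    amp <- model$edge_amp_sd_multiple * sd_tex
    f_ring <- model$ring_freq[[as.character(w$arc)]] %||% 100
    tau <- model$ring_decay_tau
    edge <- numeric(n)
    wn <- as.integer(round(model$edge_pulse_width * fs))
    rn <- as.integer(round(6 * tau * fs))
    for (tc in t_coll) {
      i0 <- as.integer(round(tc * fs)) + 1L
      ip <- i0:min(i0 + wn - 1L, n)
      edge[ip] <- edge[ip] + amp * sin(pi * (seq_along(ip) - 0.5) / wn)
      ir0 <- i0 + wn
      if (ir0 <= n) {
        ir <- ir0:min(ir0 + rn - 1L, n)
        trel <- (seq_along(ir) - 0.5) / fs
        edge[ir] <- edge[ir] + model$ring_amp_frac * amp *
          exp(-trel / tau) * sin(2 * pi * f_ring * trel)
      }
    }
    pos <- base_tr$position + edge
    curv <- if (curvature) gen_curvature(pos, fs, model) else NULL
    tr <- kinematic_trace(pos, fs, w, condition = base_tr$condition,
                          curvature = curv, revolution_period = period)
    attr(tr, "slip_component") <- attr(base_tr, "slip_component")
    attr(tr, "edge_component") <- edge
    attr(tr, "texture_sd") <- sd_tex
    attr(tr, "collision_times") <- t_coll
    tr
  })
}

#' Generate a spike train driven by a vibration trace
#'
#' Inhomogeneous Bernoulli process on `model$bin` bins with rate
#' `baseline + k_texture * |slip drive| + k_edge * arc_ratio * edge drive`.
#' The texture drive is the per-bin mean absolute slip component (falling
#' back to `|position - mean|` for traces without a stored decomposition);
#' the edge drive is a boxcar of `edge_drive_dur` after each true collision.
#' A hard refractory period is enforced.
#'
#' @param trace A [kinematic_trace()] sampled at >= 1 kHz.
#' @param truth_edges Collision onset times (s); defaults to
#'   [collision_times()] of the trace.
#' @param model A [neuron_model()].
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @param unit_id Unit identifier; defaults to `<whisker>_u1`.
#' @return A [spike_train()] with attribute `"trace_id"`.
#' @export
gen_spike_train <- function(trace, truth_edges = NULL, model = neuron_model(),
                            seed = NULL, unit_id = NULL) {
  if (trace$sample_rate < 1000)
    wp_abort("spike generation needs a trace sampled at >= 1 kHz")
  truth_edges <- truth_edges %||% collision_times(trace) %||% numeric(0)
  with_seed_opt(seed, {
    fs <- trace$sample_rate
    n <- length(trace$position)
    bin <- model$bin
    nb <- as.integer(floor(n / fs / bin))
    drive_src <- attr(trace, "slip_component") %||%
      (trace$position - mean(trace$position))
    bidx <- pmin(as.integer(floor((seq_len(n) - 1L) / fs / bin)) + 1L, nb)
    acc <- data.table::data.table(b = bidx, v = abs(drive_src))
    acc <- acc[, list(v = mean(v)), by = "b"]
    drive_tex <- numeric(nb)
    drive_tex[acc$b] <- acc$v
    drive_edge <- numeric(nb)
    for (tc in truth_edges) {
      b0 <- as.integer(floor(tc / bin)) + 1L
      b1 <- min(as.integer(ceiling((tc + model$edge_drive_dur) / bin)), nb)
      if (b0 <= nb) drive_edge[b0:min(b1, nb)] <- 1
    }
    arc <- trace$whisker$arc
    k_e <- model$k_edge * (model$arc_edge_ratio[[as.character(arc)]] %||% 1)
    rate <- pmax(model$baseline_rate + model$k_texture * drive_tex +
                   k_e * drive_edge, 0)
    p <- pmin(rate * bin, 1)
    fired <- which(stats::runif(nb) < p)
    if (model$refractory > bin && length(fired) > 1L) {
      rbins <- ceiling(model$refractory / bin)
      keep <- logical(length(fired))
      last <- -Inf
      for (i in seq_along(fired)) {
        if (fired[i] - last >= rbins) { keep[i] <- TRUE; last <- fired[i] }
      }
      fired <- fired[keep]
    }
    times <- (fired - 0.5) * bin
    st <- spike_train(times, unit_id %||% paste0(trace$whisker$name, "_u1"),
                      trace$whisker,
                      adaptation_class = model$adaptation_class,
                      t_max = n / fs)
    attr(st, "trace_id") <- trace$id
    st
  })
}

#' Generate a full synthetic session
#'
#' Full factorial of whiskers x texture grades: one edge-bearing (or
#' texture-only) trace per cell plus a spike train from that whisker's unit,
#' with a ground-truth manifest (arc gains, relative edge gains, collision
#' times). The same seed reproduces the session exactly.
#'
#' @param pad A [pad_model()].
#' @param neurons A [neuron_model()], or `NULL` to skip spike generation.
#' @param grades Character vector of texture grades.
#' @param whiskers Character vector of whisker names (one unit per whisker).
#' @param duration Seconds of recording per whisker x grade cell.
#' @param seed Master seed; every trace/train seed derives from it.
#' @param edges Attach the wheel edge (one collision per revolution).
#' @param curvature Generate curvature channels.
#' @return A [whisker_session()] with `truth$manifest` and `truth$collisions`.
#' @examples
#' \donttest{
#' s <- gen_session(pad_model(sample_rate = 2500), duration = 10, seed = 1,
#'                  grades = c("P120", "P1200"), whiskers = c("gamma", "C4"))
#' s
#' }
#' @export
gen_session <- function(pad = pad_model(), neurons = neuron_model(),
                        grades = c("P120", "P220", "P600", "P800", "P1200"),
                        whiskers = c("gamma", "C1", "C2", "C3", "C4"),
                        duration = 120, seed = 1L, edges = TRUE,
                        curvature = TRUE) {
  if (length(grades) == 0L || length(whiskers) == 0L)
    wp_abort("grades and whiskers must be nonempty")
  if (anyDuplicated(grades) || anyDuplicated(whiskers))
    wp_abort("duplicate whisker or condition keys")
  grid <- expand.grid(whisker = whiskers, grade = grades,
                      stringsAsFactors = FALSE)
  traces <- vector("list", nrow(grid))
  trains <- list()
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- whisker_id(grid$whisker[i])
    g <- grid$grade[i]
    s_i <- derive_seed(seed, i)
    tr <- if (edges)
      gen_edge_trace(g, w, duration, pad, seed = s_i, curvature = curvature)
    else
      gen_texture_trace(g, w, duration, pad, seed = s_i, curvature = curvature)
    traces[[i]] <- tr
    if (!is.null(neurons)) {
      st <- gen_spike_train(tr, model = neurons,
                            seed = derive_seed(seed, 100000L + i),
                            unit_id = paste0(w$name, "_u1"))
      trains[[length(trains) + 1L]] <- st
    }
    rows[[i]] <- data.frame(
      trace_id = tr$id, whisker = w$name, row = w$row, arc = w$arc,
      grade = g, diameter_um = tr$condition$diameter_um,
      arc_gain = pad$arc_gain[[as.character(w$arc)]],
      edge_ratio_rel = if (is.null(neurons)) NA_real_
        else neurons$arc_edge_ratio[[as.character(w$arc)]],
      n_collisions = length(collision_times(tr) %||% numeric(0)),
      texture_sd_expected = texture_trace_sd(pad, g, w),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  colls <- do.call(rbind, lapply(traces, function(tr) {
    tc <- collision_times(tr)
    if (is.null(tc)) NULL else data.frame(trace_id = tr$id, t_s = tc)
  }))
  whisker_session(traces, trains,
                  truth = list(manifest = manifest, collisions = colls))
}
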