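# Generative models: pad-level vibration transmission and first-order neurons.

#' Whisker-pad vibration model
#'
#' Parameters of the synthetic texture/edge vibration generator. Texture
#' vibration is a compound stick-slip shot-noise process riding on Gaussian
#' baseline noise: slip events arrive as a Poisson process and each event is
#' a brief biphasic excursion (slow "stick" phase, fast "slip" return) whose
#' amplitude is proportional to the texture's mean particle diameter times an
#' arc-dependent transmission gain. Edge collisions add one long excursion
#' per wheel revolution followed by a damped resonant ring.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param arc_gain Named map arc (0-4) to positive transmission gain; the
#'   default decreases strictly from arc 4 (rostral, gain 1) to arc 0.
#' @param slip_rate Slip-event rate (events/s), the grain passage rate.
#' @param slip_amp_per_um Whisker excursion (um) per um of particle diameter
#'   at gain 1.
#' @param slip_jitter_sdlog Lognormal amplitude jitter (sdlog; mean 1).
#' @param slip_dur_range Range of slip-event durations in seconds.
#' @param slip_asym Fraction of the event spent in the stick phase.
#' @param baseline_noise_sd Gaussian baseline noise SD (um).
#' @param baseline_noise_cutoff Low-pass cutoff of the baseline noise (Hz);
#'   sensor and plant noise is band-limited, which also keeps features
#'   stable under anti-aliased decimation of the trace.
#' @param edge_amp_sd_multiple Edge excursion amplitude as a multiple of the
#'   texture-component SD; must exceed 3 so collisions clear the mean+-3SD
#'   detection criterion.
#' @param edge_pulse_width Collision excursion duration (s).
#' @param ring_amp_frac Initial ringing amplitude as a fraction of the pulse.
#' @param ring_freq Named map arc to ringing frequency (Hz); rostral whiskers
#'   are shorter and ring faster.
#' @param ring_decay_tau Ringing envelope decay time constant (s).
#' @param curvature_gain Curvature per unit position (1/mm per um).
#' @param curvature_cutoff Low-pass cutoff for the curvature channel (Hz).
#' @param curvature_noise_sd Independent curvature noise SD (1/mm).
#' @param revolution_period Wheel revolution period (s).
#' @param seed Default seed for generation.
#' @return An object of class `pad_model`.
#' @export
pad_model <- function(sample_rate = 25000,
                      arc_gain = c(`0` = 0.2, `1` = 0.35, `2` = 0.55,
                                   `3` = 0.75, `4` = 1.0),
                      slip_rate = 1500,
                      slip_amp_per_um = 0.05,
                      slip_jitter_sdlog = 0.3,
                      slip_dur_range = c(0.0015, 0.005),
                      slip_asym = 0.6,
                      baseline_noise_sd = 3,
                      baseline_noise_cutoff = 500,
                      edge_amp_sd_multiple = 6,
                      edge_pulse_width = 0.05,
                      ring_amp_frac = 0.8,
                      ring_freq = c(`0` = 60, `1` = 80, `2` = 100,
                                    `3` = 125, `4` = 150),
                      ring_decay_tau = 0.05,
                      curvature_gain = 0.002,
                      curvature_cutoff = 100,
                      curvature_noise_sd = 0.002,
                      revolution_period = 3,
                      seed = 1L) {
  if (any(arc_gain <= 0)) wp_abort("all arc gains must be > 0")
  if (is.null(names(arc_gain)) || !all(as.character(0:4) %in% names(arc_gain)))
    wp_abort("arc_gain must be named with arcs '0'..'4'")
  if (edge_amp_sd_multiple <= 3)
    wp_abort("edge_amp_sd_multiple must exceed 3 (the detection criterion)")
  if (slip_rate < 0 || slip_amp_per_um < 0 || baseline_noise_sd < 0)
    wp_abort("rates, amplitudes and noise SDs must be nonnegative")
  if (slip_asym <= 0 || slip_asym >= 1)
    wp_abort("slip_asym must lie in (0, 1)")
  structure(
    list(sample_rate = sample_rate, arc_gain = arc_gain, slip_rate = slip_rate,
         slip_amp_per_um = slip_amp_per_um,
         slip_jitter_sdlog = slip_jitter_sdlog,
         slip_dur_range = slip_dur_range, slip_asym = slip_asym,
         baseline_noise_sd = baseline_noise_sd,
         baseline_noise_cutoff = baseline_noise_cutoff,
         edge_amp_sd_multiple = edge_amp_sd_multiple,
         edge_pulse_width = edge_pulse_width, ring_amp_frac = ring_amp_frac,
         ring_freq = ring_freq, ring_decay_tau = ring_decay_tau,
         curvature_gain = curvature_gain, curvature_cutoff = curvature_cutoff,
         curvature_noise_sd = curvature_noise_sd,
         revolution_period = revolution_period, seed = seed),
    class = "pad_model")
}

# Energy of the unit-amplitude biphasic slip kernel over a unit duration:
# sin(pi*u/p) on [0,p] followed by -(p/(1-p))*sin(pi*(u-p)/(1-p)) on [p,1];
# the slip-phase amplitude ratio p/(1-p) makes the event integrate to zero.
slip_kernel_energy <- function(p) {
  r <- p / (1 - p)
  p / 2 + r^2 * (1 - p) / 2
}

#' Closed-form SD of a synthetic texture trace
#'
#' Campbell's theorem for the compound-Poisson slip process plus independent
#' Gaussian baseline noise: `Var = sigma_b^2 + lambda * E[A^2] * E_k * E[L]`
#' where `E_k` is the unit-kernel energy and `L` the event duration. Used as
#' the independent oracle for the Monte-Carlo generator.
#'
#' @param model A [pad_model()].
#' @param grade Texture grade (label or custom list).
#' @param whisker Whisker identity (name or [whisker_id()]).
#' @return Expected position SD in um.
#' @export
texture_trace_sd <- function(model, grade, whisker) {
  w <- whisker_id(whisker)
  g <- model$arc_gain[[as.character(w$arc)]]
  if (is.null(g)) wp_abort(sprintf("no arc gain for arc %d", w$arc))
  cond <- texture_grade(grade)
  a0 <- model$slip_amp_per_um * cond$diameter_um * g
  ej2 <- exp(model$slip_jitter_sdlog^2)   # E[jitter^2], mean-1 lognormal
  el <- mean(model$slip_dur_range)
  v <- model$slip_rate * a0^2 * ej2 * slip_kernel_energy(model$slip_asym) * el
  sqrt(model$baseline_noise_sd^2 + v)
}

#' First-order (trigeminal ganglion) neuron model
#'
#' Inhomogeneous Bernoulli spiking on 1-ms bins with rate
#' `baseline + k_texture * |slip drive| + k_edge * arc_ratio(arc) * edge drive`.
#' The arc-dependent relative edge gain makes the edge/texture drive ratio
#' decrease from caudal (Greek, arc 0) to rostral (arc 4) whiskers.
#'
#' @param baseline_rate Spontaneous rate (Hz).
#' @param k_texture Rate gain per um of mean absolute slip drive (Hz/um).
#' @param k_edge Edge-drive rate gain at the caudal reference (Hz).
#' @param arc_edge_ratio Named map arc to relative edge gain; defaults
#'   decrease rostrally so k_edge/k_texture is largest caudally.
#' @param edge_drive_dur Duration of the edge drive window after each true
#'   collision onset (s).
#' @param refractory Hard refractory period (s); the default equals the bin
#'   width (at most one spike per bin).
#' @param bin Bin width (s).
#' @param adaptation_class `"RA"` or `"SA"` label carried to generated trains.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(baseline_rate = 5,
                         k_texture = 2,
                         k_edge = 150,
                         arc_edge_ratio = c(`0` = 1, `1` = 0.72, `2` = 0.5,
                                            `3` = 0.35, `4` = 0.25),
                         edge_drive_dur = 0.06,
                         refractory = 0.001,
                         bin = 0.001,
                         adaptation_class = c("RA", "SA")) {
  adaptation_class <- match.arg(adaptation_class)
  if (baseline_rate < 0 || k_texture < 0 || k_edge < 0)
    wp_abort("rates and gains must be nonnegative")
  if (is.null(names(arc_edge_ratio)) ||
      !all(as.character(0:4) %in% names(arc_edge_ratio)))
    wp_abort("arc_edge_ratio must be named with arcs '0'..'4'")
  structure(
    list(baseline_rate = baseline_rate, k_texture = k_texture, k_edge = k_edge,
         arc_edge_ratio = arc_edge_ratio, edge_drive_dur = edge_drive_dur,
         refractory = refractory, bin = bin,
         adaptation_class = adaptation_class),
    class = "neuron_model")
}
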