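test_that("identical seeds reproduce traces and spike trains exactly", {
  pad <- pad_model(sample_rate = 2500)
  a <- gen_edge_trace("P220", "C3", 7, pad, seed = 9)
  b <- gen_edge_trace("P220", "C3", 7, pad, seed = 9)
  expect_identical(a$position, b$position)
  expect_identical(a$curvature, b$curvature)
  expect_identical(collision_times(a), collision_times(b))
  sa <- gen_spike_train(a, model = neuron_model(), seed = 10)
  sb <- gen_spike_train(b, model = neuron_model(), seed = 10)
  expect_identical(sa$times, sb$times)
  s1 <- tiny_session(seed = 3, duration = 5)
  s2 <- tiny_session(seed = 3, duration = 5)
  expect_identical(s1$traces[[1]]$position, s2$traces[[1]]$position)
  expect_identical(s1$trains[[1]]$times, s2$trains[[1]]$times)
})

test_that("texture variance matches the compound-Poisson closed form", {
  pad <- pad_model()   # 25 kHz
  tr <- gen_texture_trace("P220", "C4", 60, pad, seed = 21, curvature = FALSE)
  expect_lt(abs(sd(tr$position) / texture_trace_sd(pad, "P220", "C4") - 1),
            0.05)

  # degenerate process: no slips leaves only baseline noise
  pad0 <- pad_model(slip_amp_per_um = 0)
  tr0 <- gen_texture_trace("P220", "C4", 10, pad0, seed = 22,
                           curvature = FALSE)
  expect_lt(abs(sd(tr0$position) / pad0$baseline_noise_sd - 1), 0.05)
})

test_that("grain diameter scales vibration SD as the variance formula predicts", {
  pad <- pad_model()
  coarse <- gen_texture_trace("P120", "C2", 20, pad, seed = 31,
                              curvature = FALSE)
  fine <- gen_texture_trace("P1200", "C2", 20, pad, seed = 32,
                            curvature = FALSE)
  expect_gt(sd(coarse$position), sd(fine$position))
  ratio_emp <- sd(coarse$position) / sd(fine$position)
  ratio_th <- texture_trace_sd(pad, "P120", "C2") /
    texture_trace_sd(pad, "P1200", "C2")
  expect_lt(abs(ratio_emp / ratio_th - 1), 0.1)
})

test_that("texture transmission is stronger through rostral whiskers", {
  pad <- pad_model(sample_rate = 2500)
  rostral <- gen_texture_trace("P220", "C4", 10, pad, seed = 41,
                               curvature = FALSE)
  caudal <- gen_texture_trace("P220", "gamma", 10, pad, seed = 42,
                              curvature = FALSE)
  expect_gt(sd(rostral$position), sd(caudal$position))
})

test_that("edge traces carry one collision per revolution", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P220", "C2", 9, pad, seed = 51, curvature = FALSE)
  expect_identical(length(collision_times(tr)), 3L)
  tr60 <- gen_edge_trace("P220", "C2", 60, pad, seed = 52, curvature = FALSE)
  expect_identical(length(collision_times(tr60)), 20L)
  expect_error(gen_edge_trace("P220", "C2", 2, pad), "revolution")
})

test_that("every collision exceeds the mean +- 3 SD criterion by construction", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P120", "gamma", 30, pad, seed = 61, curvature = FALSE)
  x <- tr$position
  thr <- 3 * sd(x)
  for (tc in collision_times(tr)) {
    i <- round(tc * 2500):round((tc + pad$edge_pulse_width) * 2500)
    expect_gt(max(abs(x[i] - mean(x))), thr)
  }
})

test_that("ringing decays to 1/e of its peak after one time constant", {
  pad <- pad_model(sample_rate = 25000)
  tr <- gen_edge_trace("P220", "C2", 3.2, pad, seed = 71, curvature = FALSE)
  edge <- attr(tr, "edge_component")
  tc <- collision_times(tr)[1]
  fs <- pad$sample_rate
  i0 <- round((tc + pad$edge_pulse_width) * fs)   # ring onset
  period_n <- round(fs / pad$ring_freq[["2"]])
  m1 <- max(abs(edge[i0 + seq_len(period_n)]))
  i_tau <- i0 + round(pad$ring_decay_tau * fs)
  m2 <- max(abs(edge[i_tau + seq_len(period_n)]))
  # both maxima sit at the first sine peak of their window, one tau apart
  expect_lt(abs(m2 / m1 - exp(-1)), 0.06)
})

test_that("baseline-only spiking is Poisson at the programmed rate", {
  tr <- kinematic_trace(numeric(100000), 1000, "C2", "P220")
  nm <- neuron_model(baseline_rate = 10, k_texture = 0, k_edge = 0)
  st <- gen_spike_train(tr, model = nm, seed = 81)
  expect_lt(abs(length(st$times) - 1000), 100)  # 3 SD of Binomial(1e5, .01)
})

test_that("edge-only drive concentrates spikes in edge windows", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P220", "C2", 30, pad, seed = 91, curvature = FALSE)
  nm <- neuron_model(baseline_rate = 2, k_texture = 0, k_edge = 400)
  st <- gen_spike_train(tr, model = nm, seed = 92)
  tc <- collision_times(tr)
  in_edge <- vapply(st$times, function(t)
    any(t >= tc & t < tc + nm$edge_drive_dur), logical(1))
  # expected in-window share: 400 Hz over 10 windows of 60 ms vs 2 Hz elsewhere
  expect_gt(mean(in_edge), 0.7)
  out_rate <- sum(!in_edge) / (30 - length(tc) * nm$edge_drive_dur)
  expect_lt(abs(out_rate - 2), 1.5)
})

test_that("programmed arc edge/texture ratios are recovered after normalization", {
  pad <- pad_model(sample_rate = 2500,
                   arc_gain = c(`0` = 0.5, `1` = 0.5, `2` = 0.5,
                                `3` = 0.5, `4` = 0.5))   # flat transmission
  nm <- neuron_model(baseline_rate = 0, k_texture = 2, k_edge = 300,
                     arc_edge_ratio = c(`0` = 1, `1` = 0.75, `2` = 0.5,
                                        `3` = 0.3, `4` = 0.2))
  sess <- gen_session(pad, nm, grades = "P220",
                      whiskers = c("gamma", "C2", "C4"),
                      duration = 120, seed = 101, curvature = FALSE)
  ft <- compute_features(sess, features = c("firing_rate_texture",
                                            "firing_rate_edge"))
  ratios <- vapply(c("gamma", "C2", "C4"), function(w) {
    edge_texture_ratio(
      ft$value[ft$whisker == w & ft$feature == "firing_rate_edge"],
      ft$value[ft$whisker == w & ft$feature == "firing_rate_texture"])
  }, numeric(1))
  nr <- normalize_to_max(ratios)
  expect_lt(max(abs(unname(nr) - c(1, 0.5, 0.2))), 0.15)
  expect_true(all(diff(unname(nr)) < 0))
})

test_that("spurious excursions in texture-only traces are rare", {
  # the generator/detector invariant bounds false excursions at 0.01 per
  # second; check the rate over 6 minutes of the worst case (coarsest
  # grain through the highest-gain whisker)
  pad <- pad_model(sample_rate = 2500)
  false_edges <- 0L
  for (s in 1:6) {
    tr <- gen_texture_trace("P120", "C4", 60, pad, seed = 110 + s,
                            curvature = FALSE)
    ep <- detect_edge_epochs(tr)
    false_edges <- false_edges + sum(ep$label == "edge")
  }
  expect_lte(false_edges, 7L)   # ~2x the bound's expectation over 360 s
})

test_that("model constructors validate their invariants", {
  expect_error(pad_model(edge_amp_sd_multiple = 2.5), "exceed 3")
  expect_error(pad_model(arc_gain = c(`0` = -1, `1` = 1, `2` = 1, `3` = 1,
                                      `4` = 1)), "> 0")
  expect_error(pad_model(arc_gain = c(a = 1)), "named")
  expect_error(neuron_model(baseline_rate = -1), "nonnegative")
  expect_error(gen_texture_trace("P220", "C2", 0, pad_model()), "duration")
  expect_error(gen_session(grades = character(0)), "nonempty")
  expect_error(gen_session(grades = c("P120", "P120"), duration = 1),
               "duplicate")
})
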