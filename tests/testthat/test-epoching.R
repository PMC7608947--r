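test_that("a featureless trace yields a single texture epoch", {
  tr <- kinematic_trace(numeric(5000), 2500, "C2", "P220")
  expect_warning(ep <- detect_edge_epochs(tr), "zero-variance")
  expect_identical(nrow(as.data.frame(ep)), 1L)
  expect_identical(ep$label, "texture")
  expect_identical(ep$start, 0L)
  expect_identical(ep$end, 5000L)
  expect_error(detect_edge_epochs(kinematic_trace(rnorm(100), 2500, "C2")),
               "at least 1 s")
})

test_that("inserted excursions are detected at their insertion times", {
  fs <- 2500
  withr::local_seed(7)
  x <- rnorm(30 * fs)   # sigma = 1
  t_ins <- c(5, 14.2, 26.5)
  for (t0 in t_ins) {   # 5-ms half-sine excursions of amplitude 10 sigma
    i <- round(t0 * fs) + seq_len(round(0.005 * fs))
    x[i] <- x[i] + 10 * sin(pi * (seq_along(i) - 0.5) / length(i))
  }
  tr <- kinematic_trace(x, fs, "C2", "P220")
  ep <- detect_edge_epochs(tr)
  ed <- ep[ep$label == "edge", ]
  expect_identical(nrow(ed), 3L)
  expect_true(all(abs(ed$t_start - t_ins) < 0.005))
})

test_that("detection is offset-invariant and scale-equivariant", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P220", "C2", 12, pad, seed = 15, curvature = FALSE)
  ep0 <- detect_edge_epochs(tr)
  tr_off <- kinematic_trace(tr$position + 1000, 2500, "C2", "P220")
  tr_scl <- kinematic_trace(tr$position * 7, 2500, "C2", "P220")
  for (tr2 in list(tr_off, tr_scl)) {
    ep2 <- detect_edge_epochs(tr2)
    expect_identical(ep2$start, ep0$start)
    expect_identical(ep2$end, ep0$end)
    expect_identical(ep2$label, ep0$label)
  }
})

test_that("one edge epoch is found per wheel revolution", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P220", "C2", 9, pad, seed = 16, curvature = FALSE)
  ep <- detect_edge_epochs(tr)
  expect_identical(sum(ep$label == "edge"), 3L)
})

test_that("epoch labels partition the trace into disjoint intervals", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P120", "gamma", 15, pad, seed = 17, curvature = FALSE)
  ep <- as.data.frame(detect_edge_epochs(tr))
  ep <- ep[order(ep$start), ]
  expect_identical(ep$start[1], 0L)
  expect_identical(ep$end[nrow(ep)], length(tr$position))
  expect_true(all(ep$start[-1] == ep$end[-nrow(ep)]))    # cover, no overlap
  expect_setequal(unique(ep$label),
                  c("texture", "edge", "guard", "pre_edge"))
})

test_that("trial segmentation tiles texture epochs without overlap", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_texture_trace("P220", "C2", 120, pad, seed = 18,
                          curvature = FALSE)
  ep <- detect_edge_epochs(tr)
  tri <- segment_trials(tr, ep, window = 0.5)
  expect_identical(nrow(tri), 240L)     # 120 s / 0.5 s
  expect_true(all(diff(tri$start) >= 1250))

  # a 0.49-s texture epoch yields no trial
  short <- data.frame(start = 0L, end = 1225L, t_start = 0, t_end = 0.49,
                      label = "texture")
  expect_identical(nrow(segment_trials(tr, short, window = 0.5)), 0L)
  expect_error(segment_trials(tr, ep, window = 0), "> 0")
})

test_that("trials never contain a true collision", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P220", "C3", 30, pad, seed = 19, curvature = FALSE)
  ep <- detect_edge_epochs(tr)
  tri <- segment_trials(tr, ep, window = 0.5)
  for (tc in collision_times(tr))
    expect_false(any(tri$t_start <= tc & tri$t_end > tc))
})

test_that("PSTH probabilities follow the alignment-event definition", {
  quiet <- spike_train(numeric(0), "u0", "C2")
  ps0 <- build_psth(quiet, c(1, 2, 3), window = c(-0.01, 0.01))
  expect_true(all(ps0$prob == 0))

  # one spike exactly at each of 50 alignment times
  al <- seq(1, 50)
  st <- spike_train(al + 0.0005, "u1", "C2")
  ps <- build_psth(st, al, window = c(-0.005, 0.005))
  expect_identical(sum(ps$prob == 1), 1L)
  expect_identical(which(ps$prob == 1), which(ps$t >= 0)[1])
  expect_true(all(ps$prob[ps$prob != 1] == 0))
  expect_identical(ps$n_events, 50L)

  # homogeneous 20 Hz spiking: mean bin probability ~ r * dt = 0.02
  withr::local_seed(8)
  times <- (which(runif(300000) < 0.02) - 0.5) / 1000
  sth <- spike_train(times, "u2", "C2")
  ph <- build_psth(sth, seq(5, 295, by = 2), window = c(-0.1, 0.1))
  expect_lt(abs(mean(ph$prob) - 0.02), 0.004)

  expect_error(build_psth(quiet, numeric(0)), "alignment")
})

test_that("epoch sets export as interval text", {
  pad <- pad_model(sample_rate = 2500)
  tr <- gen_edge_trace("P220", "C2", 9, pad, seed = 20, curvature = FALSE)
  ep <- detect_edge_epochs(tr)
  f <- withr::local_tempfile(fileext = ".bed")
  write_epochs(ep, f)
  got <- data.table::fread(f, header = FALSE)
  expect_identical(nrow(got), nrow(as.data.frame(ep)))
  expect_identical(got$V1, ep$start)
  expect_identical(got$V3, ep$label)
})
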