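test_that("position and curvature SD follow the sample-SD definition", {
  expect_identical(position_sd(rep(3.2, 100)), 0)
  expect_equal(position_sd(c(-1, -1, 1, 1)), 2 / sqrt(3))
  expect_error(position_sd(1), "at least 2")
  expect_identical(curvature_sd(rep(0.5, 10)), 0)
  expect_error(curvature_sd(0.1), "at least 2")
  # offset invariance, linear amplitude scaling
  withr::local_seed(5)
  x <- rnorm(1000)
  expect_equal(position_sd(x + 100), position_sd(x))
  expect_equal(position_sd(3 * x), 3 * position_sd(x))
})

test_that("band power integrates the PSD over the 5-250 Hz band", {
  fs <- 2500
  t <- (0:(fs / 2 - 1)) / fs   # 0.5 s trial
  x <- sin(2 * pi * 100 * t)
  expect_equal(band_power(x, fs), 0.5, tolerance = 0.05)
  expect_lt(band_power(sin(2 * pi * 400 * t), fs), 0.02 * 0.5)
  expect_identical(band_power(numeric(fs), fs), 0)
  expect_identical(band_power(rep(2, fs), fs), 0)   # offset only
  # quadratic amplitude scaling, offset invariance
  withr::local_seed(6)
  y <- rnorm(fs)
  expect_equal(band_power(2 * y, fs), 4 * band_power(y, fs), tolerance = 1e-10)
  expect_equal(band_power(y + 10, fs), band_power(y, fs), tolerance = 1e-10)
  expect_error(band_power(x, fs, band = c(5, 2000)), "Nyquist")
  expect_error(band_power(x[1:100], fs), "low-cut")
})

test_that("curvature SD scales with the generator's curvature gain", {
  pad1 <- pad_model(sample_rate = 2500, curvature_noise_sd = 0)
  pad2 <- pad_model(sample_rate = 2500, curvature_noise_sd = 0,
                    curvature_gain = 2 * pad1$curvature_gain)
  a <- gen_texture_trace("P220", "C2", 5, pad1, seed = 7)
  b <- gen_texture_trace("P220", "C2", 5, pad2, seed = 7)
  expect_equal(curvature_sd(b$curvature) / curvature_sd(a$curvature), 2,
               tolerance = 1e-6)
  # coarser grain drives larger curvature SD at a fixed whisker
  coarse <- gen_texture_trace("P120", "C4", 10, pad1, seed = 8)
  fine <- gen_texture_trace("P1200", "C4", 10, pad1, seed = 9)
  expect_gt(curvature_sd(coarse$curvature), curvature_sd(fine$curvature))
})

test_that("firing rate is spike count over window length", {
  expect_identical(firing_rate(numeric(0), c(0, 0.05)), 0)
  expect_identical(firing_rate(c(0.01, 0.02, 0.03, 0.04, 0.045), c(0, 0.05)),
                   100)
  expect_identical(firing_rate(0.005, c(0, 0.01)), 100)
  st <- spike_train(c(0.1, 0.2), "u1", "C2")
  expect_identical(firing_rate(st, c(0, 0.5)), 4)
  expect_error(firing_rate(numeric(0), c(0, 0.04), T = 0.05), "shorter")
})

test_that("edge/texture ratios normalize to the group maximum", {
  expect_identical(edge_texture_ratio(c(10, 10), c(10, 10)), 1)
  expect_warning(r <- edge_texture_ratio(5, c(0, 0)), "undefined")
  expect_true(is.na(r))
  expect_equal(normalize_to_max(c(10, 5, 2)), c(1, 0.5, 0.2))
  expect_equal(normalize_to_max(c(2, NA, 8)), c(0.25, NA, 1))
  expect_error(normalize_to_max(c(NA_real_, NA_real_)), "no positive")
})

test_that("pad maps normalize per texture and peak at exactly 1", {
  ft <- data.frame(
    whisker = rep(c("gamma", "C2", "C4"), each = 2),
    arc = rep(c(0L, 2L, 4L), each = 2),
    row = rep(c("Greek", "C", "C"), each = 2),
    condition = "P220", trial = rep(1:2, 3),
    feature = "position_sd",
    value = c(2, 2, 4, 4, 8, 8))
  pm <- build_pad_map(ft)
  expect_equal(pm$value[match(c(0, 2, 4), pm$arc)], c(0.25, 0.5, 1))

  ft$value <- 5
  pm_eq <- build_pad_map(ft)
  expect_true(all(pm_eq$value == 1))

  # max exactly 1 even when different whiskers peak per texture
  ft2 <- rbind(ft, transform(ft, condition = "P120",
                             value = c(8, 8, 4, 4, 2, 2)))
  pm2 <- build_pad_map(ft2)
  expect_identical(max(pm2$value), 1)

  expect_warning(build_pad_map(ft2[-(1:2), ]), "missing")
  expect_error(build_pad_map(ft, feature = "band_power"), "no 'band_power'")
})

test_that("session feature tables have the documented schema", {
  sess <- tiny_session(seed = 12, duration = 10, curvature = TRUE)
  ft <- compute_features(sess)
  expect_setequal(unique(ft$feature),
                  c("position_sd", "band_power", "curvature_sd",
                    "firing_rate_texture", "firing_rate_edge"))
  expect_true(all(c("trace_id", "whisker", "arc", "row", "condition",
                    "diameter_um", "trial", "feature", "value", "unit_id")
                  %in% names(ft)))
  expect_true(all(is.finite(ft$value)))
  expect_true(all(ft$value >= 0))
  # one value per key tuple
  key <- paste(ft$trace_id, ft$feature, ft$trial)
  expect_false(anyDuplicated(key) > 0)
})

test_that("feature values are stable under anti-aliased decimation", {
  pad <- pad_model()  # 25 kHz
  tr <- gen_edge_trace("P220", "C4", 10, pad, seed = 13, curvature = FALSE)
  sess <- whisker_session(list(tr))
  ft_full <- compute_features(sess, features = c("position_sd", "band_power"))
  ft_dec <- compute_features(sess, features = c("position_sd", "band_power"),
                             decimate_to = 2500)
  for (f in c("position_sd", "band_power")) {
    a <- ft_full$value[ft_full$feature == f]
    b <- ft_dec$value[ft_dec$feature == f]
    n <- min(length(a), length(b))
    expect_equal(mean(b[1:n]) / mean(a[1:n]), 1, tolerance = 0.02)
  }
})
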