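test_that("re-referencing subtracts the mastoid average", {
  data <- rbind(r1 = c(1, 1), r2 = c(3, 3), ch = c(10, 10))
  rec <- eeg_recording(data, c("r1", "r2", "ch"), 250)
  out <- rereference(rec, c("r1", "r2"))
  expect_equal(unname(out$data["ch", ]), c(8, 8))
  expect_equal(unname(out$data["r1", ]), c(-1, -1))
  expect_match(tail(out$provenance, 1), "rereference")
  # zero references leave the data unchanged
  data0 <- rbind(z1 = c(0, 0), z2 = c(0, 0), ch = c(5, -5))
  rec0 <- eeg_recording(data0, c("z1", "z2", "ch"), 250)
  expect_equal(rereference(rec0, c("z1", "z2"))$data, rec0$data)
  expect_error(rereference(rec, c("r1", "nope")), "unknown channel")
})

test_that("a channel referenced to itself becomes zero", {
  rec <- eeg_recording(matrix(sin(1:100), 1), "x", 100)
  out <- rereference(rec, c("x", "x"))
  expect_equal(max(abs(out$data)), 0)
})

test_that("notch removes line frequency and preserves the passband", {
  fs <- 1000
  t <- seq_len(6 * fs) / fs
  interior <- (fs + 1):(5 * fs)   # discard 1 s edges
  line <- eeg_recording(matrix(sin(2 * pi * 50 * t), 1), "x", fs)
  out <- notch(line, 50)
  expect_lte(sd(out$data[1, interior]), 0.05 * sd(line$data[1, interior]))
  tone <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), "x", fs)
  out10 <- notch(tone, 50)
  expect_equal(sd(out10$data[1, interior]), sd(tone$data[1, interior]),
               tolerance = 0.05)
  zero <- eeg_recording(matrix(0, 1, fs), "x", fs)
  expect_equal(max(abs(notch(zero, 50)$data)), 0)
  expect_error(notch(eeg_recording(matrix(0, 1, 100), "x", 80), 50),
               "Nyquist")
})

test_that("downsampling decimates with the expected length and spectrum", {
  fs <- 1000
  t <- seq_len(4000) / fs
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), "x", fs)
  out <- downsample(rec, 250)
  expect_equal(out$fs_hz, 250)
  expect_equal(ncol(out$data), 1000L)
  spec <- Mod(fft(out$data[1, ]))[1:500]
  peak_hz <- (which.max(spec) - 1) * 250 / 1000
  expect_equal(peak_hz, 10)
  # identity apart from provenance when target equals current rate
  same <- downsample(rec, 1000)
  expect_equal(same$data, rec$data)
  expect_match(tail(same$provenance, 1), "downsample")
  expect_error(downsample(out, 500), "upsampling")
})

test_that("bandpass passes in-band tones and rejects out-of-band tones", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  interior <- (fs + 1):(9 * fs)
  in_band <- eeg_recording(matrix(sin(2 * pi * 9 * t), 1), "x", fs)
  out <- bandpass(in_band, "lower_alpha")
  expect_equal(sd(out$data[1, interior]), sd(in_band$data[1, interior]),
               tolerance = 0.1)
  out_band <- eeg_recording(matrix(sin(2 * pi * 20 * t), 1), "x", fs)
  rej <- bandpass(out_band, "lower_alpha")
  expect_lte(sd(rej$data[1, interior]), 0.1 * sd(out_band$data[1, interior]))
  zero <- eeg_recording(matrix(0, 1, fs), "x", fs)
  expect_equal(max(abs(bandpass(zero, "lower_alpha")$data)), 0)
  expect_error(bandpass(eeg_recording(matrix(0, 1, 100), "x", 60), "gamma"),
               "Nyquist")
})

test_that("band filtering is linear and zero-phase", {
  fs <- 250
  set.seed(42)
  x <- rnorm(6 * fs)
  rec1 <- eeg_recording(matrix(x, 1), "x", fs)
  rec5 <- eeg_recording(matrix(5 * x, 1), "x", fs)
  f1 <- bandpass(rec1, "lower_alpha")$data[1, ]
  f5 <- bandpass(rec5, "lower_alpha")$data[1, ]
  expect_equal(f5, 5 * f1, tolerance = 1e-9)
  # zero-phase: cross-correlation between a band-limited input and its
  # filtered output peaks at lag 0
  t <- seq_len(6 * fs) / fs
  tone <- sin(2 * pi * 9 * t)
  out <- bandpass(eeg_recording(matrix(tone, 1), "x", fs),
                  "lower_alpha")$data[1, ]
  interior <- (fs + 1):(5 * fs)
  cc <- ccf(tone[interior], out[interior], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("segment extraction returns the first clean window", {
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(30 * fs), 1), "x", fs)
  seg <- extract_segment(rec, 18)
  expect_equal(ncol(seg$data), 18 * fs)
  expect_equal(unname(seg$data[1, ]), unname(rec$data[1, 1:(18 * fs)]))
  short <- eeg_recording(matrix(rnorm(10 * fs), 1), "x", fs)
  expect_error(extract_segment(short, 18), "shorter")
})

test_that("amplitude-threshold rejection skips past artifacts", {
  fs <- 100
  x <- rnorm(40 * fs)
  spike_at <- 2 * fs   # spike at t = 2 s
  x[spike_at] <- 500
  rec <- eeg_recording(matrix(x, 1), "x", fs)
  seg <- extract_segment(rec, 10, reject_threshold = 100)
  # returned window starts after the spike
  expect_true(all(abs(seg$data) <= 100))
  expect_equal(unname(seg$data[1, 1]), x[spike_at + 1])
  # an unsatisfiable request reports the longest clean stretch
  y <- rnorm(20 * fs)
  y[seq(5 * fs, 20 * fs, by = 5 * fs)] <- 999
  bad <- eeg_recording(matrix(y, 1), "x", fs)
  expect_error(extract_segment(bad, 10, reject_threshold = 100),
               "longest clean stretch")
})

test_that("provenance records the processing chain in execution order", {
  spec <- coupling_spec(c("a", "b", "M1", "M2"), 9, noise_sd = 0.2)
  rec <- simulate_recording(spec, 6, 1000, seed = 1)
  out <- bandpass(
    extract_segment(
      notch(downsample(rereference(rec, c("M1", "M2")), 250), 50),
      4),
    "lower_alpha")
  steps <- sub("\\(.*", "", out$provenance)
  expect_equal(steps, c("simulate", "rereference", "downsample", "notch",
                        "segment", "bandpass"))
})
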