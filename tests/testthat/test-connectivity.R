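test_that("instantaneous phase of a pure tone advances at the tone frequency", {
  fs <- 250
  t <- seq_len(8 * fs) / fs
  ph <- instantaneous_phase(cos(2 * pi * 10 * t), fs_hz = fs)
  interior <- which(attr(ph, "valid"))
  slope <- mean(diff(cumsum(c(ph[interior][1],
                              plinet:::wrap_phase(diff(ph[interior])))))) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
})

test_that("quadrature tones show a constant pi/2 phase difference", {
  fs <- 250
  t <- seq_len(8 * fs) / fs
  pc <- instantaneous_phase(cos(2 * pi * 10 * t), fs_hz = fs)
  ps <- instantaneous_phase(sin(2 * pi * 10 * t), fs_hz = fs)
  interior <- attr(pc, "valid")
  d <- plinet:::wrap_phase(pc[interior] - ps[interior])
  expect_lt(max(abs(d - pi / 2)), 0.05)
})

test_that("instantaneous phase is amplitude-invariant and needs variance", {
  fs <- 250
  t <- seq_len(4 * fs) / fs
  x <- cos(2 * pi * 9 * t)
  expect_equal(instantaneous_phase(x), instantaneous_phase(5 * x))
  expect_error(instantaneous_phase(rep(1, 100)), "zero-variance")
  expect_error(instantaneous_phase(1), "2 samples")
})

test_that("PLI matches its sign-mean definition on constructed series", {
  expect_identical(pli(rep(pi / 2, 1000)), 1)
  expect_identical(pli(rep(0, 1000)), 0)
  expect_identical(pli(rep(pi, 1000)), 0)    # 0 mod pi is symmetric
  expect_equal(pli(c(rep(0.1, 750), rep(-0.1, 250))), 0.5)
  set.seed(1)
  expect_lte(pli(runif(1e5, -pi, pi)), 0.02)
  # wrapping: adding full turns changes nothing
  set.seed(2)
  d <- runif(500, -3, 3)
  expect_equal(pli(d), pli(d + 2 * pi))
  # masking
  d2 <- c(rep(pi / 2, 100), rep(0, 100))
  expect_identical(pli(d2, c(rep(TRUE, 100), rep(FALSE, 100))), 1)
  expect_error(pli(d2, rep(FALSE, 200)), "no valid samples")
})

test_that("connectivity matrix is symmetric, zero-diagonal and in range", {
  spec <- coupling_spec(c("a", "b", "c"), 9,
                        data.frame(a = "a", b = "b", kappa = 0.6,
                                   delta = pi / 3))
  rec <- simulate_recording(spec, 10, 250, seed = 4)
  m <- connectivity_matrix(rec, "lower_alpha")
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(rownames(m), c("a", "b", "c"))
  expect_equal(attr(m, "band"), "lower_alpha")
})

test_that("a quadrature channel pair attains PLI near 1", {
  rec <- tone_recording(c(10, 10), fs = 250, duration = 10,
                        phases = c(0, pi / 2))
  m <- connectivity_matrix(rec, "lower_alpha")
  expect_equal(m[1, 2], 1, tolerance = 0.02)
})

test_that("duplicate channels have PLI exactly zero", {
  fs <- 250
  t <- seq_len(6 * fs) / fs
  x <- cos(2 * pi * 9 * t) + 0.1 * sin(2 * pi * 8.5 * t)
  rec <- eeg_recording(rbind(x, x), c("a", "b"), fs)
  m <- connectivity_matrix(rec, "lower_alpha")
  expect_identical(m[1, 2], 0)
})

test_that("rescaling a channel leaves the whole PLI matrix unchanged", {
  spec <- coupling_spec(c("a", "b", "c"), 9, noise_sd = 0.4)
  rec <- simulate_recording(spec, 10, 250, seed = 6)
  m1 <- connectivity_matrix(rec, "lower_alpha")
  rec$data[2, ] <- 7.3 * rec$data[2, ]
  m2 <- connectivity_matrix(rec, "lower_alpha")
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-9)
})

test_that("negating one channel of a constant-lag pair preserves PLI", {
  rec <- tone_recording(c(10, 10), fs = 250, duration = 10,
                        phases = c(0, pi / 3))
  m1 <- connectivity_matrix(rec, "lower_alpha")
  rec$data[2, ] <- -rec$data[2, ]
  m2 <- connectivity_matrix(rec, "lower_alpha")
  expect_lte(abs(m1[1, 2] - m2[1, 2]), 0.02)
})

test_that("global mean PLI averages the upper triangle", {
  w <- matrix(0.4, 3, 3); diag(w) <- 0
  rownames(w) <- colnames(w) <- c("a", "b", "c")
  expect_equal(global_mean_pli(pli_matrix(w)), 0.4)
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 0.2
  w2[1, 3] <- w2[3, 1] <- 0.4
  w2[2, 3] <- w2[3, 2] <- 0.6
  rownames(w2) <- colnames(w2) <- c("a", "b", "c")
  expect_equal(global_mean_pli(pli_matrix(w2)), 0.4)
  expect_equal(global_mean_pli(pli_matrix(0 * w, "x")), 0)
  expect_error(global_mean_pli(matrix(0, 1, 1)), "2 channels")
})

test_that("distance summary has the canonical category structure", {
  labels <- default_montage()
  w <- matrix(0.25, 59, 59); diag(w) <- 0
  rownames(w) <- colnames(w) <- labels
  ds <- distance_summary(pli_matrix(w))
  expect_equal(sum(ds$type == "short"), 8)
  expect_equal(sum(ds$type == "long_intra"), 12)
  expect_equal(sum(ds$type == "long_inter"), 4)
  expect_equal(sum(ds$type == "global"), 1)
  # constant matrix -> every summary value equals the constant
  expect_true(all(ds$value == 0.25))
})

test_that("distance summary equals brute-force averaging on a toy montage", {
  # 6 lateral channels: 2 per region in one hemisphere, plus a midline
  map <- tibble::tibble(
    channel = c("F1", "F3", "C1", "C3", "O1", "PO3", "Fz"),
    hemisphere = c(rep("left", 6), "midline"),
    region = c("frontal", "frontal", "central", "central",
               "occipital", "occipital", NA)
  )
  w <- make_random_w(7, seed = 31)
  rownames(w) <- colnames(w) <- map$channel
  w <- pli_matrix(round(w, 3))
  ds <- distance_summary(w, map)
  pick <- function(m) ds$value[ds$measure == m]
  expect_equal(pick("short_left_frontal"), w["F1", "F3"])
  expect_equal(pick("short_left_central"), w["C1", "C3"])
  expect_equal(pick("long_intra_left_frontal_central"),
               mean(w[c("F1", "F3"), c("C1", "C3")]))
  expect_equal(pick("long_intra_left_central_occipital"),
               mean(w[c("C1", "C3"), c("O1", "PO3")]))
  # no right hemisphere: those groups are flagged missing, not zero
  expect_true(is.na(pick("short_right_frontal")))
  expect_true(is.na(pick("long_inter_frontal")))
  # midline channel enters the global mean but no region group
  expect_equal(pick("global_mean"), mean(w[upper.tri(w)]))
  w2 <- unclass(w)
  w2["Fz", ] <- w2[, "Fz"] <- c(rep(0.9, 6), 0)
  diag(w2) <- 0
  ds2 <- distance_summary(pli_matrix(w2), map)
  keep <- ds$type != "global"
  expect_equal(ds2$value[keep], ds$value[keep])
})

test_that("connectivity matrices round-trip through TSV and JSON", {
  w <- make_random_w(5, seed = 8)
  m <- pli_matrix(round(w, 6), "beta")
  tsv <- tempfile(fileext = ".tsv")
  json <- tempfile(fileext = ".json")
  write_pli_matrix_tsv(m, tsv)
  write_pli_matrix_json(m, json)
  expect_equal(unclass(read_pli_matrix_tsv(tsv)), unclass(m),
               ignore_attr = TRUE)
  back <- read_pli_matrix_json(json)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_equal(attr(back, "band"), "beta")
})
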