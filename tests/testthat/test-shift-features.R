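test_that("per-epoch band power is spectrally calibrated (Parseval)", {
  fs <- 128
  n <- 60 * fs
  t <- seq_len(n) / fs
  a <- 10
  rec <- make_rec(Cz = a * sin(2 * pi * 10 * t), fs = fs)
  grid <- build_grid(rec)
  bp <- band_power(rec, grid, good_mask(rec, grid))
  # pure 10 Hz sine of amplitude A: alpha power A^2/2, theta/beta ~ 0
  expect_equal(unname(bp$power[, "alpha"]), rep(a^2 / 2, 60), tolerance = 1e-6)
  expect_lt(max(bp$power[, c("theta", "beta")]), 1e-12)

  # white noise: mean band power proportional to band width (4:6:14 bins)
  set.seed(6)
  recw <- make_rec(Cz = rnorm(600 * fs, sd = 15), fs = fs)
  gridw <- build_grid(recw)
  bpw <- band_power(recw, gridw, good_mask(recw, gridw))
  mt <- mean(bpw$power[, "theta"]); ma <- mean(bpw$power[, "alpha"])
  mb <- mean(bpw$power[, "beta"])
  expect_equal(ma / mt, 6 / 4, tolerance = 0.1)
  expect_equal(mb / mt, 14 / 4, tolerance = 0.1)

  # epochs of an all-bad window are missing, never zero
  mask <- good_mask(rec, grid)
  mask$window_bad[, 2] <- TRUE
  bp2 <- band_power(rec, grid, mask)
  expect_true(all(is.na(bp2$power[31:60, ])))
  expect_false(anyNA(bp2$power[1:30, ]))
})

test_that("EMG shift cascade flags bursts and spares stationary tone", {
  fs <- 128
  n_ep <- 360
  set.seed(7)
  base <- rnorm(n_ep * fs, sd = 2)
  grid <- build_grid(recording(matrix(rnorm(n_ep * fs), ncol = 1), fs,
                               "Cz", "EEG"))
  # 2 s burst at 10x background magnitude, after the 240 s baseline
  burst_ep <- 301:302
  sig <- base
  for (ep in burst_ep) sig[((ep - 1) * fs + 1):(ep * fs)] <-
      base[((ep - 1) * fs + 1):(ep * fs)] * 10
  flags <- detect_emg_shifts(make_emg(sig, grid), grid)
  expect_true(all(flags[burst_ep]))
  expect_equal(sum(flags), 2)

  # stationary EMG noise: no systematic flags
  expect_equal(sum(detect_emg_shifts(make_emg(base, grid), grid)), 0)

  # burst inside the first 240 s baseline stretch: caught by steps 2-3
  sig2 <- base
  for (ep in 101:102) sig2[((ep - 1) * fs + 1):(ep * fs)] <-
      base[((ep - 1) * fs + 1):(ep * fs)] * 10
  flags2 <- detect_emg_shifts(make_emg(sig2, grid), grid)
  expect_true(all(flags2[101:102]))

  # EMG-unavailable windows are never flagged
  prov <- rep("both", grid$n_windows); prov[11] <- "none"
  flags3 <- detect_emg_shifts(make_emg(sig, grid, prov), grid)
  expect_false(any(flags3[window_epochs(grid, 11)]))
})

test_that("EEG shift thresholds are both fixed (global median) and adaptive (2x local)", {
  n_ep <- 120
  cfg <- arousal_config()
  grid <- list(fs = 128, n_epochs = n_ep, n_windows = 4L,
               epochs_per_window = 30L,
               window_of = (seq_len(n_ep) - 1L) %/% 30L + 1L,
               partial_last = FALSE)
  class(grid) <- "epoch_grid"
  no_emg <- rep(FALSE, n_ep)

  set.seed(8)
  mk <- function(theta) {
    p <- cbind(theta = theta, alpha = rexp(n_ep) + 1,
               sigma = rexp(n_ep) + 1, beta = rexp(n_ep) + 1)
    make_bp(p)
  }
  # one epoch at 10x the global median with a clean neighbourhood -> flagged
  theta <- rep(1, n_ep) + runif(n_ep, -0.01, 0.01)
  theta[50] <- 10 * median(theta)
  fl <- detect_eeg_shifts(mk(theta), no_emg, grid, cfg)
  expect_true(fl[50, "theta"])
  expect_equal(sum(fl[, "theta"]), 1)

  # a uniformly elevated window -> the adaptive threshold scales with it and
  # an epoch at the window's own level is not a shift
  theta2 <- rep(1, n_ep) + runif(n_ep, -0.01, 0.01)
  theta2[31:60] <- theta2[31:60] * 10
  fl2 <- detect_eeg_shifts(mk(theta2), no_emg, grid, cfg)
  expect_false(fl2[50, "theta"])

  # flags are a subset of epochs above the global median, and stationary
  # noise flags are rare
  set.seed(9)
  theta3 <- rexp(n_ep)
  fl3 <- detect_eeg_shifts(mk(theta3), no_emg, grid, cfg)
  expect_true(all(theta3[fl3[, "theta"]] > median(theta3)))
  expect_lt(mean(fl3[, "theta"]), 0.2)

  # EMG-shifted epochs are excluded from the adaptive selection: an EMG
  # artefact epoch with huge power must not inflate the local threshold
  theta4 <- rep(1, n_ep) + runif(n_ep, -0.01, 0.01)
  theta4[45] <- 400            # EMG artefact epoch
  theta4[50] <- 3
  emg <- no_emg; emg[45] <- TRUE
  fl4 <- detect_eeg_shifts(mk(theta4), emg, grid, cfg)
  expect_true(fl4[50, "theta"])
})

test_that("relative sigma power above 85% of its maximum marks spindle epochs", {
  fs <- 128
  n <- 60 * fs
  t <- seq_len(n) / fs
  set.seed(10)
  x <- rnorm(n, sd = 10)
  spin <- 21:22                       # epochs with a 13.5 Hz tone
  for (ep in spin) x[((ep - 1) * fs + 1):(ep * fs)] <-
      x[((ep - 1) * fs + 1):(ep * fs)] + 40 * sin(2 * pi * 13.5 * t[1:fs])
  rec <- make_rec(Cz = x, fs = fs)
  grid <- build_grid(rec)
  bp <- band_power(rec, grid, good_mask(rec, grid))
  fl <- detect_spindle_epochs(bp)
  expect_true(all(fl[spin]))
  expect_false(any(fl[-spin]))

  # a pure 10 Hz epoch has ~no sigma power and is never a spindle epoch
  x2 <- rnorm(n, sd = 10)
  for (ep in spin) x2[((ep - 1) * fs + 1):(ep * fs)] <-
      x2[((ep - 1) * fs + 1):(ep * fs)] + 40 * sin(2 * pi * 10 * t[1:fs])
  bp2 <- band_power(make_rec(Cz = x2, fs = fs), grid, NULL)
  expect_false(any(detect_spindle_epochs(bp2)[spin]))

  # uniform relative sigma power: every epoch equals the maximum -> with the
  # strict > rule nothing exceeds 85% of max times... all are flagged since
  # each equals max > 0.85 * max
  p <- matrix(1, 10, 4, dimnames = list(NULL, c("theta", "alpha",
                                                "sigma", "beta")))
  expect_true(all(detect_spindle_epochs(make_bp(p))))
})

test_that("all shift masks are invariant to global amplitude scaling", {
  pl <- plan_events(rep(c("N2", "N3"), 10), n = 3, duration_s = 4,
                    gain = 4, with_emg = TRUE, seed = 12)
  syn <- synth_psg(synth_spec(duration_s = 600, events = pl, seed = 12,
                              stages = rep(c("N2", "N3"), 10)))
  masks_for <- function(scale) {
    rec <- syn$recording
    rec$signals <- rec$signals * scale
    rec <- quiet(mean_correct(apply_filters(rec)))
    grid <- build_grid(rec)
    mask <- detect_bad_eeg_windows(rec, grid, detect_bad_eeg_global(rec))
    emg <- quiet(build_composite_emg(rec, grid))
    quiet(shift_masks(rec, grid, mask, emg))
  }
  m1 <- masks_for(1)
  m01 <- masks_for(0.1)
  m10 <- masks_for(10)
  for (f in c("emg_shift", "eeg_shift", "spindle")) {
    expect_identical(m1[[f]], m01[[f]])
    expect_identical(m1[[f]], m10[[f]])
  }
  expect_true(any(m1$emg_shift))      # the masks are not trivially empty
  expect_true(any(m1$eeg_shift))
})
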