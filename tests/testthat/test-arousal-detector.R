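mk_masks <- function(n_ep, eeg = list(), spindle = integer(),
                     emg = integer()) {
  es <- matrix(FALSE, n_ep, 3, dimnames = list(NULL, c("theta", "alpha",
                                                       "beta")))
  for (b in names(eeg)) es[eeg[[b]], b] <- TRUE
  structure(list(
    emg_shift = seq_len(n_ep) %in% emg,
    eeg_shift = es,
    spindle = seq_len(n_ep) %in% spindle,
    emg_available = rep(TRUE, n_ep)
  ), class = "shift_masks")
}

mk_grid <- function(n_ep, fs = 128) {
  structure(list(fs = fs, n_epochs = n_ep,
                 n_windows = as.integer(ceiling(n_ep / 30)),
                 epochs_per_window = 30L,
                 window_of = (seq_len(n_ep) - 1L) %/% 30L + 1L,
                 partial_last = (n_ep %% 30L) != 0L), class = "epoch_grid")
}

test_that("runs of >=3 triggered epochs become events; shorter runs do not", {
  grid <- mk_grid(120)
  hyp <- hypnogram(rep("N2", 4))
  # 4-epoch alpha run (epochs 41-44 -> seconds 40-43)
  ev <- assemble_events(mk_masks(120, eeg = list(alpha = 41:44)), hyp, grid)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 40)
  expect_equal(ev$duration_s, 4)
  expect_false(ev$emg_associated)
  expect_equal(ev$bands, "alpha")
  expect_equal(ev$stage, "N2")

  # 2-epoch beta run: below the 3 s minimum
  ev2 <- assemble_events(mk_masks(120, eeg = list(beta = 10:11)), hyp, grid)
  expect_equal(nrow(ev2), 0)

  # every emitted event lasts at least 3 s (random masks)
  set.seed(13)
  for (i in 1:20) {
    m <- mk_masks(120, eeg = list(alpha = which(runif(120) < 0.3),
                                  theta = which(runif(120) < 0.2)),
                  spindle = which(runif(120) < 0.1))
    e <- assemble_events(m, hyp, grid)
    if (nrow(e)) expect_true(all(e$duration_s >= 3))
  }
})

test_that("REM events need a concomitant EMG shift; wake events are dropped", {
  grid <- mk_grid(120)
  hyp_rem <- hypnogram(c("REM", "REM", "N2", "N2"))
  # 5-epoch theta run in REM without EMG: rejected
  ev <- assemble_events(mk_masks(120, eeg = list(theta = 11:15)), hyp_rem, grid)
  expect_equal(nrow(ev), 0)
  # the same run with an overlapping EMG shift: kept, EMG-associated
  ev2 <- assemble_events(mk_masks(120, eeg = list(theta = 11:15), emg = 13),
                         hyp_rem, grid)
  expect_equal(nrow(ev2), 1)
  expect_true(ev2$emg_associated)
  expect_equal(ev2$stage, "REM")
  # an EMG shift 1 s beyond the boundary still counts as concomitant ...
  ev3 <- assemble_events(mk_masks(120, eeg = list(theta = 11:15), emg = 16),
                         hyp_rem, grid)
  expect_equal(nrow(ev3), 1)
  # ... but not under strict overlap
  ev4 <- assemble_events(mk_masks(120, eeg = list(theta = 11:15), emg = 16),
                         hyp_rem, grid, arousal_config(emg_concomitance_s = 0))
  expect_equal(nrow(ev4), 0)

  hyp_w <- hypnogram(c("W", "W", "N2", "N2"))
  ev5 <- assemble_events(mk_masks(120, eeg = list(alpha = 11:15)), hyp_w, grid)
  expect_equal(nrow(ev5), 0)
})

test_that("sigma (spindle) exclusion removes epochs before run-finding and can split runs", {
  grid <- mk_grid(120)
  hyp <- hypnogram(rep("N2", 4))
  # 7 triggered epochs with a spindle in the middle: two runs of 3 -> 2 events
  m <- mk_masks(120, eeg = list(alpha = 41:47), spindle = 44)
  ev <- assemble_events(m, hyp, grid)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset_s, c(40, 44))
  expect_equal(ev$duration_s, c(3, 3))
  # a spindle epoch 2 from the end leaves a 5-run and an orphan pair
  m2 <- mk_masks(120, eeg = list(alpha = 41:48), spindle = 46)
  ev2 <- assemble_events(m2, hyp, grid)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$onset_s, 40)
  # spindle-only epochs never trigger
  m3 <- mk_masks(120, spindle = 41:47)
  expect_equal(nrow(assemble_events(m3, hyp, grid)), 0)
})

test_that("detection is deterministic and invariant to amplitude scale", {
  pl <- plan_events(rep(c("N2", "N3", "REM"), 7), n = 4, duration_s = 4,
                    gain = 4, with_emg = c(TRUE, FALSE), seed = 14)
  syn <- synth_psg(synth_spec(duration_s = 630, events = pl, seed = 14,
                              stages = rep(c("N2", "N3", "REM"), 7)))
  ev1 <- quiet_detect(syn$recording, syn$hypnogram)
  ev2 <- quiet_detect(syn$recording, syn$hypnogram)
  expect_identical(ev1, ev2)

  for (scale in c(0.1, 10)) {
    rec <- syn$recording
    rec$signals <- rec$signals * scale
    expect_identical(quiet_detect(rec, syn$hypnogram), ev1)
  }
})

test_that("without EMG channels no REM events appear and nothing is EMG-associated", {
  pl <- plan_events(rep(c("N2", "REM"), 10), n = 4, duration_s = 4,
                    gain = 5, with_emg = TRUE, seed = 15)
  syn <- synth_psg(synth_spec(duration_s = 600, events = pl, n_emg = 0,
                              seed = 15, stages = rep(c("N2", "REM"), 10)))
  ev <- quiet_detect(syn$recording, syn$hypnogram)
  expect_false(any(ev$emg_associated))
  expect_false(any(ev$stage == "REM"))
})

test_that("emg_only restricts output to EMG-associated events", {
  pl <- plan_events(rep("N2", 20), n = 4, duration_s = 4, gain = 4,
                    with_emg = c(TRUE, FALSE), seed = 16)
  syn <- synth_psg(synth_spec(duration_s = 600, events = pl, seed = 16,
                              stages = rep("N2", 20)))
  all_ev <- quiet_detect(syn$recording, syn$hypnogram)
  emg_ev <- quiet_detect(syn$recording, syn$hypnogram, emg_only = TRUE)
  expect_true(all(emg_ev$emg_associated))
  expect_true(nrow(emg_ev) < nrow(all_ev))
  expect_equal(emg_ev$onset_s, all_ev$onset_s[all_ev$emg_associated])
})
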