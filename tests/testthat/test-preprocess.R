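test_that("lowpass keeps DC, kills the stopband, preserves length", {
  fs <- 500
  w <- list(fs = fs, samples = rep(80, 3000))
  y <- lowpass_fir(w)
  expect_equal(length(y$samples), 3000)
  expect_true(all(abs(y$samples - 80) < 1e-3 * 80))
  # 45 Hz tone: frequency response of the tap vector by direct DTFT sum
  taps <- signal::fir1(100, 20 / (fs / 2), type = "low")
  H45 <- sum(taps * exp(-1i * 2 * pi * 45 * (0:100) / fs))
  expect_lt(Mod(H45), 0.05)
  t <- (0:2999) / fs
  tone <- list(fs = fs, samples = sin(2 * pi * 45 * t))
  out <- lowpass_fir(tone)$samples
  expect_lt(max(abs(out[200:2800])), 0.05)
  expect_error(lowpass_fir(w, cutoff = 300), "fs/2")
  expect_error(lowpass_fir(w, n_taps = 100), "odd")
})

test_that("zero-phase filtering leaves passband tones unshifted and is idempotent", {
  fs <- 500
  t <- (0:4999) / fs
  x <- 5 * sin(2 * pi * 0.5 * t)
  y1 <- lowpass_fir(list(fs = fs, samples = x))$samples
  core <- 500:4500
  # no phase delay: the filtered tone tracks the input sample-for-sample
  expect_lt(max(abs(y1[core] - x[core])), 1e-3 * 5)
  # idempotence on a signal band-limited to the flat part of the passband
  drift <- 80 + 3 * sin(2 * pi * 0.02 * t)
  z1 <- lowpass_fir(list(fs = fs, samples = drift))$samples
  z2 <- lowpass_fir(list(fs = fs, samples = z1))$samples
  expect_lt(max(abs(z2[core] - z1[core])) / max(abs(z1)), 1e-6)
})

test_that("beat detection counts feet at the pulse rate", {
  fs <- 500
  subj <- subject_params("D", 6, baseline_hr = 60, noise_sd = 0,
                         wander_amp = 0, seed = 2)
  x <- unlist(replicate(12, synth_beat(subj, 1, fs), simplify = FALSE))
  x <- x[1:(10 * fs)]  # 10 s at 60 bpm
  beats <- detect_beats(lowpass_fir(list(fs = fs, samples = x)))
  expect_true(abs(nrow(beats) - 9) <= 1)
  expect_true(all(diff(beats$start) > 0))
  gaps <- (beats$end - beats$start) / fs
  expect_true(all(gaps >= 0.3 & gaps <= 2))
})

test_that("flat or too-short input yields no beats", {
  fs <- 500
  expect_equal(nrow(detect_beats(list(fs = fs, samples = rep(70, 5000)))), 0)
  expect_equal(nrow(detect_beats(list(fs = fs, samples = rep(70, 100)))), 0)
})

test_that("landmarks match analytic root-found positions within one sample", {
  fs <- 500
  subj <- subject_params("O", 6, noise_sd = 0, wander_amp = 0, seed = 3)
  for (crm in c(0, 0.25, 0.5, 0.75, 1)) {
    x <- synth_beat(subj, crm, fs)
    seg <- c(x, x[1])
    lm <- locate_landmarks(seg, fs)
    o <- beat_oracle(subj, crm)
    expect_true(lm$valid)
    expect_lt(abs((lm$iB - lm$iA) - o$tB * fs), 1.0 + 1e-9)
    expect_lt(abs((lm$iC - lm$iA) - o$tC * fs), 1.0 + 1e-9)
    expect_lt(abs((lm$iD - lm$iA) - o$tD * fs), 1.0 + 1e-9)
  }
})

test_that("beats without a post-peak curvature reversal are excluded", {
  fs <- 500
  # concave rise-and-fall arc: second derivative never turns positive
  t <- seq(0, pi, length.out = 400)
  seg <- 70 + 40 * sin(t)
  lm <- locate_landmarks(seg, fs)
  expect_false(lm$valid)
  expect_equal(lm$exclusion_reason, "no_inflection")
  expect_equal(locate_landmarks(c(1, 2, 3), fs)$exclusion_reason, "malformed")
})

test_that("with several post-peak inflections only the first is kept", {
  fs <- 500
  t <- (0:499) / fs
  g <- function(mu, sig) exp(-(t - mu)^2 / (2 * sig^2))
  # three bumps -> two curvature reversals after the systolic peak
  seg <- 70 + 40 * (g(0.15, 0.04) + 0.5 * g(0.38, 0.05) + 0.45 * g(0.65, 0.06))
  lm <- locate_landmarks(seg, fs)
  expect_true(lm$valid)
  # first reversal sits between the systolic peak and the second bump
  expect_gt(lm$iD, lm$iC)
  expect_lt(lm$iD, 0.38 * fs)
  # a later reversal exists too (between bumps two and three)
  s <- stats::filter(seg, rep(1 / 5, 5), sides = 2)
  d2 <- c(NA, diff(diff(as.numeric(s))), NA)
  idx <- (lm$iD + 25):(length(seg) - 10)
  later <- any(d2[idx] < 0 & d2[idx + 1] > 0, na.rm = TRUE)
  expect_true(later)
})

test_that("landmark ordering and half-rise placement hold across a cohort", {
  proto <- make_protocol(step_duration = 8)
  for (seed in 1:3) {
    subj <- sample_cohort(1, 6, seed = seed)[[1]]
    sess <- simulate_session(subj, proto)
    filt <- lowpass_fir(sess$waveform)
    beats <- detect_beats(filt)
    for (b in seq_len(nrow(beats))) {
      seg <- filt$samples[beats$start[b]:beats$end[b]]
      lm <- locate_landmarks(seg, sess$waveform$fs)
      if (!lm$valid) next
      expect_true(lm$iA < lm$iB && lm$iB < lm$iC &&
                    lm$iC < lm$iD && lm$iD < lm$iA_next)
      # half-rise pressure within one inter-sample step of the midpoint
      mid <- (seg[lm$iA] + seg[lm$iC]) / 2
      local_step <- abs(seg[lm$iB] - seg[lm$iB - 1])
      expect_lte(abs(seg[lm$iB] - mid), local_step + 1e-12)
    }
  }
})
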