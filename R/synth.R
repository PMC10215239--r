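#' @importFrom stats rnorm runif quantile sd
NULL

# Fractions of baseline retained at full decompensation (CRM = 0):
# pulse pressure shrinks to 50%, half-rise->inflection delay to 55%,
# and heart rate rises by 40%. These effect sizes define the simulated
# physiology and are shared by the generator and its documentation.
.crm_effects <- list(pp_floor = 0.50, delay_floor = 0.55, hr_gain = 0.40)

#' Construct a synthetic LBNP subject
#'
#' @param subject_id Character id.
#' @param hdd_step Step (4..8 in the default cohort) at which the subject
#'   reaches hemodynamic decompensation.
#' @param baseline_sys,baseline_dia Baseline systolic/diastolic pressure, mmHg.
#' @param baseline_hr Baseline heart rate, beats/min (40..120).
#' @param hrip_base Baseline half-rise to inflection-point delay, seconds.
#' @param noise_sd Additive Gaussian measurement noise sd, mmHg.
#' @param wander_amp Amplitude of the 0.2 Hz baseline wander sinusoid, mmHg.
#' @param seed Integer seed controlling all of this subject's randomness.
#' @return List of class `crm_subject`.
#' @export
subject_params <- function(subject_id, hdd_step,
                           baseline_sys = 120, baseline_dia = 75,
                           baseline_hr = 65, hrip_base = 0.25,
                           noise_sd = 1.0, wander_amp = 2.0, seed = 1L) {
  stopifnot(baseline_sys > baseline_dia, baseline_dia > 0,
            baseline_hr >= 40, baseline_hr <= 120,
            hrip_base > 0, noise_sd >= 0, wander_amp >= 0)
  structure(list(subject_id = as.character(subject_id),
                 hdd_step = as.integer(hdd_step),
                 baseline_sys = baseline_sys, baseline_dia = baseline_dia,
                 baseline_hr = baseline_hr, hrip_base = hrip_base,
                 noise_sd = noise_sd, wander_amp = wander_amp,
                 seed = as.integer(seed)),
            class = "crm_subject")
}

#' Analytic beat-shape parameters at a given CRM
#'
#' The noise-free pulse is modelled as two positive log-concave (Gaussian)
#' components -- the systolic wave and a delayed reflected wave -- on a
#' slowly decaying diastolic baseline. As CRM falls, pulse pressure
#' shrinks, heart rate rises, and the systolic wave narrows (faster
#' ejection), which advances the first post-systolic curvature reversal
#' and thus shortens the half-rise to inflection delay; the reflected
#' wave arrives correspondingly earlier. The morphological features the
#' models must learn therefore genuinely carry the label.
#'
#' @param subject A `crm_subject`.
#' @param crm CRM value in \[0, 1\].
#' @return List with period `T`, pulse pressure `pp`, component centres
#'   `t1`, `t2`, widths `sig1`, `sig2`, reflected amplitude ratio `r`,
#'   diastolic decay amplitude `c0` and rate `k`.
#' @export
beat_model_params <- function(subject, crm) {
  if (crm < 0 || crm > 1) stop("crm outside [0,1]")
  e <- .crm_effects
  hr <- subject$baseline_hr * (1 + e$hr_gain * (1 - crm))
  pp0 <- subject$baseline_sys - subject$baseline_dia
  period <- 60 / hr
  # systolic width carries the half-rise->inflection timing: the B->D
  # delay of the sampled beat is ~2.2 sigma1, so sigma1 is scaled to the
  # subject's baseline delay and its CRM-dependent contraction
  sig1 <- subject$hrip_base *
    (e$delay_floor + (1 - e$delay_floor) * crm) / 2.2
  t1 <- max(0.12, 2 * sig1)
  sig2 <- 0.05
  list(T = period,
       pp = pp0 * (e$pp_floor + (1 - e$pp_floor) * crm),
       t1 = t1, sig1 = sig1,
       t2 = t1 + sig1 + sig2 + 0.03,   # reflected wave beyond the D crossing
       sig2 = sig2, r = 0.35,
       c0 = 0.06, k = 2 / period)
}

# Unit-amplitude beat shape (before pressure scaling); vectorised over t.
.beat_shape <- function(t, p) {
  k <- p$k
  exp(-(t - p$t1)^2 / (2 * p$sig1^2)) +
    p$r * exp(-(t - p$t2)^2 / (2 * p$sig2^2)) +
    p$c0 * exp(-k * t)
}

#' Synthesize one cardiac cycle
#'
#' Samples the analytic two-component beat model on a uniform grid and
#' rescales it so that (peak - foot) pressure equals the CRM-dependent
#' pulse pressure exactly and the foot sits at the subject's diastolic
#' pressure. Gaussian measurement noise of sd `noise_sd` is added unless
#' overridden.
#'
#' @inheritParams beat_model_params
#' @param fs Sampling rate, Hz.
#' @param noise_sd Noise sd in mmHg; defaults to the subject's.
#' @return Numeric vector of pressures (mmHg) covering one beat period.
#' @export
synth_beat <- function(subject, crm, fs = 500, noise_sd = subject$noise_sd) {
  p <- beat_model_params(subject, crm)
  n <- round(p$T * fs)
  t <- (seq_len(n) - 1) / fs
  s <- .beat_shape(t, p)
  amp <- p$pp / (max(s) - min(s))
  x <- subject$baseline_dia + amp * (s - min(s))
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  x
}

#' Simulate one LBNP session
#'
#' Generates the concatenated beat train for steps 1..`hdd_step`, truncating
#' the protocol at the subject's decompensation step. Each step is filled
#' with whole beats at that step's CRM until the step duration is reached
#' (so the session length matches the summed durations to within one beat
#' period). A low-frequency sinusoidal baseline wander is added across the
#' whole session. Fully reproducible from the subject's seed.
#'
#' @param subject A `crm_subject`.
#' @param protocol Protocol from [make_protocol()].
#' @param fs Sampling rate, Hz.
#' @return List of class `crm_session` with elements `waveform` (list with
#'   `fs`, `samples`), `beats` (data.frame: per-beat `start` sample, `step`,
#'   `crm`), `steps` (data.frame: `step`, `crm`, `start`, `end` sample
#'   boundaries) and `subject`.
#' @export
simulate_session <- function(subject, protocol, fs = 500) {
  if (subject$hdd_step > nrow(protocol))
    stop("subject hdd_step outside protocol")
  set.seed(subject$seed)
  samples <- vector("list", subject$hdd_step)
  beat_start <- integer(0); beat_step <- integer(0); beat_crm <- numeric(0)
  step_rows <- vector("list", subject$hdd_step)
  pos <- 0L
  for (s in seq_len(subject$hdd_step)) {
    crm <- crm_label(s, subject$hdd_step, protocol)
    need <- round(protocol$duration[s] * fs)
    got <- 0L
    chunk <- list()
    while (got < need) {
      b <- synth_beat(subject, crm, fs)
      beat_start <- c(beat_start, pos + got + 1L)
      beat_step <- c(beat_step, s)
      beat_crm <- c(beat_crm, crm)
      chunk[[length(chunk) + 1L]] <- b
      got <- got + length(b)
    }
    samples[[s]] <- unlist(chunk)
    step_rows[[s]] <- data.frame(step = s, crm = crm,
                                 start = pos + 1L, end = pos + got)
    pos <- pos + got
  }
  x <- unlist(samples)
  if (subject$wander_amp > 0) {
    tt <- (seq_along(x) - 1) / fs
    phase <- runif(1, 0, 2 * pi)
    x <- x + subject$wander_amp * sin(2 * pi * 0.2 * tt + phase)
  }
  structure(list(waveform = list(fs = fs, samples = x),
                 beats = data.frame(start = beat_start, step = beat_step,
                                    crm = beat_crm),
                 steps = do.call(rbind, step_rows),
                 subject = subject),
            class = "crm_session")
}

#' Sample a balanced synthetic cohort
#'
#' Draws subject-level parameters from population distributions typical of
#' healthy adults (systolic ~ N(125, 10) mmHg, pulse pressure ~ N(45, 6)
#' mmHg, heart rate ~ N(65, 8) bpm, half-rise to inflection delay
#' ~ N(0.25, 0.025) s, all truncated to physiologic ranges) with an equal
#' number of subjects per decompensation-step group. Per-subject seeds are
#' derived deterministically from the cohort seed.
#'
#' @param n_per_group Subjects per decompensation-step group (>= 1).
#' @param groups Integer vector of decompensation steps, default 4..8.
#' @param seed Cohort seed.
#' @param noise_sd,wander_amp Measurement noise sd and wander amplitude
#'   (mmHg) shared by all subjects.
#' @return List of `crm_subject`, length `n_per_group * length(groups)`.
#' @export
sample_cohort <- function(n_per_group, groups = 4:8, seed = 1L,
                          noise_sd = 1.0, wander_amp = 2.0) {
  stopifnot(n_per_group >= 1)
  if (length(groups) == 0) stop("groups must be non-empty")
  set.seed(seed)
  n <- n_per_group * length(groups)
  sys <- pmin(pmax(rnorm(n, 125, 10), 100), 160)
  pp0 <- pmin(pmax(rnorm(n, 45, 6), 30), 60)
  hr <- pmin(pmax(rnorm(n, 65, 8), 50), 85)
  hrip <- pmin(pmax(rnorm(n, 0.25, 0.025), 0.18), 0.30)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  i <- 0L
  for (g in groups) for (j in seq_len(n_per_group)) {
    i <- i + 1L
    out[[i]] <- subject_params(
      subject_id = sprintf("S%02d_g%d", i, g), hdd_step = g,
      baseline_sys = sys[i], baseline_dia = sys[i] - pp0[i],
      baseline_hr = hr[i], hrip_base = hrip[i],
      noise_sd = noise_sd, wander_amp = wander_amp, seed = seeds[i])
  }
  out
}
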