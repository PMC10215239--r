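.phases5 <- c("sys_rise", "sys_dec", "sys", "dec", "dia")
.phases6 <- c(.phases5, "pp")

#' The canonical 54-feature registry
#'
#' Names, categories, units and formula sketches for every per-beat
#' morphological feature. The registry is the single source of truth for
#' feature order: feature tables, rankings and model specs all refer to
#' these names. The catalogue partitions as 7 individual, 6 time-duration,
#' 5 average-pressure, 5 area, 10 normalized-area, 18 NODIA (pressure
#' re-referenced to the inflection point) and 3 slope features.
#'
#' Phases are delimited by the landmarks: `sys_rise` = foot A to systolic
#' peak C, `sys_dec` = C to inflection D, `sys` = A to D, `dec` = C to next
#' foot A', `dia` = D to A', and `pp` = the full beat A to A'.
#'
#' @return data.frame with columns `name`, `category`, `unit`, `formula`.
#' @export
feature_registry <- function() {
  rows <- list(
    c("sys_pressure",  "individual", "mmHg", "P(C)"),
    c("dia_pressure",  "individual", "mmHg", "P(A)"),
    c("infl_pressure", "individual", "mmHg", "P(D)"),
    c("PP",            "individual", "mmHg", "P(C) - P(A)"),
    c("PPI",           "individual", "s",    "beat period A to A'"),
    c("HR",            "individual", "beats/min", "60 / PPI"),
    c("SI",            "individual", "1",    "(P(D) - P(A)) / PP"),
    c("t_sys_rise",    "time", "s", "t(C) - t(A)"),
    c("t_sys_dec",     "time", "s", "t(D) - t(C)"),
    c("t_sys",         "time", "s", "t(D) - t(A)"),
    c("t_dec",         "time", "s", "t(A') - t(C)"),
    c("t_dia",         "time", "s", "t(A') - t(D)"),
    c("HRIP",          "time", "s", "t(D) - t(B)"))
  for (ph in .phases5)
    rows[[length(rows) + 1]] <- c(paste0("avg_", ph), "average", "mmHg",
                                  sprintf("mean P over %s", ph))
  for (ph in .phases5)
    rows[[length(rows) + 1]] <- c(paste0(ph, "_area"), "area", "mmHg*s",
                                  sprintf("trapezoid integral of P over %s", ph))
  for (ph in .phases5)
    rows[[length(rows) + 1]] <- c(paste0(ph, "_area_norm"), "normalized", "mmHg",
                                  sprintf("%s_area / phase sample count", ph))
  for (ph in .phases5)
    rows[[length(rows) + 1]] <- c(paste0(ph, "_area_norm_beat"), "normalized",
                                  "mmHg",
                                  sprintf("%s_area / beat sample count", ph))
  for (ph in .phases6)
    rows[[length(rows) + 1]] <- c(paste0(ph, "_area_nodia"), "nodia", "mmHg*s",
                                  sprintf("integral of P - P(D) over %s", ph))
  for (ph in .phases6)
    rows[[length(rows) + 1]] <- c(paste0("avg_", ph, "_nodia"), "nodia", "mmHg",
                                  sprintf("mean of P - P(D) over %s", ph))
  for (ph in .phases6)
    rows[[length(rows) + 1]] <- c(paste0(ph, "_area_norm_nodia"), "nodia",
                                  "mmHg",
                                  sprintf("%s_area_nodia / phase sample count", ph))
  rows[[length(rows) + 1]] <- c("slope_sys", "slope", "mmHg/s",
                                "(P(C) - P(A)) / t_sys_rise")
  rows[[length(rows) + 1]] <- c("slope_desc_sys", "slope", "mmHg/s",
                                "(P(D) - P(C)) / t_sys_dec")
  rows[[length(rows) + 1]] <- c("slope_dia", "slope", "mmHg/s",
                                "(P(A') - P(D)) / t_dia")
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "category", "unit", "formula")
  out
}

# trapezoidal integral of x over indices idx at sampling rate fs
.trapz <- function(x, idx, fs) {
  v <- x[idx]
  (sum(v) - (v[1] + v[length(v)]) / 2) / fs
}

#' Extract the 54-feature vector from one beat
#'
#' @param x Beat samples (foot to next foot inclusive), mmHg.
#' @param lm Landmarks from [locate_landmarks()]; must be valid.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector of length 54 in registry order.
#' @export
extract_features <- function(x, lm, fs) {
  if (!isTRUE(lm$valid)) stop("landmarks invalid: ", lm$exclusion_reason)
  A <- lm$iA; B <- lm$iB; C <- lm$iC; D <- lm$iD; A2 <- lm$iA_next
  if (C <= A || D <= C || A2 <= D) stop("zero-duration phase")
  phase_idx <- list(sys_rise = A:C, sys_dec = C:D, sys = A:D,
                    dec = C:A2, dia = D:A2, pp = A:A2)
  nbeat <- A2 - A + 1L
  f <- c(sys_pressure = x[C], dia_pressure = x[A], infl_pressure = x[D],
         PP = x[C] - x[A], PPI = (A2 - A) / fs, HR = 60 * fs / (A2 - A),
         SI = (x[D] - x[A]) / (x[C] - x[A]),
         t_sys_rise = (C - A) / fs, t_sys_dec = (D - C) / fs,
         t_sys = (D - A) / fs, t_dec = (A2 - C) / fs, t_dia = (A2 - D) / fs,
         HRIP = (D - B) / fs)
  for (ph in .phases5) f[paste0("avg_", ph)] <- mean(x[phase_idx[[ph]]])
  for (ph in .phases5) f[paste0(ph, "_area")] <- .trapz(x, phase_idx[[ph]], fs)
  for (ph in .phases5)
    f[paste0(ph, "_area_norm")] <-
      f[[paste0(ph, "_area")]] / length(phase_idx[[ph]])
  for (ph in .phases5)
    f[paste0(ph, "_area_norm_beat")] <- f[[paste0(ph, "_area")]] / nbeat
  y <- x - x[D]
  for (ph in .phases6) f[paste0(ph, "_area_nodia")] <- .trapz(y, phase_idx[[ph]], fs)
  for (ph in .phases6) f[paste0("avg_", ph, "_nodia")] <- mean(y[phase_idx[[ph]]])
  for (ph in .phases6)
    f[paste0(ph, "_area_norm_nodia")] <-
      f[[paste0(ph, "_area_nodia")]] / length(phase_idx[[ph]])
  f["slope_sys"] <- (x[C] - x[A]) / ((C - A) / fs)
  f["slope_desc_sys"] <- (x[D] - x[C]) / ((D - C) / fs)
  f["slope_dia"] <- (x[A2] - x[D]) / ((A2 - D) / fs)
  f[feature_registry()$name]
}

#' Build a labeled feature table from simulated sessions
#'
#' Runs each session through the lowpass filter, beat detection and
#' landmark location, extracts the 54 features for every valid beat, and
#' attaches the subject id, decompensation group, protocol step and
#' ground-truth CRM label (a detected beat inherits the step whose
#' boundaries contain its foot). Invalid beats are dropped and counted.
#'
#' @param sessions List of `crm_session` objects (or a single one).
#' @param cutoff,n_taps Lowpass filter settings, see [lowpass_fir()].
#' @return data.frame with columns `subject_id`, `group`, `step`, `crm`
#'   and the 54 registry features, one row per retained beat, ordered by
#'   subject then time. The exclusion log (counts by reason) is attached
#'   as attribute `"exclusions"`.
#' @export
build_table <- function(sessions, cutoff = 20, n_taps = 101L) {
  if (inherits(sessions, "crm_session")) sessions <- list(sessions)
  reg <- feature_registry()$name
  per_sess <- vector("list", length(sessions))
  excl <- c(no_inflection = 0L, malformed = 0L)
  for (si in seq_along(sessions)) {
    sess <- sessions[[si]]
    fs <- sess$waveform$fs
    filt <- lowpass_fir(sess$waveform, cutoff = cutoff, n_taps = n_taps)
    beats <- detect_beats(filt)
    if (nrow(beats) == 0) next
    # step containing each beat's foot
    st <- findInterval(beats$start, sess$steps$start)
    st[beats$start > sess$steps$end[nrow(sess$steps)]] <- NA_integer_
    fmat <- matrix(NA_real_, nrow(beats), length(reg))
    keep <- logical(nrow(beats))
    for (b in seq_len(nrow(beats))) {
      if (is.na(st[b])) next
      seg <- filt$samples[beats$start[b]:beats$end[b]]
      lm <- locate_landmarks(seg, fs)
      if (!lm$valid) {
        excl[lm$exclusion_reason] <- excl[lm$exclusion_reason] + 1L
        next
      }
      fmat[b, ] <- extract_features(seg, lm, fs)
      keep[b] <- TRUE
    }
    if (!any(keep)) next
    d <- as.data.frame(fmat[keep, , drop = FALSE])
    names(d) <- reg
    per_sess[[si]] <- cbind(
      data.frame(subject_id = sess$subject$subject_id,
                 group = sess$subject$hdd_step, step = st[keep],
                 crm = sess$steps$crm[st[keep]],
                 stringsAsFactors = FALSE),
      d)
  }
  per_sess <- per_sess[!vapply(per_sess, is.null, logical(1))]
  if (!length(per_sess)) stop("all beats invalid or no beats detected")
  tab <- do.call(rbind, per_sess)
  rownames(tab) <- NULL
  attr(tab, "exclusions") <- excl
  tab
}
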