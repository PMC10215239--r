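#' @importFrom signal fir1
#' @importFrom pracma findpeaks
NULL

#' Zero-phase windowed-sinc lowpass filter
#'
#' Applies a Hamming-window FIR lowpass (unit DC gain) with the filter
#' centred on each sample, so there is no net phase delay. Edges are
#' padded by replicating the end samples; output length equals input
#' length.
#'
#' @param w Waveform: list with `fs` (Hz) and `samples` (mmHg).
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < fs/2).
#' @param n_taps Odd number of filter taps.
#' @return Filtered waveform in the same list form.
#' @export
lowpass_fir <- function(w, cutoff = 20, n_taps = 101L) {
  fs <- w$fs
  if (cutoff <= 0 || cutoff >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  if (n_taps %% 2 == 0) stop("n_taps must be odd")
  taps <- signal::fir1(n_taps - 1L, cutoff / (fs / 2), type = "low")
  taps <- taps / sum(taps)   # exact unit gain at DC
  x <- w$samples
  pad <- (n_taps - 1L) / 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  y <- stats::filter(xp, taps, method = "convolution", sides = 2)
  y <- as.numeric(y[(pad + 1L):(pad + length(x))])
  list(fs = fs, samples = y)
}

#' Segment a filtered waveform into foot-to-foot beats
#'
#' Pulse feet are located from the first derivative: each beat's maximal
#' upslope shows as a derivative peak, and the foot is the pressure minimum
#' in the window immediately preceding it. A 0.3 s refractory period
#' suppresses secondary derivative peaks within a beat. Beats are delimited
#' foot-to-foot; the trailing incomplete beat is discarded.
#'
#' @param w Filtered waveform (list with `fs`, `samples`).
#' @param refractory Minimum spacing between upslope peaks, seconds.
#' @return data.frame with columns `start`, `end`: 1-based sample indices
#'   of consecutive feet (a beat spans `start..end` inclusive, `end` being
#'   the next beat's foot). Zero rows for flat or too-short input.
#' @export
detect_beats <- function(w, refractory = 0.3) {
  x <- w$samples
  fs <- w$fs
  empty <- data.frame(start = integer(0), end = integer(0))
  if (length(x) < 2 * fs) return(empty)
  dx <- diff(x)
  top <- max(dx)
  # absolute floor keeps pure-noise derivatives from producing beats
  thr <- max(0.25 * top, 25 / fs)
  if (top < 25 / fs) return(empty)
  pk <- pracma::findpeaks(dx, minpeakheight = thr,
                          minpeakdistance = round(refractory * fs))
  if (is.null(pk) || nrow(pk) == 0) return(empty)
  up <- sort(pk[, 2])
  win <- as.integer(round(refractory * fs))
  feet <- vapply(up, function(i) {
    i <- as.integer(i)
    lo <- max(1L, i - win)
    lo + which.min(x[lo:i]) - 1L
  }, integer(1))
  feet <- unique(feet)
  if (length(feet) < 2) return(empty)
  data.frame(start = feet[-length(feet)], end = feet[-1])
}

# 5-point moving average used before the second-derivative sign test.
.smooth5 <- function(x) {
  as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
}

#' Locate pulse landmarks A, B, C, D within one beat
#'
#' Landmarks on a foot-to-foot beat segment: the pulse foot A (segment
#' start), the systolic peak C (global maximum), the half-rise B (first
#' rising-limb sample at or above the A-C amplitude midpoint), and the
#' post-systolic inflection D (first sample after C where the second
#' derivative of the smoothed beat crosses zero from negative to
#' positive). Beats with no such crossing before the next foot are flagged
#' invalid with reason `no_inflection` and excluded from analysis; when
#' several crossings exist only the first is kept.
#'
#' @param x Numeric vector: beat samples from foot to next foot inclusive.
#' @param fs Sampling rate, Hz.
#' @return List of class `crm_landmarks`: `iA`, `iB`, `iC`, `iD`,
#'   `iA_next` (1-based indices into `x`), `valid`, `exclusion_reason`
#'   (one of `"none"`, `"no_inflection"`, `"malformed"`).
#' @export
locate_landmarks <- function(x, fs) {
  bad <- function(reason) structure(
    list(iA = NA_integer_, iB = NA_integer_, iC = NA_integer_,
         iD = NA_integer_, iA_next = length(x), valid = FALSE,
         exclusion_reason = reason),
    class = "crm_landmarks")
  n <- length(x)
  if (n < 5) return(bad("malformed"))
  iA <- 1L
  iA_next <- n
  iC <- which.max(x)
  if (iC <= iA + 1L || iC >= iA_next) return(bad("malformed"))
  mid <- (x[iA] + x[iC]) / 2
  iB <- iA + which(x[(iA + 1L):iC] >= mid)[1]
  if (is.na(iB) || iB >= iC) return(bad("malformed"))
  s <- .smooth5(x)
  d2 <- c(NA, diff(diff(s)), NA)  # d2[i] ~ s[i-1] - 2 s[i] + s[i+1]
  lo <- iC + 1L
  hi <- iA_next - 1L
  iD <- NA_integer_
  if (hi > lo) {
    seg <- lo:(hi - 1L)
    cross <- seg[!is.na(d2[seg]) & !is.na(d2[seg + 1L]) &
                   d2[seg] < 0 & d2[seg + 1L] > 0]
    if (length(cross)) iD <- cross[1] + 1L
  }
  if (is.na(iD)) return(bad("no_inflection"))
  structure(list(iA = iA, iB = as.integer(iB), iC = as.integer(iC),
                 iD = as.integer(iD), iA_next = as.integer(iA_next),
                 valid = TRUE, exclusion_reason = "none"),
            class = "crm_landmarks")
}
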