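#' Default LBNP staircase pressures (mmHg)
#'
#' Canonical 9-step lower-body-negative-pressure ladder running from the
#' 0 mmHg baseline down to -100 mmHg. Step 1 is always baseline.
#'
#' @format Numeric vector of length 9, strictly decreasing.
#' @export
lbnp_default_ladder <- c(0, -15, -30, -45, -60, -70, -80, -90, -100)

#' Build an LBNP staircase protocol
#'
#' An LBNP session applies progressively more negative chamber pressure in
#' discrete steps of fixed duration. The default reproduces the standard
#' 9-step profile (baseline 0 mmHg down to -100 mmHg, 5 min per step).
#'
#' @param n_steps Number of steps including baseline (>= 1).
#' @param min_pressure Final (most negative) chamber pressure in mmHg (<= 0).
#' @param step_duration Duration of every step in seconds (> 0).
#' @param ladder Optional custom pressure ladder (mmHg); must start at 0,
#'   end at `min_pressure`, and be strictly decreasing. When `NULL` the
#'   canonical ladder is used for the 9-step default, otherwise pressures
#'   are spaced linearly.
#' @return A data.frame with one row per step and columns `index`,
#'   `pressure` (mmHg) and `duration` (s), of class `crm_protocol`.
#' @examples
#' make_protocol()            # 9 steps, 0 .. -100 mmHg, 300 s each
#' make_protocol(n_steps = 1) # degenerate baseline-only protocol
#' @export
make_protocol <- function(n_steps = 9L, min_pressure = -100, step_duration = 300,
                          ladder = NULL) {
  stopifnot(n_steps >= 1, min_pressure <= 0, step_duration > 0)
  if (!is.null(ladder)) {
    if (length(ladder) != n_steps)
      stop("custom ladder length must equal n_steps")
    if (ladder[1] != 0)
      stop("protocol must start at 0 mmHg baseline")
    if (n_steps > 1 && any(diff(ladder) >= 0))
      stop("protocol pressures must be strictly decreasing")
    pressures <- as.numeric(ladder)
  } else if (n_steps == 9L && min_pressure == -100) {
    pressures <- lbnp_default_ladder
  } else if (n_steps == 1L) {
    pressures <- 0
  } else {
    pressures <- seq(0, min_pressure, length.out = n_steps)
    if (any(diff(pressures) >= 0))
      stop("protocol pressures must be strictly decreasing")
  }
  proto <- data.frame(index = seq_len(n_steps),
                      pressure = pressures,
                      duration = rep(as.numeric(step_duration), n_steps))
  class(proto) <- c("crm_protocol", "data.frame")
  proto
}

#' Ground-truth CRM label for a protocol step
#'
#' The compensatory reserve measurement is defined relative to the subject's
#' own decompensation pressure: `CRM = 1 - LBNP / LBNP_HDD`, where `LBNP` is
#' the chamber pressure at the current step and `LBNP_HDD` the pressure of
#' the step at which the subject decompensates. CRM is 1 at baseline and 0
#' at the decompensation step.
#'
#' @param step_index Step number (1-based, 1 = baseline).
#' @param hdd_step Index of the subject's hemodynamic decompensation step.
#' @param protocol Protocol from [make_protocol()].
#' @return CRM label in \[0, 1\].
#' @export
crm_label <- function(step_index, hdd_step, protocol) {
  if (hdd_step > nrow(protocol) || hdd_step < 2)
    stop("hdd_step outside protocol")
  if (any(step_index > hdd_step) || any(step_index < 1))
    stop("step_index must lie in 1..hdd_step")
  p <- protocol$pressure[step_index]
  p_hdd <- protocol$pressure[hdd_step]
  1 - p / p_hdd
}
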