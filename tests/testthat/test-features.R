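test_that("registry holds 54 features in the canonical partition", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 54)
  expect_equal(anyDuplicated(reg$name), 0)
  counts <- table(reg$category)
  expect_equal(as.integer(counts[c("individual", "time", "average", "area",
                                   "normalized", "nodia", "slope")]),
               c(7L, 6L, 5L, 5L, 10L, 18L, 3L))
})

test_that("every valid beat yields exactly the 54 registry features, finite", {
  tab <- clean_session()$table
  reg <- feature_registry()$name
  expect_true(all(reg %in% names(tab)))
  expect_equal(sum(names(tab) %in% reg), 54)
  expect_true(all(is.finite(as.matrix(tab[, reg]))))
})

test_that("phase areas and averages have their closed form on flat fixtures", {
  fs <- 500
  # synthetic landmark frame over a constant-pressure 'beat'
  lm <- structure(list(iA = 1L, iB = 30L, iC = 100L, iD = 200L,
                       iA_next = 401L, valid = TRUE,
                       exclusion_reason = "none"), class = "crm_landmarks")
  seg <- rep(50, 401)
  f <- extract_features(seg, lm, fs)
  # dia phase: constant c over T seconds -> area c*T, average c
  expect_equal(unname(f["dia_area"]), 50 * (401 - 200) / fs * 1, tolerance = 0.01)
  expect_equal(unname(f["avg_dia"]), 50)
  expect_equal(unname(f["sys_area"]), 50 * (200 - 1) / fs, tolerance = 0.01)
  # whole beat at the inflection pressure -> all NODIA features vanish
  nodia <- grep("nodia", names(f), value = TRUE)
  expect_length(nodia, 18)
  expect_true(all(abs(f[nodia]) < 1e-12))
})

test_that("trapezoidal areas match 10x-oversampled Riemann sums on smooth beats", {
  fs <- 500
  subj <- subject_params("R", 6, noise_sd = 0, wander_amp = 0, seed = 9)
  o <- beat_oracle(subj, 0.7)
  p <- o$params
  n <- round(p$T * fs)
  t <- (seq_len(n) - 1) / fs
  s <- o$shape(t)
  amp <- p$pp / (max(s) - min(s))
  x <- subj$baseline_dia + amp * (s - min(s))
  seg <- c(x, x[1])
  lm <- locate_landmarks(seg, fs)
  f <- extract_features(seg, lm, fs)
  # oversampled Riemann oracle on the continuous model over each phase
  cont <- function(tt) subj$baseline_dia + amp * (o$shape(tt) - min(s))
  riemann <- function(i0, i1) {
    tt <- seq((i0 - 1) / fs, (i1 - 1) / fs, by = 1 / (10 * fs))
    sum(cont(tt)) / (10 * fs)
  }
  expect_equal(unname(f["sys_rise_area"]), riemann(lm$iA, lm$iC),
               tolerance = 0.01)
  expect_equal(unname(f["sys_area"]), riemann(lm$iA, lm$iD), tolerance = 0.01)
  expect_equal(unname(f["dec_area"]), riemann(lm$iC, lm$iA_next),
               tolerance = 0.01)
  expect_equal(unname(f["dia_area"]), riemann(lm$iD, lm$iA_next),
               tolerance = 0.01)
})

test_that("HRIP matches the analytic half-rise to inflection delay", {
  fs <- 500
  subj <- subject_params("H", 6, noise_sd = 0, wander_amp = 0, seed = 13)
  for (crm in c(0.1, 0.5, 0.9)) {
    x <- synth_beat(subj, crm, fs)
    seg <- c(x, x[1])
    lm <- locate_landmarks(seg, fs)
    f <- extract_features(seg, lm, fs)
    o <- beat_oracle(subj, crm)
    expect_lt(abs(f[["HRIP"]] - (o$tD - o$tB)), 2 / fs + 1e-9)
  }
})

test_that("pressure scaling is equivariant where dimensional analysis says so", {
  fs <- 500
  subj <- subject_params("K", 6, noise_sd = 0, wander_amp = 0, seed = 4)
  x <- synth_beat(subj, 0.6, fs)
  seg <- c(x, x[1])
  lm <- locate_landmarks(seg, fs)
  f1 <- extract_features(seg, lm, fs)
  k <- 2.5
  lm2 <- locate_landmarks(k * seg, fs)
  f2 <- extract_features(k * seg, lm2, fs)
  reg <- feature_registry()
  scales_with_pressure <- reg$name[reg$unit %in% c("mmHg", "mmHg*s", "mmHg/s")]
  time_like <- reg$name[reg$unit == "s"]
  expect_equal(unname(f2[scales_with_pressure]),
               unname(k * f1[scales_with_pressure]), tolerance = 1e-8)
  expect_equal(unname(f2[time_like]), unname(f1[time_like]))
  expect_equal(f2[["SI"]], f1[["SI"]], tolerance = 1e-12)
  expect_equal(f2[["HR"]], f1[["HR"]])
})

test_that("feature extraction rejects invalid landmark frames", {
  fs <- 500
  bad <- structure(list(iA = 1L, iB = 2L, iC = 3L, iD = 4L, iA_next = 10L,
                        valid = FALSE, exclusion_reason = "no_inflection"),
                   class = "crm_landmarks")
  expect_error(extract_features(rep(1, 10), bad, fs), "invalid")
  degen <- structure(list(iA = 1L, iB = 2L, iC = 5L, iD = 5L, iA_next = 10L,
                          valid = TRUE, exclusion_reason = "none"),
                     class = "crm_landmarks")
  expect_error(extract_features(rep(1, 10), degen, fs), "zero-duration")
})

test_that("tables keep valid beats only, log exclusions, label from steps", {
  cs <- clean_session()
  tab <- cs$table
  expect_true(all(tab$crm %in% cs$session$steps$crm))
  excl <- attr(tab, "exclusions")
  expect_named(excl, c("no_inflection", "malformed"))
  # row order: time order within subject
  expect_true(all(diff(tab$step) >= 0))
})
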