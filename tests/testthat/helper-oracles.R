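# Independent oracles and shared fixtures for the test suite.
# Oracles deliberately re-derive quantities by brute force (closed forms,
# double loops, exhaustive enumeration) so they cannot share a defect with
# the implementation paths they check.

# ---- analytic beat-model oracle -------------------------------------------

# Continuous beat shape and its exact second derivative for a subject/CRM;
# landmark times found by optimization/root-finding on the closed form.
beat_oracle <- function(subject, crm) {
  p <- beat_model_params(subject, crm)
  s <- function(t) {
    exp(-(t - p$t1)^2 / (2 * p$sig1^2)) +
      p$r * exp(-(t - p$t2)^2 / (2 * p$sig2^2)) +
      p$c0 * exp(-p$k * t)
  }
  d2 <- function(t) {
    g1 <- exp(-(t - p$t1)^2 / (2 * p$sig1^2))
    g2 <- exp(-(t - p$t2)^2 / (2 * p$sig2^2))
    g1 * ((t - p$t1)^2 - p$sig1^2) / p$sig1^4 +
      p$r * g2 * ((t - p$t2)^2 - p$sig2^2) / p$sig2^4 +
      p$c0 * p$k^2 * exp(-p$k * t)
  }
  tC <- stats::optimize(s, c(0, p$t2), maximum = TRUE)$maximum
  mid <- (s(0) + s(tC)) / 2
  tB <- stats::uniroot(function(t) s(t) - mid, c(1e-6, tC))$root
  grid <- seq(tC + 1e-4, p$T - 1e-4, by = 1e-5)
  v <- d2(grid)
  i <- which(v[-length(v)] < 0 & v[-1] > 0)[1]
  tD <- stats::uniroot(d2, c(grid[i], grid[i + 1]))$root
  list(tB = tB, tC = tC, tD = tD, shape = s, d2 = d2, params = p)
}

# ---- brute-force oracles ---------------------------------------------------

# plug-in MI by explicit double loop over the joint histogram
mi_bruteforce <- function(x, y, bins) {
  bx <- eqfreq_bin(x, bins)
  by <- eqfreq_bin(y, bins)
  n <- length(x)
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    pij <- sum(bx == i & by == j) / n
    if (pij > 0) {
      pi_ <- sum(bx == i) / n
      pj_ <- sum(by == j) / n
      mi <- mi + pij * log(pij / (pi_ * pj_))
    }
  }
  mi
}

# exhaustive greedy MRMR: recompute the criterion for every candidate at
# every step, with no caching
mrmr_exhaustive <- function(tab, features, k, bins, scheme = "difference") {
  y <- tab$crm
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(features, sel)
    best <- -Inf; best_f <- NA
    for (f in cand) {
      relv <- mi_bruteforce(tab[[f]], y, bins)
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s2)
          mi_bruteforce(tab[[f]], tab[[s2]], bins), numeric(1)))
      sc <- if (scheme == "difference") relv - red
            else relv / max(red, .Machine$double.eps)
      if (sc > best) { best <- sc; best_f <- f }  # first max wins ties
    }
    sel <- c(sel, best_f)
  }
  sel
}

# naive elementwise-loop metric computations
perfect_naive <- function(y, yhat) {
  n <- length(y)
  sse <- 0; for (i in seq_len(n)) sse <- sse + (yhat[i] - y[i])^2
  mu <- sum(y) / n
  sst <- 0; for (i in seq_len(n)) sst <- sst + (y[i] - mu)^2
  list(P_RMSE = sqrt(sse / n), P_R2 = 1 - sse / sst)
}

linear_naive <- function(y, yhat) {
  n <- length(y)
  mx <- mean(y); my <- mean(yhat)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y[i] - mx) * (yhat[i] - my)
    sxx <- sxx + (y[i] - mx)^2
    syy <- syy + (yhat[i] - my)^2
  }
  m <- sxy / sxx
  b <- my - m * mx
  sse <- 0
  for (i in seq_len(n)) sse <- sse + (yhat[i] - (m * y[i] + b))^2
  list(RMSE = sqrt(sse / n), R2 = sxy^2 / (sxx * syy), m = m, b = b)
}

# ---- shared fixtures (lazily built, cached across test files) -------------

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# short noise-free session + feature table (one subject, hdd step 8)
clean_session <- function() .cached("clean_session", function() {
  subj <- subject_params("CLEAN", 8, noise_sd = 0, wander_amp = 0, seed = 7)
  proto <- make_protocol(step_duration = 12)
  sess <- simulate_session(subj, proto)
  list(session = sess, table = build_table(sess))
})

# small noisy cohort split into train/test feature tables
mini_cohort <- function() .cached("mini_cohort", function() {
  proto <- make_protocol(step_duration = 10)
  cohort <- sample_cohort(3, c(5, 7), seed = 42)
  split <- split_cohort(cohort, train_per_group = 2, test_per_group = 1,
                        seed = 42)
  cfg <- run_config(n_per_group = 3, groups = c(5, 7), train_per_group = 2,
                    test_per_group = 1, step_duration = 10, seed = 42)
  list(split = split,
       train = cohort_features(split$train, proto, cfg),
       test = cohort_features(split$test, proto, cfg))
})

# full-scale stochastic runs used by the recovery and learning-curve checks:
# default cohort structure (12 subjects x groups 4..8, 8:4 split), protocol
# shortened to 30 s steps to keep the suite fast without changing the
# per-beat statistics the models learn from
acceptance_runs <- function(seeds = 1:5) .cached("acceptance_runs", function() {
  lapply(seeds, function(seed) {
    proto <- make_protocol(step_duration = 30)
    cfg <- run_config(step_duration = 30, seed = seed)
    cohort <- sample_cohort(cfg$n_per_group, cfg$groups, seed = seed)
    sp <- split_cohort(cohort, cfg$train_per_group, cfg$test_per_group,
                       seed = seed)
    train_tab <- cohort_features(sp$train, proto, cfg)
    test_tab <- cohort_features(sp$test, proto, cfg)
    ranking <- rank_mrmr(train_tab, k = nrow(feature_registry()))
    top10 <- ranking$name[1:10]
    bag <- fit_crm_model(model_spec("bagged_trees", top10, seed = seed),
                         train_tab)
    fine <- fit_crm_model(model_spec("tree_fine", top10, seed = seed),
                          train_tab)
    pm_bag <- perfect_metrics(test_tab$crm, predict(bag, test_tab))
    pm_fine <- perfect_metrics(test_tab$crm, predict(fine, test_tab))
    # learning-curve point: only 2 training subjects per group
    grp <- vapply(sp$train, function(s) s$hdd_step, integer(1))
    ids2 <- unlist(lapply(split(seq_along(sp$train), grp),
                          function(ix) ix[1:2]))
    small_ids <- vapply(sp$train[ids2], function(s) s$subject_id,
                        character(1))
    small_tab <- train_tab[train_tab$subject_id %in% small_ids, ,
                           drop = FALSE]
    rk2 <- rank_mrmr(small_tab, k = 10)
    bag2 <- fit_crm_model(model_spec("bagged_trees", rk2$name, seed = seed),
                          small_tab)
    pm_small <- perfect_metrics(test_tab$crm, predict(bag2, test_tab))
    list(seed = seed, ranking = ranking,
         hrip_rank = which(ranking$name == "HRIP"),
         test_P_R2 = pm_bag$P_R2, test_P_RMSE = pm_bag$P_RMSE,
         fine_P_RMSE = pm_fine$P_RMSE,
         small_train_P_RMSE = pm_small$P_RMSE,
         n_train = nrow(train_tab), n_test = nrow(test_tab))
  })
})
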