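#' Default run configuration
#'
#' Bundles every knob of the simulate -> preprocess -> extract -> rank ->
#' train -> evaluate pipeline. The defaults reproduce the reference study
#' conditions: groups 4..8, 12 subjects per group split 8 training / 4
#' blind-test, the 9-step protocol at 300 s per step sampled at 500 Hz,
#' a 20 Hz / 101-tap lowpass, MRMR difference scheme, and the six model
#' families swept over the top 15/10/5/1 features.
#'
#' @param n_per_group Subjects generated per decompensation group.
#' @param groups Decompensation-step groups.
#' @param seed Master seed; all cohort and model randomness derives from it.
#' @param step_duration Protocol step length, seconds.
#' @param fs Sampling rate, Hz.
#' @param cutoff,n_taps Lowpass filter settings.
#' @param top_k Feature-count sweep for the model grid.
#' @param train_per_group,test_per_group Subject-level split sizes.
#' @param n_learners Ensemble size.
#' @param selected_k Feature count for the down-selected operating model.
#' @param clamp Clamp predictions to \[0, 1\].
#' @param out_dir Optional output directory for report artifacts.
#' @return List of class `crm_config`.
#' @export
run_config <- function(n_per_group = 12L, groups = 4:8, seed = 1L,
                       step_duration = 300, fs = 500,
                       cutoff = 20, n_taps = 101L,
                       top_k = c(15L, 10L, 5L, 1L),
                       train_per_group = 8L, test_per_group = 4L,
                       n_learners = 30L, selected_k = 10L,
                       clamp = FALSE, out_dir = NULL) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              groups = as.integer(groups), seed = as.integer(seed),
              step_duration = step_duration, fs = fs,
              cutoff = cutoff, n_taps = as.integer(n_taps),
              top_k = as.integer(top_k),
              train_per_group = as.integer(train_per_group),
              test_per_group = as.integer(test_per_group),
              n_learners = as.integer(n_learners),
              selected_k = as.integer(selected_k),
              clamp = isTRUE(clamp), out_dir = out_dir)
  if (cfg$train_per_group + cfg$test_per_group > cfg$n_per_group)
    stop("split sizes exceed subjects per group")
  if (any(cfg$top_k <= 0) || cfg$selected_k <= 0)
    stop("top_k and selected_k must be positive")
  class(cfg) <- c("crm_config", "list")
  cfg
}

# FNV-1a over the serialized config: a light, dependency-free stamp.
# 32-bit arithmetic is done in 16-bit halves to stay inside exact doubles.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")], auto_unbox = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Split a cohort into disjoint train and test subjects per group
#'
#' @param subjects List of `crm_subject` (e.g. from [sample_cohort()]).
#' @param train_per_group,test_per_group Subjects per group in each split.
#' @param seed Seed controlling the random assignment.
#' @return List with `train` and `test`, each a list of `crm_subject`.
#' @export
split_cohort <- function(subjects, train_per_group = 8L, test_per_group = 4L,
                         seed = 1L) {
  grp <- vapply(subjects, function(s) s$hdd_step, integer(1))
  set.seed(seed)
  train <- list(); test <- list()
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    if (length(idx) < train_per_group + test_per_group)
      stop("insufficient subjects in group ", g, ": have ", length(idx),
           ", need ", train_per_group + test_per_group)
    pick <- sample(idx, train_per_group + test_per_group)
    train <- c(train, subjects[pick[seq_len(train_per_group)]])
    test <- c(test, subjects[pick[train_per_group + seq_len(test_per_group)]])
  }
  list(train = train, test = test)
}

.subject_ids <- function(subjects)
  vapply(subjects, function(s) s$subject_id, character(1))

#' Simulate sessions and build the labeled feature table for a subject set
#'
#' @param subjects List of `crm_subject`.
#' @param protocol Protocol from [make_protocol()].
#' @param cfg A `crm_config` (filter and sampling settings are taken from it).
#' @return Feature table as from [build_table()].
#' @export
cohort_features <- function(subjects, protocol, cfg = run_config()) {
  sessions <- lapply(subjects, simulate_session, protocol = protocol,
                     fs = cfg$fs)
  build_table(sessions, cutoff = cfg$cutoff, n_taps = cfg$n_taps)
}

#' Run the full experiment
#'
#' Executes the whole pipeline and reproduces the study's report artifacts
#' on synthetic data: the model-family x top-k grid of train/test
#' identity-line metrics (`grid`), per-test-group metrics of the
#' down-selected all-step model (`subgroups`), per-group MRMR top-10
#' rankings with rank shifts against the all-step ranking (`rankings`),
#' and the full train-group x test-group metric matrix (`matrix`). Every
#' artifact is stamped with the config hash and seed.
#'
#' @param cfg A `crm_config`.
#' @return List of class `crm_report` with elements `config`, `hash`,
#'   `seed`, `exclusions`, `ranking_all`, `grid`, `selected`, `subgroups`,
#'   `rankings`, `shifts`, `matrix`.
#' @export
run_experiment <- function(cfg = run_config()) {
  protocol <- make_protocol(step_duration = cfg$step_duration)
  cohort <- sample_cohort(cfg$n_per_group, cfg$groups, seed = cfg$seed)
  split <- split_cohort(cohort, cfg$train_per_group, cfg$test_per_group,
                        seed = cfg$seed)
  train_tab <- cohort_features(split$train, protocol, cfg)
  test_tab <- cohort_features(split$test, protocol, cfg)

  p <- nrow(feature_registry())
  ranking_all <- rank_mrmr(train_tab, k = p)

  grid <- list()
  for (k in cfg$top_k) for (kind in .model_kinds) {
    feats <- ranking_all$name[seq_len(k)]
    m <- fit_crm_model(model_spec(kind, feats, n_learners = cfg$n_learners,
                                  seed = cfg$seed), train_tab)
    yhat <- predict(m, test_tab, clamp = cfg$clamp)
    tp <- perfect_metrics(test_tab$crm, yhat)
    grid[[length(grid) + 1]] <- data.frame(
      model = kind, top_k = k,
      train_P_RMSE = m$summary$P_RMSE, train_P_R2 = m$summary$P_R2,
      test_P_RMSE = tp$P_RMSE, test_P_R2 = tp$P_R2,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grid)

  # down-selected operating model: bagged trees + top selected_k features
  sel_feats <- ranking_all$name[seq_len(cfg$selected_k)]
  sel_spec <- model_spec("bagged_trees", sel_feats,
                         n_learners = cfg$n_learners, seed = cfg$seed)
  sel_model <- fit_crm_model(sel_spec, train_tab)
  subgroups <- do.call(rbind, lapply(sort(unique(test_tab$group)), function(g) {
    rows <- test_tab[test_tab$group == g, , drop = FALSE]
    yhat <- predict(sel_model, rows, clamp = cfg$clamp)
    pm <- perfect_metrics(rows$crm, yhat)
    lmm <- linear_metrics(rows$crm, yhat)
    data.frame(group = g, P_R2 = pm$P_R2, P_RMSE = pm$P_RMSE,
               R2 = lmm$R2, RMSE = lmm$RMSE, n = nrow(rows))
  }))

  # per-group rankings and rank shifts vs the all-step ranking
  group_names <- c("all", as.character(cfg$groups))
  rankings <- list(all = ranking_all)
  for (g in cfg$groups) {
    sub <- train_tab[train_tab$group == g, , drop = FALSE]
    rankings[[as.character(g)]] <- rank_mrmr(sub, k = p)
  }
  all_pos <- stats::setNames(seq_len(p), ranking_all$name)
  shifts <- do.call(rbind, lapply(group_names, function(g) {
    r <- rankings[[g]]
    top <- r$name[seq_len(min(10L, p))]
    data.frame(group = g, rank = seq_along(top), feature = top,
               shift = as.integer(all_pos[top]) - seq_along(top),
               stringsAsFactors = FALSE)
  }))

  models <- train_matrix(train_tab, group_names, sel_spec)
  mat <- evaluate_matrix(models, test_tab, .subject_ids(split$train))

  report <- structure(list(config = cfg, hash = config_hash(cfg),
                           seed = cfg$seed,
                           exclusions = attr(train_tab, "exclusions") +
                             attr(test_tab, "exclusions"),
                           ranking_all = ranking_all, grid = grid,
                           selected = sel_model, subgroups = subgroups,
                           rankings = rankings, shifts = shifts,
                           matrix = mat),
                      class = "crm_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a report bundle to disk
#'
#' Serializes the grid, subgroup table, rank-shift table and metric matrix
#' as CSV plus a JSON summary stamped with the config hash and seed.
#'
#' @param report A `crm_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  rp <- function(f) file.path(dir, "reports", f)
  utils::write.csv(report$grid, rp("model_grid.csv"), row.names = FALSE)
  utils::write.csv(report$subgroups, rp("subgroup_metrics.csv"), row.names = FALSE)
  utils::write.csv(report$shifts, rp("rank_shifts.csv"), row.names = FALSE)
  utils::write.csv(report$matrix, rp("cross_matrix.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(hash = report$hash, seed = report$seed,
         exclusions = as.list(report$exclusions),
         config = report$config[setdiff(names(report$config), "out_dir")],
         selected_features = report$selected$spec$features,
         selected_summary = report$selected$summary),
    rp("run_summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
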