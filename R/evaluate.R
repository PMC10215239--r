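#' Identity-line ("perfect") regression metrics
#'
#' Error metrics computed about the line y = x rather than a fitted line:
#' `P_RMSE = sqrt(mean((yhat - y)^2))` and
#' `P_R2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`. `P_R2` can be
#' negative (predictions worse than the label mean) and never exceeds the
#' conventional fitted-line R-squared.
#'
#' @param y_true Calculated CRM labels.
#' @param y_pred Predicted CRM values.
#' @return List with `P_RMSE` and `P_R2` (`P_R2` is `NA` with a warning
#'   when `y_true` is constant).
#' @export
perfect_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n == 0 || n != length(y_pred))
    stop("y_true and y_pred must have equal nonzero length")
  sse <- sum((y_pred - y_true)^2)
  p_rmse <- sqrt(sse / n)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) {
    warning("y_true is constant; P_R2 undefined")
    return(list(P_RMSE = p_rmse, P_R2 = NA_real_))
  }
  list(P_RMSE = p_rmse, P_R2 = 1 - sse / sst)
}

#' Conventional least-squares regression metrics
#'
#' Fits `y_pred = m * y_true + b` by ordinary least squares and reports
#' the squared Pearson correlation `R2`, the root-mean-square residual
#' about the fitted line `RMSE`, and the fitted slope and intercept.
#'
#' @inheritParams perfect_metrics
#' @return List with `RMSE`, `R2`, `m`, `b`.
#' @export
linear_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n < 3 || n != length(y_pred))
    stop("need >= 3 paired points")
  if (stats::sd(y_true) == 0) stop("y_true is constant; fit undefined")
  fit <- stats::lm(y_pred ~ y_true)
  co <- stats::coef(fit)
  list(RMSE = sqrt(mean(stats::resid(fit)^2)),
       R2 = stats::cor(y_true, y_pred)^2,
       m = unname(co[2]), b = unname(co[1]))
}

#' Cross-evaluate per-group models against per-group test data
#'
#' Produces the full training-group x test-group matrix of metrics: each
#' model (rows) is blind-tested against the pooled beats of each test
#' subgroup (columns), with both the identity-line and conventional metric
#' families. Subject-level leakage between a model's training subjects and
#' the test table is an error.
#'
#' @param models Named list from [train_matrix()].
#' @param test_table Feature table of held-out subjects.
#' @param train_subjects Character vector (or list per model) of subject
#'   ids used in training, for the leakage check.
#' @param groups Test groups; default all groups present in `test_table`.
#' @return data.frame of class `crm_matrix`: one row per
#'   (train_group, test_group) cell with columns `P_RMSE`, `P_R2`,
#'   `RMSE`, `R2`, `m`, `b`, `n`.
#' @export
evaluate_matrix <- function(models, test_table, train_subjects,
                            groups = sort(unique(test_table$group))) {
  leak <- intersect(unique(unlist(train_subjects)),
                    unique(test_table$subject_id))
  if (length(leak))
    stop("subject leakage between train and test: ",
         paste(leak, collapse = ", "))
  cells <- list()
  for (mg in names(models)) for (tg in groups) {
    rows <- test_table[test_table$group == as.integer(tg), , drop = FALSE]
    if (nrow(rows) == 0) stop("empty test group: ", tg)
    yhat <- predict(models[[mg]], rows)
    pm <- perfect_metrics(rows$crm, yhat)
    lmm <- linear_metrics(rows$crm, yhat)
    cells[[length(cells) + 1]] <- data.frame(
      train_group = mg, test_group = tg,
      P_RMSE = pm$P_RMSE, P_R2 = pm$P_R2,
      RMSE = lmm$RMSE, R2 = lmm$R2, m = lmm$m, b = lmm$b,
      n = nrow(rows), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cells)
  class(out) <- c("crm_matrix", "data.frame")
  out
}
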