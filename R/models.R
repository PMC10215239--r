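#' @importFrom rpart rpart rpart.control
#' @importFrom stats lm predict as.formula
NULL

.model_kinds <- c("linear", "tree_fine", "tree_medium", "tree_coarse",
                  "bagged_trees", "boosted_trees")

# conventional minimum-leaf-size presets for the named tree granularities
.leaf_presets <- c(tree_fine = 4L, tree_medium = 12L, tree_coarse = 36L,
                   bagged_trees = 8L, boosted_trees = 8L)

#' Specify a regression model
#'
#' The six classical families used for CRM estimation: ordinary least
#' squares, fine/medium/coarse regression trees (minimum leaf sizes
#' 4/12/36), bootstrap-aggregated trees and least-squares boosted trees
#' (both with leaf size 8 and 30 learners by default).
#'
#' @param kind One of `"linear"`, `"tree_fine"`, `"tree_medium"`,
#'   `"tree_coarse"`, `"bagged_trees"`, `"boosted_trees"`.
#' @param features Ordered character vector of feature names to use.
#' @param n_learners Ensemble size (bagged/boosted only).
#' @param leaf Minimum observations per leaf; defaults to the kind's preset.
#' @param learning_rate Shrinkage for boosting.
#' @param max_depth Depth limit for boosted base learners.
#' @param bootstrap Draw bootstrap resamples when bagging (disable to make
#'   a 1-learner bag identical to a single tree).
#' @param seed Integer seed for resampling reproducibility.
#' @return List of class `crm_model_spec`.
#' @export
model_spec <- function(kind, features, n_learners = 30L, leaf = NULL,
                       learning_rate = 0.1, max_depth = 4L,
                       bootstrap = TRUE, seed = 1L) {
  kind <- match.arg(kind, .model_kinds)
  if (length(features) == 0) stop("feature subset must be non-empty")
  if (is.null(leaf) && kind != "linear") leaf <- .leaf_presets[[kind]]
  structure(list(kind = kind, features = as.character(features),
                 n_learners = as.integer(n_learners), leaf = leaf,
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "crm_model_spec")
}

.rpart_fit <- function(df, leaf, max_depth = 30L) {
  ctrl <- rpart::rpart.control(minsplit = 2L * leaf, minbucket = leaf,
                               cp = 0, xval = 0, maxsurrogate = 0,
                               maxcompete = 0, maxdepth = max_depth)
  rpart::rpart(crm ~ ., data = df, method = "anova", control = ctrl)
}

#' Fit a CRM regression model
#'
#' @param spec A `crm_model_spec`.
#' @param table Feature table with a `crm` column (see [build_table()]).
#' @return Object of class `crm_model` holding the spec, the fitted state
#'   and a training summary (`n`, in-sample `P_RMSE` and `P_R2`).
#' @export
fit_crm_model <- function(spec, table) {
  missing <- setdiff(spec$features, names(table))
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  if (nrow(table) < 10) stop("need at least 10 training rows")
  df <- table[, c("crm", spec$features), drop = FALSE]
  set.seed(spec$seed)
  fitted <- switch(spec$kind,
    linear = stats::lm(crm ~ ., data = df),
    tree_fine = ,
    tree_medium = ,
    tree_coarse = .rpart_fit(df, spec$leaf),
    bagged_trees = {
      n <- nrow(df)
      lapply(seq_len(spec$n_learners), function(b) {
        idx <- if (spec$bootstrap) sample.int(n, n, replace = TRUE)
               else seq_len(n)
        .rpart_fit(df[idx, , drop = FALSE], spec$leaf)
      })
    },
    boosted_trees = {
      f0 <- mean(df$crm)
      resid <- df$crm - f0
      trees <- vector("list", spec$n_learners)
      work <- df
      for (b in seq_len(spec$n_learners)) {
        work$crm <- resid
        tr <- .rpart_fit(work, spec$leaf, max_depth = spec$max_depth)
        resid <- resid - spec$learning_rate *
          stats::predict(tr, newdata = work)
        trees[[b]] <- tr
      }
      list(f0 = f0, trees = trees)
    })
  m <- structure(list(spec = spec, fitted = fitted), class = "crm_model")
  yhat <- predict(m, table)
  pm <- perfect_metrics(table$crm, yhat)
  m$summary <- list(n = nrow(table), P_RMSE = pm$P_RMSE, P_R2 = pm$P_R2)
  m
}

#' Predict CRM for new beats
#'
#' @param object A fitted `crm_model`.
#' @param newdata data.frame containing the spec's feature columns.
#' @param clamp Clamp predictions into \[0, 1\] (off by default; raw
#'   regression output can over/undershoot the label range).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.crm_model <- function(object, newdata, clamp = FALSE, ...) {
  spec <- object$spec
  missing <- setdiff(spec$features, names(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  nd <- newdata[, spec$features, drop = FALSE]
  yhat <- switch(spec$kind,
    linear = as.numeric(stats::predict(object$fitted, newdata = nd)),
    tree_fine = ,
    tree_medium = ,
    tree_coarse = as.numeric(stats::predict(object$fitted, newdata = nd)),
    bagged_trees = {
      preds <- vapply(object$fitted, function(tr)
        as.numeric(stats::predict(tr, newdata = nd)), numeric(nrow(nd)))
      if (nrow(nd) == 1) mean(preds) else rowMeans(matrix(preds, nrow = nrow(nd)))
    },
    boosted_trees = {
      acc <- rep(object$fitted$f0, nrow(nd))
      for (tr in object$fitted$trees)
        acc <- acc + spec$learning_rate * as.numeric(stats::predict(tr, newdata = nd))
      acc
    })
  if (clamp) yhat <- pmin(pmax(yhat, 0), 1)
  yhat
}

#' Train one model per decompensation-step group
#'
#' Mirrors the subgroup analysis: the `"all"` model trains on every
#' subject, while each numeric group's model trains only on subjects whose
#' decompensation step equals that group, with an otherwise identical spec.
#'
#' @param table Training feature table (must have a `group` column).
#' @param groups Character/integer vector drawn from `"all"` and the step
#'   groups present.
#' @param spec Model spec applied to every group.
#' @return Named list of `crm_model`, one per requested group.
#' @export
train_matrix <- function(table, groups, spec) {
  out <- list()
  for (g in groups) {
    sub <- if (identical(as.character(g), "all")) table
           else table[table$group == as.integer(g), , drop = FALSE]
    if (nrow(sub) == 0) stop("empty training group: ", g)
    out[[as.character(g)]] <- fit_crm_model(spec, sub)
  }
  out
}

#' Serialize a fitted model to JSON
#'
#' Linear models serialize completely (coefficients); tree ensembles
#' serialize their spec, training summary and per-learner node counts.
#'
#' @param m A `crm_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  desc <- list(kind = m$spec$kind, features = m$spec$features,
               summary = m$summary)
  if (m$spec$kind == "linear") {
    desc$coefficients <- as.list(stats::coef(m$fitted))
  } else if (m$spec$kind %in% c("bagged_trees", "boosted_trees")) {
    trees <- if (m$spec$kind == "bagged_trees") m$fitted else m$fitted$trees
    desc$n_learners <- length(trees)
    desc$nodes_per_tree <- vapply(trees, function(tr) nrow(tr$frame), integer(1))
  } else {
    desc$n_nodes <- nrow(m$fitted$frame)
  }
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
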