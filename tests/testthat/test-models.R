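test_that("OLS recovers an exact affine relationship", {
  set.seed(31)
  tab <- data.frame(crm = runif(100), PP = NA)
  tab$PP <- 2 * tab$crm + 1
  m <- fit_crm_model(model_spec("linear", "PP"), tab)
  expect_lt(m$summary$P_RMSE, 1e-8)
  expect_equal(predict(m, data.frame(PP = c(1, 3))), c(0, 1),
               tolerance = 1e-8)
})

test_that("tree presets honor their minimum leaf sizes", {
  set.seed(32)
  tab <- data.frame(crm = runif(100), PP = rnorm(100), HRIP = rnorm(100))
  for (kind in c("tree_fine", "tree_medium", "tree_coarse")) {
    m <- fit_crm_model(model_spec(kind, c("PP", "HRIP")), tab)
    fr <- m$fitted$frame
    leaf_n <- fr$n[fr$var == "<leaf>"]
    expect_gte(min(leaf_n), m$spec$leaf)
  }
  fine <- fit_crm_model(model_spec("tree_fine", c("PP", "HRIP")), tab)
  expect_equal(fine$spec$leaf, 4L)
})

test_that("bagged ensembles hold the requested learner count at leaf 8", {
  mc <- mini_cohort()
  spec <- model_spec("bagged_trees", c("PP", "HRIP", "t_sys_rise"))
  m <- fit_crm_model(spec, mc$train)
  expect_length(m$fitted, 30)
  expect_equal(spec$leaf, 8L)
  for (tr in m$fitted[1:3]) {
    fr <- tr$frame
    expect_gte(min(fr$n[fr$var == "<leaf>"]), 8)
  }
})

test_that("a single-learner bag without bootstrap is exactly one tree", {
  mc <- mini_cohort()
  feats <- c("PP", "HRIP", "t_sys_rise")
  bag1 <- fit_crm_model(model_spec("bagged_trees", feats, n_learners = 1L,
                                   leaf = 4L, bootstrap = FALSE, seed = 3),
                        mc$train)
  tree <- fit_crm_model(model_spec("tree_fine", feats, seed = 3), mc$train)
  expect_identical(predict(bag1, mc$test), predict(tree, mc$test))
})

test_that("bagged predictions are the mean of the member trees", {
  mc <- mini_cohort()
  m <- fit_crm_model(model_spec("bagged_trees", c("PP", "HRIP"),
                                n_learners = 5L, seed = 9), mc$train)
  rows <- mc$test[1:7, ]
  per_tree <- sapply(m$fitted, function(tr) predict(tr, newdata = rows))
  expect_equal(predict(m, rows), unname(rowMeans(per_tree)),
               tolerance = 1e-12)
})

test_that("boosting stacks shrunken residual trees reproducibly", {
  mc <- mini_cohort()
  m <- fit_crm_model(model_spec("boosted_trees", c("PP", "HRIP"), seed = 5),
                     mc$train)
  expect_length(m$fitted$trees, 30)
  p1 <- predict(m, mc$test)
  m2 <- fit_crm_model(model_spec("boosted_trees", c("PP", "HRIP"), seed = 5),
                      mc$train)
  expect_identical(p1, predict(m2, mc$test))
  expect_true(all(is.finite(p1)))
})

test_that("constant targets, clamping and feature checks behave", {
  tab <- data.frame(crm = rep(0.4, 50), PP = rnorm(50))
  m <- suppressWarnings(fit_crm_model(model_spec("tree_fine", "PP"), tab))
  expect_true(all(abs(predict(m, tab) - 0.4) < 1e-12))
  mc <- mini_cohort()
  mm <- fit_crm_model(model_spec("linear", c("PP", "HRIP")), mc$train)
  expect_true(all(predict(mm, mc$test, clamp = TRUE) >= 0))
  expect_true(all(predict(mm, mc$test, clamp = TRUE) <= 1))
  expect_error(fit_crm_model(model_spec("linear", "nope"), mc$train),
               "unknown feature")
  expect_error(predict(mm, mc$test[, "crm", drop = FALSE]), "missing feature")
})

test_that("per-group training uses only that group's subjects", {
  mc <- mini_cohort()
  spec <- model_spec("bagged_trees", c("PP", "HRIP"), n_learners = 5L)
  mods <- train_matrix(mc$train, c("all", 5, 7), spec)
  expect_named(mods, c("all", "5", "7"))
  for (g in c(5, 7)) {
    sub <- mc$train[mc$train$group == g, ]
    expect_true(all(sub$group == g))
    expect_equal(mods[[as.character(g)]]$summary$n, nrow(sub))
  }
  expect_error(train_matrix(mc$train, "6", spec), "empty training group")
})
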