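test_that("the stump splits at the midpoint of the separating gap", {
  d <- data.frame(css_mg_per_L = c(1, 2, 5, 7, 8),
                  auc_mg_h_per_L = rep(50, 5),  # uninformative
                  toxicity = c("none", "none", "none",
                               "life_threatening", "life_threatening"))
  st <- fit_stump(d)
  expect_equal(st$feature, "css")
  expect_equal(st$threshold, 6)
  expect_equal(unname(st$leaf_probabilities), c(0, 1))
  expect_equal(unname(st$leaf_counts[, "positive"]), c(0, 2))
  expect_equal(st$n, 5)
})

test_that("single-class data yield a degenerate majority model, not an error", {
  d <- data.frame(css_mg_per_L = 1:4, auc_mg_h_per_L = 4:1,
                  toxicity = "none")
  st <- fit_stump(d)
  expect_true(is.na(st$feature))
  expect_equal(unname(st$leaf_probabilities["all"]), 0)
  pred <- predict(st, data.frame(css_mg_per_L = c(0.5, 99)))
  expect_equal(pred$p_positive, c(0, 0))
  expect_false(any(pred$class))
})

test_that("a perfectly separating concentration beats an overlapping AUC", {
  set.seed(3)
  y <- rep(c(FALSE, TRUE), each = 20)
  d <- data.frame(css_mg_per_L = ifelse(y, runif(40, 6.2, 9), runif(40, 1, 5.8)),
                  auc_mg_h_per_L = runif(40, 20, 120),
                  toxicity = ifelse(y, "life_threatening", "none"))
  st <- fit_stump(d)
  expect_equal(st$feature, "css")
  expect_equal(unname(st$leaf_probabilities), c(0, 1))
})

test_that("fit_stump matches the exhaustive brute-force oracle", {
  set.seed(101)
  for (i in 1:50) {
    dat <- random_stump_data(sample(3:50, 1))
    st <- fit_stump(dat$rows)
    or <- oracle_stump(dat$css, dat$auc, dat$y)
    expect_equal(st$feature, or$feature)
    expect_equal(st$threshold, or$threshold)
    if (!is.na(st$feature)) {
      expect_equal(unname(st$leaf_counts), unname(or$leaf_counts))
      expect_equal(st$impurity_gain, or$gain, tolerance = 1e-12)
    }
  }
})

test_that("the fit is invariant under monotone transforms of the unselected feature", {
  set.seed(7)
  dat <- random_stump_data(60)
  st <- fit_stump(dat$rows)
  expect_equal(st$feature, "css")
  rows2 <- dat$rows
  rows2$auc_mg_h_per_L <- exp(rows2$auc_mg_h_per_L / 50)
  st2 <- fit_stump(rows2)
  expect_equal(st2$feature, st$feature)
  expect_equal(st2$threshold, st$threshold)
  expect_equal(st2$leaf_counts, st$leaf_counts)
})

test_that("fit_stump agrees with an rpart depth-1 tree", {
  skip_if_not_installed("rpart")
  set.seed(19)
  dat <- random_stump_data(80)
  st <- fit_stump(dat$rows)
  fit <- rpart::rpart(
    y ~ css + auc,
    data = data.frame(css = dat$css, auc = dat$auc, y = factor(dat$y)),
    method = "class",
    control = rpart::rpart.control(maxdepth = 1, minsplit = 2,
                                   minbucket = 1, cp = 1e-9, xval = 0))
  expect_equal(st$feature, rownames(fit$splits)[1])
  expect_equal(st$threshold, unname(fit$splits[1, "index"]))
})

test_that("prediction routes by the threshold and reports leaf probabilities", {
  # the published tree: P(life-threatening) 0.03 below 6 mg/L, 0.86 above
  st <- structure(list(feature = "css", threshold = 6,
                       leaf_counts = matrix(c(97, 14, 3, 86), nrow = 2,
                                            dimnames = list(c("below", "above"),
                                                            c("negative", "positive"))),
                       leaf_probabilities = c(below = 0.03, above = 0.86),
                       impurity_gain = 0.5, n = 200, criterion = "gini"),
                  class = "fu_stump")
  p <- predict(st, data.frame(css_mg_per_L = c(5.9, 6.1)))
  expect_equal(p$p_positive, c(0.03, 0.86))
  expect_equal(p$class, c(FALSE, TRUE))
  expect_error(predict(st, data.frame(auc_mg_h_per_L = 1)), "css_mg_per_L")
})

test_that("the entropy criterion is available and picks a sensible split", {
  d <- data.frame(css_mg_per_L = c(1, 2, 5, 7, 8),
                  auc_mg_h_per_L = rep(50, 5),
                  toxicity = c("none", "none", "none",
                               "life_threatening", "life_threatening"))
  st <- fit_stump(d, criterion = "information")
  expect_equal(st$feature, "css")
  expect_equal(st$threshold, 6)
})
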