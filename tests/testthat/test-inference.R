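# ABC rejection, model selection, forest regression and the PLS option.

make_table <- function(n = 400, p = 8, seed = 31) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 1] * 2 + rnorm(n, sd = 0.01)
  list(x = x, y = y)
}

test_that("rejection retains exactly round(tolerance * n) nearest rows", {
  tb <- make_table()
  post <- abc_reject(tb$x[7, ], tb$x, tb$y, tolerance = 0.05)
  expect_length(post$accepted_indices, round(0.05 * 400))
  expect_true(!is.unsorted(post$distances))
  # the self-match row is always retained, at distance zero
  expect_identical(post$accepted_indices[1], 7L)
  expect_equal(post$distances[1], 0)
  # tolerance 1 retains everything; mean estimate is the label mean
  all_in <- abc_reject(tb$x[7, ], tb$x, tb$y, tolerance = 1)
  expect_length(all_in$accepted_indices, 400)
  expect_equal(unname(all_in$point_estimates["mean"]), mean(tb$y))
  expect_error(abc_reject(tb$x[7, ], tb$x, tb$y, tolerance = 1e-9), "zero")
})

test_that("study-design retention arithmetic is exact", {
  expect_identical(round(0.0025 * 600000), 1500)
  expect_identical(round(0.00750 * 200000), 1500)
})

test_that("standardization makes rejection invariant to affine rescaling", {
  tb <- make_table()
  target <- tb$x[11, ]
  post1 <- abc_reject(target, tb$x, tb$y, retain = 25)
  scale_f <- c(100, 0.01, 7, 1, 3, 0.5, 40, 2)
  xs <- sweep(tb$x, 2, scale_f, `*`)
  post2 <- abc_reject(target * scale_f, xs, tb$y, retain = 25)
  expect_identical(post1$accepted_indices, post2$accepted_indices)
})

test_that("model selection arithmetic and tie-breaking follow the rules", {
  # four retained simulations with Psi = {1, 1, 10, 10}
  x <- matrix(c(0, 0, 0, 0, 10, 10), ncol = 1)
  y <- c(1, 1, 10, 10, 3, 3)
  post <- abc_model_select(0, x, y, retain = 4)
  expect_equal(unname(post$point_estimates["mean"]), 5.5)
  expect_equal(unname(post$point_estimates["median"]), 5.5)
  expect_equal(unname(post$point_estimates["mode"]), 1)  # tie -> lowest
  expect_equal(sum(post$category_posteriors), 1)
  expect_equal(unname(post$category_posteriors[c("1", "10")]), c(0.5, 0.5))
  # unanimity
  uni <- abc_model_select(0, x, y, retain = 2)
  expect_equal(unname(uni$point_estimates), c(1, 1, 1))
  expect_equal(unname(uni$category_posteriors["1"]), 1)
})

test_that("forest recovers a noiseless linear label and stays in range", {
  set.seed(32)
  n <- 1500
  x <- matrix(rnorm(n * 8), n, 8)
  y <- round(x[, 1] * 2)          # label encoded in one summary column
  y <- pmin(pmax(y, -3), 3)
  hold <- 1:60
  forest <- rf_train(x[-hold, ], y[-hold], n_cycles = 20,
                     trees_per_cycle = 10, per_class = 80, mtry = 8)
  pred <- rf_predict(forest, x[hold, ])
  expect_gt(cor(pred, y[hold]), 0.99)
  expect_true(all(pred >= min(y) & pred <= max(y)))
})

test_that("forest predictions are constant when labels are constant", {
  tb <- make_table()
  expect_error(rf_train(tb$x, rep(2, 400)), "distinct")
})

test_that("forest runs are bit-reproducible under a seed", {
  tb <- make_table(n = 200)
  y <- as.numeric(tb$x[, 2] > 0)
  set.seed(33)
  f1 <- rf_train(tb$x, y, n_cycles = 4, trees_per_cycle = 5,
                 per_class = 40, balance_by = y)
  p1 <- rf_predict(f1, tb$x[1:20, ])
  set.seed(33)
  f2 <- rf_train(tb$x, y, n_cycles = 4, trees_per_cycle = 5,
                 per_class = 40, balance_by = y)
  p2 <- rf_predict(f2, tb$x[1:20, ])
  expect_identical(p1, p2)
})

test_that("forest split-candidate default is a third of the statistics", {
  set.seed(34)
  x <- matrix(rnorm(100 * 100), 100, 100)
  y <- x[, 1]
  f <- rf_train(x, y, n_cycles = 1, trees_per_cycle = 2, per_class = 20,
                balance_by = rep(1:2, 50))
  expect_identical(f$mtry, 33L)
})

test_that("PLS keeps the fewest components reaching the variance target", {
  set.seed(35)
  # one dominating direction: a single component suffices
  base <- rnorm(200)
  x <- outer(base, rep(1, 10)) + matrix(rnorm(2000, sd = 1e-3), 200, 10)
  y <- base + rnorm(200, sd = 0.1)
  tr <- pls_transform(x[1:100, ], y[1:100], x[101:200, ])
  expect_identical(tr$n_comp, 1L)
  expect_gte(tr$cum_var_explained[tr$n_comp], 0.95)
  # component count is non-decreasing in the variance threshold
  set.seed(36)
  x2 <- matrix(rnorm(3000), 150, 20)
  y2 <- rowSums(x2[, 1:3])
  n_comp <- vapply(c(0.5, 0.8, 0.95, 0.99), function(th)
    pls_transform(x2[1:75, ], y2[1:75], x2[76:150, ],
                  var_explained = th)$n_comp, 0L)
  expect_true(!is.unsorted(n_comp))
  # variance accounting: reconstruction from kept scores explains >= 95%
  tr2 <- pls_transform(x2[1:75, ], y2[1:75], x2[76:150, ],
                       var_explained = 0.95)
  xc <- scale(x2[1:75, ], scale = FALSE)
  fitted <- tr2$train_scores %*%
    qr.solve(tr2$train_scores, xc)
  expect_gte(sum(fitted^2) / sum(xc^2), 0.95)
})
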