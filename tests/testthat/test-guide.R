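# GUIDE-style tree: selection tests, split search, importance scores,
# bootstrap protocol, pruning and the Spearman helper.

test_that("a constant response yields a root-only tree with zero importance", {
  d <- data.frame(x1 = runif(100), x2 = runif(100), y = 1)
  fit <- guide_tree(y ~ x1 + x2, d)
  expect_true(fit$constant_response)
  expect_equal(hybtherm:::n_splits(fit$nodes), 0L)
  imp <- importance(fit)
  expect_true(all(imp$score == 0))
})

test_that("the first split recovers a step function against a noise predictor", {
  set.seed(41)
  n <- 2000
  d <- data.frame(x1 = runif(n), x2 = runif(n))
  d$y <- ifelse(d$x1 > 0.55, 4, 0) + rnorm(n, sd = 0.4)
  fit <- guide_tree(y ~ x1 + x2, d, prune = FALSE)
  root <- fit$nodes[[1]]
  expect_equal(root$split_var, "x1")
  expect_lt(abs(root$split_point - 0.55), 0.03)
  imp <- importance(fit)
  expect_equal(imp$predictor[1], "x1")
  # cross-check with an independent recursive-partitioning fit
  skip_if_not_installed("rpart")
  rp <- rpart::rpart(y ~ x1 + x2, d)
  expect_lt(abs(rp$splits[1, "index"] - root$split_point), 0.03)
})

test_that("a single-predictor table always splits on that predictor", {
  set.seed(42)
  d <- data.frame(x = runif(500))
  d$y <- sin(6 * d$x) + rnorm(500, sd = 0.2)
  fit <- guide_tree(y ~ x, d, min_node_size = 60, prune = FALSE)
  svars <- na.omit(vapply(fit$nodes, `[[`, character(1), "split_var"))
  expect_gt(length(svars), 0)
  expect_true(all(svars == "x"))
})

test_that("importance is chi-square times root node size, summed over splits", {
  set.seed(43)
  n <- 600
  d <- data.frame(x1 = runif(n), x2 = runif(n))
  d$y <- ifelse(d$x1 > 0.5, 3, 0) + rnorm(n, sd = 0.3)
  fit <- guide_tree(y ~ x1 + x2, d, max_depth = 1, prune = FALSE)
  root <- fit$nodes[[1]]
  imp <- importance(fit)
  expect_equal(imp$score[imp$predictor == root$split_var],
               root$chi_sq * sqrt(root$n))
  expect_equal(imp$relative[1], 1)
  # deeper tree: score equals the hand-computed sum over split nodes
  fit2 <- guide_tree(y ~ x1 + x2, d, max_depth = 3, min_node_size = 80,
                     prune = FALSE)
  hand <- setNames(numeric(2), c("x1", "x2"))
  for (id in hybtherm:::active_ids(fit2$nodes)) {
    nd <- fit2$nodes[[id]]
    if (!nd$leaf) hand[nd$split_var] <- hand[nd$split_var] +
        nd$chi_sq * sqrt(nd$n)
  }
  imp2 <- importance(fit2)
  expect_equal(setNames(imp2$score, imp2$predictor)[names(hand)], hand)
})

test_that("the node chi-square matches the standard contingency statistic", {
  set.seed(44)
  x <- runif(200); pos <- runif(200) > 0.4
  br <- unique(quantile(x, c(.25, .5, .75), names = FALSE))
  bin <- findInterval(x, br, left.open = TRUE) + 1L
  ours <- hybtherm:::curvature_stat(x, pos)
  ref <- suppressWarnings(chisq.test(table(pos, bin), correct = FALSE))
  expect_equal(ours, unname(ref$statistic))
})

test_that("prediction, residuals and plotting work on fitted trees", {
  set.seed(45)
  d <- data.frame(x1 = runif(400), x2 = runif(400))
  d$y <- 2 * d$x1 + ifelse(d$x2 > 0.5, 1, 0) + rnorm(400, sd = 0.1)
  fit <- guide_tree(y ~ x1 + x2, d, min_node_size = 50, prune = FALSE)
  pr <- predict(fit, d)
  expect_length(pr, 400)
  expect_gt(cor(pr, d$y), 0.9)
  expect_equal(residuals(fit, d), d$y - pr)
  pdf(NULL)
  expect_silent(plot(fit))
  expect_silent(plot(importance(fit)))
  dev.off()
})

test_that("cost-complexity pruning respects the one-standard-error rule", {
  set.seed(46)
  n <- 1200
  d <- data.frame(x1 = runif(n), x2 = runif(n))
  d$y <- ifelse(d$x1 > 0.5, 2, 0) + ifelse(d$x2 > 0.7, 1, 0) +
    rnorm(n, sd = 0.5)
  fit <- guide_tree(y ~ x1 + x2, d, min_node_size = 60, prune = TRUE,
                    cv_folds = 5)
  tr <- fit$pruning
  expect_false(is.null(tr))
  chosen <- attr(tr, "chosen")
  best <- which.min(tr$cv_error)
  expect_lte(tr$cv_error[chosen], tr$cv_error[best] + tr$cv_se[best] + 1e-9)
  # the chosen tree is never larger than the unpruned one
  grown <- guide_tree(y ~ x1 + x2, d, min_node_size = 60, prune = FALSE)
  expect_lte(hybtherm:::n_leaves_active(fit$nodes),
             hybtherm:::n_leaves_active(grown$nodes))
})

test_that("bootstrap importance is deterministic and SD-zero on constant scores", {
  set.seed(47)
  d <- data.frame(x1 = runif(300), x2 = runif(300))
  d$y <- ifelse(d$x1 > 0.5, 3, 0) + rnorm(300, sd = 0.3)
  b1 <- bootstrap_importance(y ~ x1 + x2, d, n_rep = 8, seed = 123)
  b2 <- bootstrap_importance(y ~ x1 + x2, d, n_rep = 8, seed = 123)
  expect_identical(b1, b2)
  expect_equal(b1$relative[1], 1)
  expect_error(bootstrap_importance(y ~ x1 + x2, d, n_rep = 1), "n_rep")
  # degenerate: constant response in every replicate -> all-zero scores
  dc <- data.frame(x1 = runif(100), x2 = runif(100), y = 2)
  bc <- bootstrap_importance(y ~ x1 + x2, dc, n_rep = 4, seed = 1)
  expect_true(all(bc$sd == 0))
})

test_that("permuting an informative predictor destroys its importance", {
  set.seed(48)
  n <- 1500
  d <- data.frame(x1 = runif(n), x3 = runif(n))
  # two nonlinear signal sources (linear trends are absorbed by the
  # piecewise-linear leaf models and carry no split information)
  d$y <- ifelse(d$x1 > 0.5, 3, 0) + ifelse(d$x3 > 0.65, 2, 0) +
    rnorm(n, sd = 0.4)
  d$x2 <- sample(d$x1)           # permuted copy: no information left
  b <- bootstrap_importance(y ~ x1 + x2 + x3, d, n_rep = 15, seed = 9)
  m <- setNames(b$mean, b$predictor)
  expect_lt(m[["x2"]], m[["x1"]])
  expect_lt(m[["x2"]], m[["x3"]])
})

test_that("spearman correlation handles ties, signs and exact small-n p-values", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$rho, -1)
  expect_error(spearman_cor(1:5, rep(1, 5)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "length")
  set.seed(49)
  # exact permutation p-values agree with the reference implementation
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    ours <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman")
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  # large n: t-approximation agrees with the reference
  x <- rnorm(50); y <- x + rnorm(50)
  ours <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
})
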