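test_that("splitChains keeps chains whole and respects the fraction", {
  chains <- LETTERS[1:8]
  sp <- splitChains(chains, trainFrac = 0.75, seed = 1L)
  expect_length(sp$train, 6L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$test), chains)
  expect_length(intersect(sp$train, sp$test), 0L)
  # deterministic in the seed
  expect_identical(sp, splitChains(chains, trainFrac = 0.75, seed = 1L))
  expect_false(identical(sp, splitChains(chains, seed = 2L)))
  # both sides always keep at least one chain
  sp2 <- splitChains(c("A", "B"), trainFrac = 0.99, seed = 3L)
  expect_length(sp2$train, 1L)
  expect_length(sp2$test, 1L)
  expect_error(splitChains("A"), "at least 2")
})

test_that("makeCVFolds partitions chains into near-equal folds", {
  chains <- sprintf("c%02d", 1:13)
  folds <- makeCVFolds(chains, k = 5L, seed = 7L)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), chains)
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_identical(folds, makeCVFolds(chains, k = 5L, seed = 7L))
  expect_error(makeCVFolds(c("A", "B"), k = 5L), "fewer chains")
})

test_that("splitChains and makeCVFolds leave the global RNG untouched", {
  set.seed(99)
  before <- .Random.seed
  splitChains(LETTERS[1:6], seed = 4L)
  makeCVFolds(LETTERS[1:6], k = 3L, seed = 4L)
  expect_identical(.Random.seed, before)
})

test_that("pcc matches the closed-form on worked examples", {
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 2, 2, 5)), 6 / sqrt(45))
  expect_equal(pcc(1:5, 1:5), 1)
  expect_equal(pcc(1:5, 5:1), -1)
  expect_equal(pcc(1:5, 2 * (1:5) + 7), 1)   # affine invariance
  expect_error(pcc(1:3, 1:4), "lengths differ")
  expect_error(pcc(1:4, rep(2, 4)), "zero variance")
  set.seed(12)
  y <- rnorm(30); yh <- rnorm(30)
  expect_equal(pcc(y, yh), cor(y, yh), tolerance = 1e-12)
})

test_that("modelSpec presets carry the tuned hyperparameters", {
  expect_equal(modelSpec("ridge")@hyperparameters$alpha, 500)
  expect_equal(modelSpec("lasso")@hyperparameters$alpha, 1)
  expect_equal(modelSpec("lasso", preset = "esph-single")@hyperparameters$alpha,
               0.01)
  rf <- modelSpec("rf")@hyperparameters
  expect_equal(rf$n_trees, 2000)
  expect_equal(rf$min_samples_leaf, 5)
  expect_equal(modelSpec("rf", preset = "esph-single")@hyperparameters$n_trees,
               500)
  xgb <- modelSpec("xgboost")@hyperparameters
  expect_equal(xgb$n_trees, 50); expect_equal(xgb$max_depth, 3)
  svr <- modelSpec("svr")@hyperparameters
  expect_equal(svr$gamma, 0.001); expect_equal(svr$cost, 0.1)
  expect_equal(svr$epsilon, 0.1)
  ann <- modelSpec("ann")@hyperparameters
  expect_equal(ann$n_hidden_layers, 3); expect_equal(ann$nodes_per_layer, 900)
  annS <- modelSpec("ann", preset = "esph-single")@hyperparameters
  expect_equal(annS$n_hidden_layers, 4); expect_equal(annS$nodes_per_layer, 68)
  # overrides win
  expect_equal(modelSpec("rf", n_trees = 25)@hyperparameters$n_trees, 25)
  expect_error(modelSpec("kriging"), "unknown model family")
})

test_that("ridge closed form: alpha 0 is OLS, huge alpha shrinks to the mean", {
  set.seed(42)
  n <- 40; p <- 6
  X <- matrix(rnorm(n * p), n)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.1)
  m0 <- trainModel(modelSpec("ridge", alpha = 0), X, y)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  expect_equal(unname(m0$fit$beta), unname(ols[-1]), tolerance = 1e-10)
  expect_equal(m0$fit$intercept, unname(ols[1]), tolerance = 1e-10)
  mBig <- trainModel(modelSpec("ridge", alpha = 1e12), X, y)
  expect_equal(unname(predict(mBig, X)), rep(mean(y), n), tolerance = 1e-6)
  # the penalized normal equations hold at the reported solution
  m <- trainModel(modelSpec("ridge", alpha = 3), X, y)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  resid <- crossprod(Xc, yc - Xc %*% m$fit$beta) - 3 * m$fit$beta
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("lasso objective mapping: huge alpha gives the constant model", {
  set.seed(43)
  X <- matrix(rnorm(200), 40)
  y <- rnorm(40, mean = 3)
  m <- trainModel(modelSpec("lasso", alpha = 1e6), X, y)
  expect_equal(unname(predict(m, X)), rep(mean(y), 40), tolerance = 1e-6)
  # moderate alpha yields a sparse but non-trivial fit
  y2 <- drop(X %*% c(3, 0, 0, 0, 0)) + rnorm(40, sd = 0.1)
  m2 <- trainModel(modelSpec("lasso", alpha = 0.5), X, y2)
  expect_gt(pcc(y2, predict(m2, X)), 0.9)
})

test_that("stochastic trainers are deterministic given the spec seed", {
  set.seed(44)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  for (fam in c("rf", "xgboost", "ann")) {
    hp <- switch(fam, rf = list(n_trees = 30),
                 xgboost = list(n_trees = 10),
                 ann = list(nodes_per_layer = 8, n_hidden_layers = 2,
                            epochs = 3))
    spec <- do.call(modelSpec, c(list(family = fam, seed = 5L), hp))
    m1 <- trainModel(spec, X, y)
    m2 <- trainModel(spec, X, y)
    expect_equal(predict(m1, X), predict(m2, X), tolerance = 1e-12,
                 info = fam)
  }
  # svr and the linear models are deterministic outright
  for (fam in c("ridge", "lasso", "svr")) {
    m1 <- trainModel(modelSpec(fam), X, y)
    m2 <- trainModel(modelSpec(fam), X, y)
    expect_equal(predict(m1, X), predict(m2, X), tolerance = 1e-12,
                 info = fam)
  }
})

test_that("every family learns an easy smooth signal", {
  set.seed(45)
  n <- 120
  X <- matrix(runif(n * 4, -1, 1), n)
  y <- X[, 1] + 0.5 * X[, 2]^2 + rnorm(n, sd = 0.05)
  train <- 1:90; test <- 91:n
  specs <- list(
    modelSpec("ridge", alpha = 1),
    modelSpec("lasso", alpha = 0.05),
    modelSpec("rf", n_trees = 200, seed = 2L),
    modelSpec("xgboost", n_trees = 60, seed = 2L),
    modelSpec("svr", gamma = 0.5, cost = 10),
    modelSpec("ann", n_hidden_layers = 2, nodes_per_layer = 16,
              epochs = 60, seed = 2L))
  for (spec in specs) {
    m <- trainModel(spec, X[train, ], y[train])
    expect_gt(pcc(y[test], predict(m, X[test, ])), 0.6)
  }
})

test_that("predict validates feature-count mismatches", {
  X <- matrix(rnorm(60), 20)
  m <- trainModel(modelSpec("ridge", alpha = 1), X, rnorm(20))
  expect_error(predict(m, matrix(0, 2, 5)), "expects 3")
})

test_that("evaluateModel pools across chains and reports per-chain scores", {
  structs <- smallStructures(seed = 16L, nChains = 4L, nt = c(6L, 10L))
  cfg <- FeatureConfig(cutoff = 8, feRatio = 0.5, binSize = 0.5)
  ds <- buildDataset(structs, cfg)
  sp <- splitChains(unique(chainLabels(ds)), seed = 2L)
  trainSel <- chainLabels(ds) %in% sp$train
  m <- trainModel(modelSpec("ridge", alpha = 50),
                  featureMatrix(ds)[trainSel, ], targets(ds)[trainSel])
  test <- ds[, !trainSel]
  ev <- evaluateModel(m, test)
  expect_s3_class(ev, "EvalResult")
  expect_true(is.finite(ev$pcc))
  expect_setequal(names(ev$perChain), sp$test)
  expect_equal(ev$pcc, pcc(ev$y, ev$predictions))
  for (cid in names(ev$perChain)) {
    sel <- ev$chains == cid
    expect_equal(ev$perChain[[cid]], pcc(ev$y[sel], ev$predictions[sel]))
  }
})

test_that("cvScore pools out-of-fold predictions without chain leakage", {
  structs <- smallStructures(seed = 17L, nChains = 5L, nt = c(5L, 8L))
  cfg <- FeatureConfig(cutoff = 8, feRatio = 0.5, binSize = 0.5)
  ds <- buildDataset(structs, cfg)
  cv <- cvScore(ds, modelSpec("ridge", alpha = 50), k = 5L, seed = 3L)
  expect_true(all(is.finite(cv$predictions)))
  expect_true(all(cv$fold %in% 1:5))
  # every sample of a chain sits in the same fold
  ch <- chainLabels(ds)
  for (cid in unique(ch))
    expect_length(unique(cv$fold[ch == cid]), 1L)
  expect_equal(cv$pcc, pcc(targets(ds), cv$predictions))
  # deterministic
  cv2 <- cvScore(ds, modelSpec("ridge", alpha = 50), k = 5L, seed = 3L)
  expect_identical(cv, cv2)
})

test_that("gridSearch returns the argmax of its own score table", {
  structs <- smallStructures(seed = 18L, nChains = 5L, nt = c(5L, 7L))
  fg <- expand.grid(cutoff = c(6, 10), feRatio = 0.5, binSize = 1,
                    KEEP.OUT.ATTRS = FALSE)
  mg <- data.frame(alpha = c(1, 100))
  gs <- gridSearch(structs, fg, mg, family = "ridge",
                   elements = c("C", "P"), dims = 0L, k = 5L, seed = 1L)
  expect_equal(nrow(gs$table), 4L)
  best <- gs$table[which.max(gs$table$cv_pcc), ]
  expect_equal(gs$pcc, best$cv_pcc)
  expect_equal(gs$config@cutoff, best$cutoff)
  expect_equal(gs$spec@hyperparameters$alpha, best$alpha)
})

test_that("defaultSearchGrid spans the documented ranges", {
  g <- defaultSearchGrid()
  expect_setequal(unique(g$cutoff), seq(10, 45, by = 5))
  expect_setequal(unique(g$feRatio), seq(0.5, 1.0, by = 0.1))
  expect_setequal(unique(g$binSize), c(0.15, 0.5, 1.0, 1.5))
  expect_equal(nrow(g), 8 * 6 * 4)
})
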