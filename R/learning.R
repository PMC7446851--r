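#' @include features.R mlp.R
NULL

# run fn() under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Chain-level train/test split
#'
#' Chains never straddle the split: a whole chain lands either in training or
#' in test. The training size is round(trainFrac * n) clamped so that both
#' sides keep at least one chain.
#'
#' @param chains character vector of chain identifiers.
#' @param trainFrac fraction of chains for training (default 0.75).
#' @param seed integer seed; the split is a pure function of it.
#' @return list with \code{train} and \code{test} chain vectors.
#' @export
splitChains <- function(chains, trainFrac = 0.75, seed = 1L) {
  chains <- unique(as.character(chains))
  n <- length(chains)
  if (n < 2L) stop("need at least 2 chains to split")
  nTrain <- min(max(as.integer(round(trainFrac * n)), 1L), n - 1L)
  shuffled <- .with_seed(seed, function() sample(chains))
  list(train = sort(shuffled[seq_len(nTrain)]),
       test = sort(shuffled[(nTrain + 1L):n]))
}

#' Chain-level cross-validation folds
#'
#' @param chains character vector of (training) chain identifiers.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k character vectors partitioning \code{chains}; fold
#'   sizes differ by at most one.
#' @export
makeCVFolds <- function(chains, k = 5L, seed = 1L) {
  chains <- unique(as.character(chains))
  if (length(chains) < k) stop("fewer chains than folds")
  shuffled <- .with_seed(seed, function() sample(chains))
  unname(split(shuffled, rep_len(seq_len(k), length(chains))))
}

#' Pearson correlation between observed and predicted values
#'
#' Computed as \eqn{\sum (y_i - \bar y)(\hat y_i - \bar{\hat y}) /
#' \sqrt{\sum (y_i - \bar y)^2 \sum (\hat y_i - \bar{\hat y})^2}}.
#'
#' @param y observed values.
#' @param yhat predicted values, same length (>= 2).
#' @return correlation in [-1, 1].
#' @export
pcc <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 2L) stop("need at least 2 observations")
  dy <- y - mean(y); dh <- yhat - mean(yhat)
  den <- sqrt(sum(dy^2) * sum(dh^2))
  if (den == 0) stop("undefined PCC: zero variance in y or yhat")
  sum(dy * dh) / den
}

#' Construct a ModelSpec
#'
#' Family-specific hyperparameter keys (missing ones take these defaults,
#' which are the tuned values for the four-element feature set unless a
#' \code{preset} is named):
#' \describe{
#'   \item{ridge/lasso}{\code{alpha}: regularization weight of the penalized
#'     least-squares objective RSS + alpha * penalty.}
#'   \item{rf}{\code{n_trees}, \code{min_samples_leaf}; the number of split
#'     candidates follows mtry = ceiling(sqrt(p)).}
#'   \item{xgboost}{\code{n_trees}, \code{max_depth}.}
#'   \item{svr}{RBF kernel with \code{gamma}, \code{cost}, \code{epsilon}.}
#'   \item{ann}{\code{n_hidden_layers}, \code{nodes_per_layer} (sigmoid
#'     hidden, leaky-ReLU output), \code{dropout}, \code{epochs}.}
#' }
#' The \code{"esph-single"} preset carries the tuned values for
#' single-element features, \code{"esph-cnop"} (default) those for the
#' four-element concatenation.
#'
#' @param family one of ridge, lasso, rf, xgboost, svr, ann.
#' @param ... hyperparameter overrides (named).
#' @param preset \code{"esph-cnop"} or \code{"esph-single"}.
#' @param seed integer seed for stochastic trainers.
#' @return a validated \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(family, ..., preset = "esph-cnop", seed = 1L) {
  preset <- match.arg(preset, c("esph-cnop", "esph-single"))
  single <- preset == "esph-single"
  defaults <- switch(family,
    ridge = list(alpha = 500),
    lasso = list(alpha = if (single) 0.01 else 1),
    rf = list(n_trees = if (single) 500 else 2000, min_samples_leaf = 5),
    xgboost = list(n_trees = 50, max_depth = 3),
    svr = list(gamma = if (single) 0.01 else 0.001, cost = 0.1,
               epsilon = 0.1),
    ann = if (single)
      list(n_hidden_layers = 4, nodes_per_layer = 68, dropout = 0.2,
           epochs = 15)
    else
      list(n_hidden_layers = 3, nodes_per_layer = 900, dropout = 0.2,
           epochs = 10),
    stop("unknown model family: ", family))
  hp <- utils::modifyList(defaults, list(...))
  new("ModelSpec", family = family, hyperparameters = hp,
      seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  hp <- object@hyperparameters
  cat("ModelSpec:", object@family, "(",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
      ") seed =", object@seed, "\n")
  invisible(NULL)
})

# closed-form ridge (unpenalized intercept via centring); alpha = 0 is OLS
.fit_ridge <- function(X, y, alpha) {
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  beta <- if (alpha == 0) {
    qr_ <- qr(Xc)
    b <- qr.coef(qr_, yc)
    b[is.na(b)] <- 0
    b
  } else {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + alpha
    drop(solve(A, crossprod(Xc, yc)))
  }
  list(beta = beta, intercept = ybar - sum(xbar * beta))
}

#' Train a regression model on a feature matrix
#'
#' Dispatches on the spec's family. Ridge solves the penalized normal
#' equations in closed form (objective RSS + alpha * ||beta||^2, intercept
#' unpenalized); lasso delegates to glmnet with the lambda matching
#' RSS + alpha * ||beta||_1; rf to ranger with mtry = ceiling(sqrt(p));
#' xgboost to xgb.train; svr to an RBF-kernel epsilon-SVR; ann to the
#' built-in multilayer perceptron. rf, xgboost and ann are deterministic
#' given the spec seed; the others are deterministic outright.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param X n x p numeric matrix.
#' @param y length-n numeric response.
#' @return a \code{topoflexModel}; use \code{predict(model, newX)}.
#' @export
trainModel <- function(spec, X, y) {
  stopifnot(is(spec, "ModelSpec"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  hp <- spec@hyperparameters
  p <- ncol(X)
  fit <- switch(spec@family,
    ridge = .fit_ridge(X, y, hp$alpha),
    lasso = {
      n <- nrow(X)
      glmnet::glmnet(X, y, alpha = 1, lambda = hp$alpha / (2 * n),
                     standardize = FALSE, thresh = 1e-10)
    },
    rf = ranger::ranger(
      x = X, y = y,
      num.trees = as.integer(hp$n_trees),
      min.node.size = as.integer(hp$min_samples_leaf),
      mtry = ceiling(sqrt(p)),
      seed = spec@seed, num.threads = 1L),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(max_depth = as.integer(hp$max_depth),
                      seed = spec@seed, nthread = 1),
        data = dtrain, nrounds = as.integer(hp$n_trees), verbose = 0)
    },
    svr = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", gamma = hp$gamma, cost = hp$cost,
                     epsilon = hp$epsilon, scale = FALSE),
    ann = .mlp_train(X, y,
                     layers = as.integer(hp$n_hidden_layers),
                     nodes = as.integer(hp$nodes_per_layer),
                     dropout = hp$dropout,
                     epochs = as.integer(hp$epochs),
                     seed = spec@seed))
  structure(list(spec = spec, fit = fit, p = p,
                 features = colnames(X)),
            class = "topoflexModel")
}

#' Predict from a trained topoflex model
#' @param object a \code{topoflexModel} from \code{\link{trainModel}}.
#' @param newdata matrix (or \linkS4class{TopoDataset}) of features with the
#'   same columns as at training.
#' @param ... ignored.
#' @return numeric vector of predicted normalized B-factors.
#' @export
predict.topoflexModel <- function(object, newdata, ...) {
  if (is(newdata, "TopoDataset")) newdata <- featureMatrix(newdata)
  X <- as.matrix(newdata)
  if (ncol(X) != object$p)
    stop("newdata has ", ncol(X), " features; model expects ", object$p)
  if (is.null(colnames(X))) colnames(X) <- object$features
  fam <- object$spec@family
  fit <- object$fit
  switch(fam,
    ridge = drop(X %*% fit$beta) + fit$intercept,
    lasso = drop(stats::predict(fit, newx = X)),
    rf = stats::predict(fit, data = X, num.threads = 1L)$predictions,
    xgboost = stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    svr = drop(stats::predict(fit, newdata = X)),
    ann = .mlp_predict(fit, X))
}

#' @export
print.topoflexModel <- function(x, ...) {
  cat("topoflexModel (", x$spec@family, "), p =", x$p, "\n")
  invisible(x)
}

#' Evaluate a model on a held-out dataset
#'
#' Computes the pooled PCC over all test samples plus one PCC per test
#' chain. Chains with fewer than 2 samples, or zero variance in either the
#' observed or predicted values, are skipped with a warning. The pooled PCC
#' generally differs from the mean of the per-chain PCCs: pooling is
#' sensitive to between-chain offsets that per-chain correlations ignore.
#'
#' @param model a \code{topoflexModel}.
#' @param dataset test \linkS4class{TopoDataset} (chains disjoint from
#'   training).
#' @return list of class \code{EvalResult}: \code{pcc}, \code{perChain}
#'   (named vector), \code{predictions}, \code{y}, \code{chains}.
#' @export
evaluateModel <- function(model, dataset) {
  stopifnot(is(dataset, "TopoDataset"))
  if (ncol(dataset) == 0L) stop("empty test set")
  X <- featureMatrix(dataset)
  y <- targets(dataset)
  ch <- chainLabels(dataset)
  yhat <- predict(model, X)
  perChain <- c()
  for (cid in unique(ch)) {
    sel <- ch == cid
    r <- tryCatch(pcc(y[sel], yhat[sel]), error = function(e) {
      warning("chain ", cid, " skipped in per-chain PCC: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(r)) perChain[cid] <- r
  }
  structure(list(pcc = pcc(y, yhat), perChain = perChain,
                 predictions = yhat, y = y, chains = ch),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("pooled PCC = %.4f over %d samples in %d chain(s)\n",
              x$pcc, length(x$y), length(unique(x$chains))))
  if (length(x$perChain)) {
    cat("per-chain PCC:\n")
    for (cid in names(x$perChain))
      cat(sprintf("  %s: %.4f\n", cid, x$perChain[[cid]]))
  }
  invisible(x)
}

#' Chain-grouped k-fold cross-validation score
#'
#' Splits the dataset's chains into k folds, trains on k-1 folds, predicts
#' the held-out fold, pools all out-of-fold predictions and returns a single
#' PCC. No prediction ever comes from a model that saw its chain.
#'
#' @param dataset a \linkS4class{TopoDataset}.
#' @param spec a \linkS4class{ModelSpec}.
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return list: \code{pcc}, \code{predictions} (aligned with the dataset),
#'   \code{fold} (fold index per sample).
#' @export
cvScore <- function(dataset, spec, k = 5L, seed = 1L) {
  ch <- chainLabels(dataset)
  folds <- makeCVFolds(unique(ch), k = k, seed = seed)
  X <- featureMatrix(dataset)
  y <- targets(dataset)
  yhat <- rep(NA_real_, length(y))
  foldIdx <- rep(NA_integer_, length(y))
  for (f in seq_along(folds)) {
    testSel <- ch %in% folds[[f]]
    model <- trainModel(spec, X[!testSel, , drop = FALSE], y[!testSel])
    yhat[testSel] <- predict(model, X[testSel, , drop = FALSE])
    foldIdx[testSel] <- f
  }
  list(pcc = pcc(y, yhat), predictions = yhat, fold = foldIdx)
}

#' Default featurization search grid
#'
#' Cut-off E from 10 to 45 Angstrom in steps of 5, F/E from 0.5 to 1.0 in
#' steps of 0.1, bin size in {0.15, 0.5, 1.0, 1.5} Angstrom.
#'
#' @return data.frame with columns \code{cutoff}, \code{feRatio},
#'   \code{binSize}, one row per combination.
#' @export
defaultSearchGrid <- function() {
  expand.grid(cutoff = seq(10, 45, by = 5),
              feRatio = seq(0.5, 1.0, by = 0.1),
              binSize = c(0.15, 0.5, 1.0, 1.5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Joint grid search over featurization and model hyperparameters
#'
#' For every feature configuration the (training) structures are featurized
#' once; every model-hyperparameter combination is then scored by chain-
#' grouped k-fold CV (pooled out-of-fold PCC). Combinations that fail to
#' train are recorded with a missing score and skipped. Returns the argmax
#' and the full score table.
#'
#' @param structures training \linkS4class{StructureSet}(s) — test chains
#'   must not be included.
#' @param featureGrid data.frame with columns \code{cutoff},
#'   \code{feRatio}, \code{binSize} (see \code{\link{defaultSearchGrid}}).
#' @param modelGrid data.frame of hyperparameter combinations for
#'   \code{family} (one column per hyperparameter key).
#' @param family model family passed to \code{\link{modelSpec}}.
#' @param elements,dims featurization element set and homology dimensions.
#' @param k CV folds.
#' @param seed seed for fold assignment and stochastic trainers.
#' @return list: \code{config} (best \linkS4class{FeatureConfig}),
#'   \code{spec} (best \linkS4class{ModelSpec}), \code{pcc} (its CV score),
#'   \code{table} (score data.frame).
#' @export
gridSearch <- function(structures, featureGrid, modelGrid, family,
                       elements = c("C", "N", "O", "P"), dims = c(0L, 1L),
                       k = 5L, seed = 1L) {
  stopifnot(nrow(featureGrid) >= 1L, nrow(modelGrid) >= 1L)
  rows <- list()
  best <- list(pcc = -Inf)
  for (i in seq_len(nrow(featureGrid))) {
    cfg <- FeatureConfig(cutoff = featureGrid$cutoff[i],
                         feRatio = featureGrid$feRatio[i],
                         binSize = featureGrid$binSize[i],
                         elements = elements, dims = dims)
    ds <- buildDataset(structures, cfg)
    for (j in seq_len(nrow(modelGrid))) {
      hp <- as.list(modelGrid[j, , drop = FALSE])
      spec <- do.call(modelSpec, c(list(family = family, seed = seed), hp))
      score <- tryCatch(cvScore(ds, spec, k = k, seed = seed)$pcc,
                        error = function(e) {
                          warning("combination failed: ",
                                  conditionMessage(e))
                          NA_real_
                        })
      rows[[length(rows) + 1L]] <- cbind(
        featureGrid[i, , drop = FALSE],
        modelGrid[j, , drop = FALSE],
        data.frame(cv_pcc = score))
      if (is.finite(score) && score > best$pcc)
        best <- list(pcc = score, config = cfg, spec = spec)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.finite(best$pcc)) stop("every grid combination failed")
  list(config = best$config, spec = best$spec, pcc = best$pcc, table = tab)
}
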