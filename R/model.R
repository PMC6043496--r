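# Classifier layer. Four algorithm families sit behind one surface:
# random forest (ranger), gradient boosting (xgboost), regularized linear
# model (glmnet) and SVM (e1071). Hyperparameter search, when requested,
# selects by inner cross-validated AUC.

#' Classifier specification
#'
#' Documented default hyperparameters per family (all overridable through
#' \code{hyperparameters} or searchable through \code{searchSpace}):
#' \describe{
#'   \item{random_forest}{\code{num.trees} 500, \code{mtry}
#'     floor(sqrt(p)), \code{min.node.size} 1.}
#'   \item{gradient_boosting}{\code{nrounds} 150, \code{eta} 0.1,
#'     \code{max_depth} 3, \code{subsample} 0.8, \code{colsample_bytree}
#'     1. Row subsampling is essential under exact degree-balanced
#'     training: with parity, every split on a per-protein feature has
#'     exactly zero gain on the full sample, so deterministic boosting
#'     never grows a tree (see the methods vignette).}
#'   \item{linear_model}{ridge-penalized logistic regression;
#'     \code{alpha} 0, \code{lambda} 0.01, solved along a warm-start
#'     path. Note that on exactly degree-balanced training sets the
#'     intercept is a stationary point of any generalized linear model,
#'     so a GLM can only exploit marginal (single-protein) signal.}
#'   \item{svm}{radial kernel; \code{cost} 1, \code{gamma} 1/p; Platt
#'     probabilities, orientation-checked against the decision values
#'     (the backing library ties its sign convention to training row
#'     order).}
#' }
#'
#' @param algorithm Algorithm family.
#' @param hyperparameters Named list of overrides.
#' @param search \code{"none"} (default), \code{"grid"} (Cartesian product
#'   of \code{searchSpace}) or \code{"random"} (\code{nIter} draws from it).
#' @param searchSpace Named list of candidate values per hyperparameter.
#' @param nIter Draws for random search.
#' @param innerFolds Folds of the inner CV that scores candidates by AUC.
#' @param seed RNG seed used for fitting and search.
#' @return A \linkS4class{ClassifierSpec}.
#' @export
classifierSpec <- function(algorithm = c("random_forest", "gradient_boosting",
                                         "linear_model", "svm"),
                           hyperparameters = list(), search = "none",
                           searchSpace = list(), nIter = 10L,
                           innerFolds = 3L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (search != "none" && length(searchSpace) == 0L)
    configError("search = '%s' requires a non-empty searchSpace", search)
  new("ClassifierSpec", algorithm = algorithm,
      hyperparameters = hyperparameters, search = search,
      searchSpace = searchSpace, nIter = as.integer(nIter),
      innerFolds = as.integer(innerFolds), seed = as.integer(seed))
}

defaultHyperparameters <- function(algorithm, p) {
  switch(algorithm,
    random_forest = list(num.trees = 500L, mtry = max(1L, floor(sqrt(p))),
                         min.node.size = 1L),
    gradient_boosting = list(nrounds = 150L, eta = 0.1, max_depth = 3L,
                             subsample = 0.8, colsample_bytree = 1),
    linear_model = list(alpha = 0, lambda = 0.01),
    svm = list(cost = 1, gamma = 1 / p))
}

resolveHyperparameters <- function(spec, p, overrides = NULL) {
  hp <- defaultHyperparameters(spec@algorithm, p)
  hp[names(spec@hyperparameters)] <- spec@hyperparameters
  if (!is.null(overrides)) hp[names(overrides)] <- overrides
  hp
}

# Fit one classifier on a feature matrix. y is integer 0/1.
fitOne <- function(X, y, algorithm, hp, seed) {
  switch(algorithm,
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)), probability = TRUE,
      num.trees = hp$num.trees, mtry = min(hp$mtry, ncol(X)),
      min.node.size = hp$min.node.size, seed = seed, num.threads = 1L),
    gradient_boosting = {
      set.seed(seed)
      xgboost::xgboost(X, factor(y, levels = c(0L, 1L)),
                       nrounds = hp$nrounds, objective = "binary:logistic",
                       learning_rate = hp$eta, max_depth = hp$max_depth,
                       subsample = hp$subsample,
                       colsample_bytree = hp$colsample_bytree,
                       nthreads = 1L, seed = seed, verbosity = 0)
    },
    linear_model = {
      set.seed(seed)
      # warm-start path down to the requested lambda: single-lambda fits
      # converge poorly
      path <- exp(seq(log(max(1, hp$lambda * 100)),
                      log(hp$lambda), length.out = 30L))
      list(glmnet = glmnet::glmnet(X, y, family = "binomial",
                                   alpha = hp$alpha, lambda = path),
           lambda = hp$lambda)
    },
    svm = {
      set.seed(seed)
      # constant columns (unobserved dipeptides) cannot be scaled; e1071
      # warns and ignores them, which is the intended behaviour here
      fit <- suppressWarnings(
        e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                   kernel = "radial", cost = hp$cost,
                   gamma = hp$gamma, probability = TRUE))
      # e1071 orients Platt probabilities by training row order; detect a
      # flipped "1" column against the model's own class predictions
      pr <- attr(predict(fit, X, probability = TRUE),
                 "probabilities")[, "1"]
      cls <- as.integer(as.character(predict(fit, X)))
      flip <- length(unique(cls)) == 2L &&
        mean(pr[cls == 1L]) < mean(pr[cls == 0L])
      list(svm = fit, flip = flip)
    })
}

# Probability of the positive class for a fitted object.
scoreOne <- function(fit, algorithm, X) {
  switch(algorithm,
    random_forest = {
      p <- predict(fit, data = X, num.threads = 1L)$predictions
      as.numeric(p[, "1"])
    },
    gradient_boosting = as.numeric(predict(fit, X)),
    linear_model = as.numeric(predict(fit$glmnet, X, s = fit$lambda,
                                      type = "response")),
    svm = {
      pr <- predict(fit$svm, X, probability = TRUE)
      p <- as.numeric(attr(pr, "probabilities")[, "1"])
      if (fit$flip) 1 - p else p
    })
}

searchCandidates <- function(spec) {
  if (spec@search == "grid") {
    grid <- expand.grid(spec@searchSpace, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else {
    withr::with_seed(spec@seed, lapply(seq_len(spec@nIter), function(i)
      lapply(spec@searchSpace, function(v) v[[sample.int(length(v), 1L)]])))
  }
}

# Inner stratified CV AUC for one hyperparameter candidate.
innerCvAuc <- function(X, y, algorithm, hp, folds, seed) {
  aucs <- vapply(sort(unique(folds)), function(i) {
    fit <- fitOne(X[folds != i, , drop = FALSE], y[folds != i],
                  algorithm, hp, seed)
    rocAuc(scoreOne(fit, algorithm, X[folds == i, , drop = FALSE]),
           y[folds == i])
  }, numeric(1))
  mean(aucs)
}

#' Train a classifier on an interaction dataset
#'
#' Encodes every pair as its 940-dimensional vector, optionally selects
#' hyperparameters by inner cross-validated AUC over the search space, fits
#' the requested classifier, and binds the fit to the feature schema and a
#' training fingerprint. Training is deterministic under a fixed seed for
#' the tree and linear families; the SVM probability calibration is seeded
#' but only reproducible to solver tolerance.
#'
#' @param trainSet An \linkS4class{InteractionDataset} with both labels.
#' @param cfg A \linkS4class{PaacConfig}.
#' @param spec A \linkS4class{ClassifierSpec}.
#' @param cache Optional per-sequence encoding matrix from
#'   \code{\link{encodeStore}}.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainModel <- function(trainSet, cfg = paacConfig(), spec = classifierSpec(),
                       cache = NULL) {
  stopifnot(is(trainSet, "InteractionDataset"), is(spec, "ClassifierSpec"))
  recs <- records(trainSet)
  y <- labelsToBinary(recs$label)
  if (length(unique(y)) < 2L)
    userError("training set must contain both classes")
  X <- pairFeatureMatrix(recs, sequenceStore(trainSet), cfg, cache = cache)
  chosen <- NULL
  if (spec@search != "none") {
    candidates <- searchCandidates(spec)
    k <- spec@innerFolds
    folds <- integer(length(y))
    folds[y == 1L] <- withr::with_seed(spec@seed,
      sample(rep_len(seq_len(k), sum(y == 1L))))
    folds[y == 0L] <- withr::with_seed(spec@seed + 1L,
      sample(rep_len(seq_len(k), sum(y == 0L))))
    scores <- vapply(candidates, function(cand)
      innerCvAuc(X, y, spec@algorithm,
                 resolveHyperparameters(spec, ncol(X), cand), folds,
                 spec@seed), numeric(1))
    chosen <- candidates[[which.max(scores)]]
  }
  hp <- resolveHyperparameters(spec, ncol(X), chosen)
  fit <- fitOne(X, y, spec@algorithm, hp, spec@seed)
  resolved <- initialize(spec, hyperparameters = hp, search = "none",
                         searchSpace = list())
  fp <- sprintf("n=%d;pos=%d;neg=%d;p=%d;checksum=%.10e;seed=%d",
                nrow(X), sum(y == 1L), sum(y == 0L), ncol(X), sum(X),
                spec@seed)
  new("TrainedModel", algorithm = spec@algorithm, spec = resolved,
      fit = fit, featureSchema = colnames(X), fingerprint = fp)
}

#' Score (IDP, partner) pairs with a trained model
#'
#' @param model A \linkS4class{TrainedModel}.
#' @param pairs Record \code{data.frame} with \code{idpId} and
#'   \code{partnerId} columns (an \linkS4class{InteractionDataset} is also
#'   accepted).
#' @param cfg The \linkS4class{PaacConfig} used at training time.
#' @param store \code{AAStringSet} resolving every referenced id.
#' @param cache Optional per-sequence encoding matrix.
#' @return Numeric vector of probability-like scores in [0, 1], one per
#'   pair, in input order.
#' @export
predictPairs <- function(model, pairs, cfg = paacConfig(), store = NULL,
                         cache = NULL) {
  stopifnot(is(model, "TrainedModel"))
  if (is(pairs, "InteractionDataset")) {
    if (is.null(store)) store <- sequenceStore(pairs)
    pairs <- records(pairs)
  }
  if (is.null(store) && is.null(cache))
    userError("predictPairs needs a sequence store or an encoding cache")
  X <- pairFeatureMatrix(pairs, store, cfg, cache = cache)
  if (!identical(colnames(X), model@featureSchema))
    userError("feature schema mismatch: model was trained on a different encoding")
  scoreOne(model@fit, model@algorithm, X)
}

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s on %d features\n", object@algorithm,
              length(object@featureSchema)))
  cat("  fingerprint:", object@fingerprint, "\n")
})

#' Persist a trained model
#'
#' Single-file persistence with the feature schema and training fingerprint
#' embedded; \code{\link{loadModel}} refuses files that do not contain a
#' disoPPI model, and prediction refuses mismatched schemas.
#'
#' @param model A \linkS4class{TrainedModel}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  saveRDS(list(format = "disoPPI-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) userError("model file not found: %s", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "disoPPI-model") ||
      !is(obj$model, "TrainedModel"))
    userError("%s is not a disoPPI model file", path)
  obj$model
}
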