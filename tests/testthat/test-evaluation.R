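test_that("confusion counts follow the >= threshold convention", {
  expect_equal(confusionAtThreshold(c(0.9, 0.1), c(1, 0)),
               c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  # a score of exactly 0.5 predicts positive
  expect_equal(confusionAtThreshold(0.5, 0)[["fp"]], 1L)
  expect_equal(confusionAtThreshold(0.5, 1)[["tp"]], 1L)
  expect_error(confusionAtThreshold(c(0.1, 0.2), 1), "differ in length")
  withr::with_seed(19, {
    sc <- runif(100); y <- rbinom(100, 1, 0.4)
    cm <- confusionAtThreshold(sc, y, 0.37)
    expect_equal(cm[["tp"]], sum(sc >= 0.37 & y == 1))
    expect_equal(sum(cm), 100L)
  })
})

test_that("threshold metrics match hand computation and flag degeneracies", {
  m <- classificationMetrics(c(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m[["acc"]], 0.7)
  expect_equal(m[["precision"]], 3 / 4)
  expect_equal(m[["recall"]], 3 / 5)
  expect_equal(m[["fallout"]], 1 / 5)
  expect_equal(m[["f"]], 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_equal(m[["mcc"]], (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))
  perfect <- classificationMetrics(c(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(unname(perfect[c("acc", "f", "mcc")]), c(1, 1, 1))
  coin <- classificationMetrics(c(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(coin[["mcc"]], 0)
  expect_equal(coin[["acc"]], 0.5)
  degenerate <- classificationMetrics(c(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(degenerate[["precision"]], 0)
  expect_true("precision" %in% attr(degenerate, "flagged"))
})

test_that("MCC is bounded and symmetric under simultaneous class flips", {
  withr::with_seed(23, {
    for (i in 1:25) {
      sc <- runif(40)
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      m <- classificationMetrics(confusionAtThreshold(sc, y))[["mcc"]]
      flipped <- classificationMetrics(confusionAtThreshold(1 - sc +
        1e-9, 1 - y))[["mcc"]]
      expect_gte(m, -1); expect_lte(m, 1)
      expect_equal(m, mccOracle(sc, y), tolerance = 1e-12)
      expect_equal(m, flipped, tolerance = 1e-12)
    }
  })
})

test_that("rank AUC handles separation, ties and random fixtures", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
  withr::with_seed(29, {
    for (i in 1:25) {
      sc <- round(runif(30), 2)  # rounding forces ties
      y <- rbinom(30, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(rocAuc(sc, y), aucOracle(sc, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(31, {
    sc <- runif(50); y <- rbinom(50, 1, 0.5)
    expect_equal(rocAuc(sc, y), rocAuc(qlogis(sc * 0.98 + 0.01), y),
                 tolerance = 1e-12)
    expect_equal(rocAuc(sc, y), rocAuc(sc^3, y), tolerance = 1e-12)
  })
})

test_that("average-precision AUPRC matches the step-wise oracle", {
  expect_equal(prAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  withr::with_seed(37, {
    for (i in 1:25) {
      sc <- round(runif(30), 2)
      y <- rbinom(30, 1, 0.4)
      if (length(unique(y)) < 2) next
      expect_equal(prAuc(sc, y), apOracle(sc, y), tolerance = 1e-12)
    }
  })
})

test_that("rank AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    sc <- runif(60); y <- rbinom(60, 1, 0.5)
    expect_equal(rocAuc(sc, y),
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                                levels = c(0, 1),
                                                direction = "<"))),
                 tolerance = 1e-12)
  })
})

test_that("report aggregation is exactly the mean and sd of the rows", {
  pr <- data.frame(auc = c(0.7, 0.8, 0.75), acc = c(0.6, 0.65, 0.7))
  rep <- evaluationReport(pr, meta = list(note = "unit"))
  ag <- aggregated(rep)
  expect_equal(ag$mean[ag$metric == "auc"], mean(pr$auc), tolerance = 1e-13)
  expect_equal(ag$sd[ag$metric == "acc"], sd(pr$acc), tolerance = 1e-13)
  # tampering with the aggregate slot trips the validity method
  broken <- rep
  broken@aggregate$mean[1] <- 0.99
  expect_error(validObject(broken), "mean/sd")
})

test_that("cross-validation produces per-fold rows and catches bad k", {
  sc <- syntheticConfig(nIdps = 10L, nPartners = 50L,
                        idpLengthRange = c(60L, 100L),
                        partnerLengthRange = c(60L, 100L), seed = 77)
  store <- generateSequences(sc)
  net <- generateNetwork(store, sc)
  neg <- sampleNegatives(net, mode = "balanced", seed = 78)
  ds <- bindRecords(net, neg)
  enc <- encodeStore(store, paacConfig())
  rep <- crossValidate(ds, paacConfig(),
                       classifierSpec("random_forest",
                                      hyperparameters = list(num.trees = 100L),
                                      seed = 7),
                       k = 3L, seed = 7, cache = enc)
  expect_equal(nrow(perRepeat(rep)), 3L)
  expect_true(all(c("auc", "auprc", "acc", "f", "mcc", "precision",
                    "recall", "fallout") %in% names(perRepeat(rep))))
  rep2 <- crossValidate(ds, paacConfig(),
                        classifierSpec("random_forest",
                                       hyperparameters = list(num.trees = 100L),
                                       seed = 7),
                        k = 3L, seed = 7, cache = enc)
  expect_equal(perRepeat(rep), perRepeat(rep2))
  expect_error(crossValidate(ds, paacConfig(), classifierSpec(), k = 1L),
               ">= 2")
  expect_error(crossValidate(ds, paacConfig(), classifierSpec(),
                             k = 10000L), "exceeds")
})

test_that("holdout evaluation reports mean +- sd per imbalance ratio", {
  sc <- syntheticConfig(nIdps = 10L, nPartners = 60L,
                        idpLengthRange = c(60L, 100L),
                        partnerLengthRange = c(60L, 100L), seed = 55)
  net <- generateNetwork(generateSequences(sc), sc)
  reports <- evaluateHoldout(net, paacConfig(),
                             classifierSpec("random_forest",
                                            hyperparameters = list(num.trees = 100L),
                                            seed = 5),
                             splitSpec(nRepeats = 2, seed = 5),
                             negativeRatios = c(1, 5))
  expect_named(reports, c("1N", "5N"))
  for (r in reports) {
    expect_equal(nrow(perRepeat(r)), 2L)
    expect_s4_class(r, "EvaluationReport")
  }
  # evaluating a dataset that already contains negatives is refused
  neg <- sampleNegatives(net, mode = "balanced", seed = 6)
  expect_error(evaluateHoldout(bindRecords(net, neg)), "positives-only")
})

test_that("reports and scores export to delimited text plus JSON", {
  pr <- data.frame(auc = c(0.7, 0.8), acc = c(0.6, 0.7))
  rep <- evaluationReport(pr, meta = list(ratio = "1N"))
  prefix <- tempfile("report")
  writeReport(rep, prefix)
  expect_true(file.exists(paste0(prefix, ".tsv")))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$meta$ratio, "1N")
  recs <- data.frame(idpId = "a", partnerId = "b", label = "positive")
  path <- tempfile(fileext = ".tsv")
  writeScores(recs, 0.8, path)
  tab <- read.delim(path)
  expect_equal(tab$score, 0.8)
  expect_equal(tab$label, 1L)
})
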