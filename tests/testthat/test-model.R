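# Small planted-rule dataset shared by the model tests: positives pair
# charge-complementary proteins, negatives are degree-balanced.
modelFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- syntheticConfig(nIdps = 12L, nPartners = 80L,
                            idpLengthRange = c(80L, 160L),
                            partnerLengthRange = c(80L, 160L), seed = 99)
      store <- generateSequences(sc)
      net <- generateNetwork(store, sc)
      neg <- sampleNegatives(net, mode = "balanced", seed = 100)
      cache <<- list(store = store, net = net,
                     train = bindRecords(net, neg),
                     enc = encodeStore(store, paacConfig()))
    }
    cache
  }
})

test_that("classifier specifications validate algorithm and search settings", {
  expect_error(classifierSpec("neural_net"), "arg")
  expect_error(classifierSpec("svm", search = "grid"), "searchSpace")
  spec <- classifierSpec("random_forest", search = "random",
                         searchSpace = list(num.trees = c(100L, 200L)))
  expect_s4_class(spec, "ClassifierSpec")
})

test_that("training requires both classes and an intact schema", {
  fx <- modelFixture()
  expect_error(trainModel(fx$net, paacConfig(), classifierSpec()),
               "both classes")
  model <- trainModel(fx$train, paacConfig(), classifierSpec(seed = 5),
                      cache = fx$enc)
  expect_s4_class(model, "TrainedModel")
  expect_length(model@featureSchema, 940L)
  # a different lambda changes the schema and must be refused
  small <- paacConfig(lambda = 10L)
  expect_error(predictPairs(model, records(fx$net)[1:2, ], small,
                            store = fx$store), "schema")
})

test_that("scores are probabilities, order-stable and seed-deterministic", {
  fx <- modelFixture()
  model <- trainModel(fx$train, paacConfig(), classifierSpec(seed = 5),
                      cache = fx$enc)
  recs <- records(fx$net)[c(1, 2, 1), ]
  sc <- predictPairs(model, recs, paacConfig(), cache = fx$enc)
  expect_length(sc, 3L)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc[1], sc[3])  # duplicated input pair, identical score
  model2 <- trainModel(fx$train, paacConfig(), classifierSpec(seed = 5),
                       cache = fx$enc)
  expect_identical(predictPairs(model2, recs, paacConfig(), cache = fx$enc),
                   sc)
})

test_that("every algorithm family trains and scores the fixture", {
  fx <- modelFixture()
  recs <- records(fx$train)
  y <- as.integer(recs$label == "positive")
  for (alg in c("random_forest", "gradient_boosting", "linear_model",
                "svm")) {
    model <- trainModel(fx$train, paacConfig(),
                        classifierSpec(alg, seed = 2), cache = fx$enc)
    sc <- predictPairs(model, recs, paacConfig(), cache = fx$enc)
    expect_true(all(sc >= 0 & sc <= 1), info = alg)
    if (alg != "linear_model") {
      # the nonlinear families separate their own training data; a GLM
      # cannot: under exact degree parity the intercept is a stationary
      # point for any linear model (see the methods vignette)
      expect_gt(rocAuc(sc, y), 0.6)
    }
  }
})

test_that("the linear model learns marginal signal when training negatives are random", {
  fx <- modelFixture()
  negR <- sampleNegatives(fx$net, mode = "random", seed = 101)
  trainR <- bindRecords(fx$net, negR)
  recs <- records(trainR)
  y <- as.integer(recs$label == "positive")
  model <- trainModel(trainR, paacConfig(),
                      classifierSpec("linear_model", seed = 2),
                      cache = fx$enc)
  sc <- predictPairs(model, recs, paacConfig(), cache = fx$enc)
  expect_gt(rocAuc(sc, y), 0.6)
})

test_that("pairs obeying the planted rule outscore pairs violating it", {
  fx <- modelFixture()
  model <- trainModel(fx$train, paacConfig(), classifierSpec(seed = 5),
                      cache = fx$enc)
  q <- vapply(seq_along(fx$store),
              function(i) netChargeFraction(as.character(fx$store[[i]])),
              numeric(1))
  names(q) <- names(fx$store)
  partners <- setdiff(names(fx$store), idpIds(fx$net))
  idp <- idpIds(fx$net)[which.max(q[idpIds(fx$net)])]
  match <- partners[order(abs(q[partners] + q[idp]))][1:10]
  clash <- partners[order(-abs(q[partners] + q[idp]))][1:10]
  scM <- predictPairs(model, data.frame(idpId = idp, partnerId = match),
                      paacConfig(), cache = fx$enc)
  scC <- predictPairs(model, data.frame(idpId = idp, partnerId = clash),
                      paacConfig(), cache = fx$enc)
  expect_gt(mean(scM), mean(scC))
})

test_that("grid search selects hyperparameters by inner CV AUC", {
  fx <- modelFixture()
  spec <- classifierSpec("random_forest", search = "grid",
                         searchSpace = list(num.trees = c(50L, 100L),
                                            min.node.size = c(1L, 5L)),
                         innerFolds = 2L, seed = 3)
  model <- trainModel(fx$train, paacConfig(), spec, cache = fx$enc)
  hp <- model@spec@hyperparameters
  expect_true(hp$num.trees %in% c(50L, 100L))
  expect_true(hp$min.node.size %in% c(1L, 5L))
  expect_equal(model@spec@search, "none")  # resolved spec is frozen
})

test_that("model persistence embeds and enforces the format", {
  fx <- modelFixture()
  model <- trainModel(fx$train, paacConfig(), classifierSpec(seed = 5),
                      cache = fx$enc)
  path <- tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(back@featureSchema, model@featureSchema)
  expect_identical(back@fingerprint, model@fingerprint)
  recs <- records(fx$net)[1:3, ]
  expect_identical(predictPairs(back, recs, paacConfig(), cache = fx$enc),
                   predictPairs(model, recs, paacConfig(), cache = fx$enc))
  junk <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(loadModel(junk), "not a disoPPI model")
})
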