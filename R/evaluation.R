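# Evaluation: confusion counts at the 0.5 threshold, the metric suite
# (ACC, precision, recall, fall-out, F, MCC), rank-statistic AUC,
# average-precision AUPRC, cross-validation, and repeated C2 holdout
# evaluation with imbalance sweeps.

# Normalize labels to 0/1 integers. Accepts numeric 0/1, logical, or
# "positive"/"negative" strings.
labelsToBinary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative")))
      userError("labels must be 0/1 or 'positive'/'negative'")
    return(as.integer(labels == "positive"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (!all(labels %in% c(0, 1)))
    userError("numeric labels must be 0 or 1")
  as.integer(labels)
}

#' Confusion counts at a score threshold
#'
#' A score greater than or equal to the threshold predicts the positive
#' class (the boundary score of exactly 0.5 counts as a positive
#' prediction).
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels Binary labels (0/1 or "positive"/"negative").
#' @param threshold Decision threshold; default 0.5.
#' @return Named integer vector \code{c(tp, fp, tn, fn)}.
#' @export
#' @examples
#' confusionAtThreshold(c(0.9, 0.1), c(1, 0))
confusionAtThreshold <- function(scores, labels, threshold = 0.5) {
  y <- labelsToBinary(labels)
  if (length(scores) != length(y))
    userError("scores (%d) and labels (%d) differ in length",
              length(scores), length(y))
  pred <- as.integer(scores >= threshold)
  c(tp = sum(pred == 1L & y == 1L), fp = sum(pred == 1L & y == 0L),
    tn = sum(pred == 0L & y == 0L), fn = sum(pred == 0L & y == 1L))
}

#' Threshold metrics from confusion counts
#'
#' ACC, precision, recall (sensitivity), fall-out (false positive rate),
#' F score and the Matthews correlation coefficient. Any metric with a zero
#' denominator is defined as 0 and listed in the \code{"flagged"} attribute
#' rather than returned as NaN, so small folds still aggregate.
#'
#' @param counts Result of \code{\link{confusionAtThreshold}} (or any named
#'   vector/list with tp, fp, tn, fn).
#' @return Named numeric vector (acc, precision, recall, fallout, f, mcc)
#'   with attribute \code{flagged}.
#' @export
classificationMetrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  total <- tp + fp + tn + fn
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); 0 } else num / den
  }
  acc <- safe(tp + tn, total, "acc")
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  fallout <- safe(fp, fp + tn, "fallout")
  f <- safe(2 * precision * recall, precision + recall, "f")
  mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mccDen, "mcc")
  out <- c(acc = acc, precision = precision, recall = recall,
           fallout = fallout, f = f, mcc = mcc)
  attr(out, "flagged") <- flagged
  out
}

#' Area under the ROC curve
#'
#' Computed as the rank statistic: the probability that a random positive
#' scores above a random negative, with ties counted one half (equivalent to
#' the trapezoidal ROC area with average-rank tie handling).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  y <- labelsToBinary(labels)
  if (length(scores) != length(y))
    userError("scores and labels differ in length")
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0L || N == 0L)
    userError("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Average-precision (step-wise) convention without linear interpolation:
#' thresholds descend through the unique score values and each recall
#' increment is weighted by the precision at that threshold. Tied scores
#' enter as a single threshold.
#'
#' @inheritParams rocAuc
#' @return AUPRC in (0, 1].
#' @export
prAuc <- function(scores, labels) {
  y <- labelsToBinary(labels)
  if (length(scores) != length(y))
    userError("scores and labels differ in length")
  P <- sum(y == 1L)
  if (P == 0L || sum(y == 0L) == 0L)
    userError("AUPRC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  cumTp <- cumsum(yy)
  cumPred <- seq_along(yy)
  last <- which(diff(c(s, -Inf)) != 0)  # last index of each tied block
  prec <- cumTp[last] / cumPred[last]
  rec <- cumTp[last] / P
  sum(diff(c(0, rec)) * prec)
}

#' Assemble an evaluation report
#'
#' @param perRepeat \code{data.frame} of per-repeat (or per-fold) metric
#'   rows; a \code{repeat.} column is added if absent.
#' @param meta Optional provenance list.
#' @return An \linkS4class{EvaluationReport}; the aggregate slot holds the
#'   exact arithmetic mean and sd of each metric column.
#' @export
evaluationReport <- function(perRepeat, meta = list()) {
  if (!"repeat." %in% names(perRepeat))
    perRepeat <- cbind(repeat. = seq_len(nrow(perRepeat)), perRepeat)
  metrics <- setdiff(names(perRepeat), "repeat.")
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(perRepeat[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(perRepeat) > 1L) sd(perRepeat[[m]]) else 0, numeric(1)),
    row.names = NULL)
  new("EvaluationReport", perRepeat = perRepeat, aggregate = agg, meta = meta)
}

#' @describeIn EvaluationReport-class Per-repeat metric table.
#' @export
setMethod("perRepeat", "EvaluationReport", function(x) x@perRepeat)

#' @describeIn EvaluationReport-class Aggregate mean/sd table.
#' @export
setMethod("aggregated", "EvaluationReport", function(x) x@aggregate)

setMethod("show", "EvaluationReport", function(object) {
  ag <- object@aggregate
  cat(sprintf("EvaluationReport: %d repeat(s)\n", nrow(object@perRepeat)))
  for (i in seq_len(nrow(ag)))
    cat(sprintf("  %-9s %.3f ± %.3f\n", ag$metric[i], ag$mean[i],
                ag$sd[i]))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, paste,
        collapse = ",")), sep = "=", collapse = " "), "\n")
})

# Full metric row for one scored test set.
metricRow <- function(scores, labels, threshold = 0.5) {
  cm <- classificationMetrics(confusionAtThreshold(scores, labels, threshold))
  c(auc = rocAuc(scores, labels), auprc = prAuc(scores, labels),
    acc = cm[["acc"]], f = cm[["f"]], mcc = cm[["mcc"]],
    precision = cm[["precision"]], recall = cm[["recall"]],
    fallout = cm[["fallout"]])
}

#' Stratified k-fold cross-validation
#'
#' Pair-level stratified folds: positives and negatives are each dealt
#' across the k folds, every fold is scored by a model trained on the other
#' k - 1, and the per-fold metric rows are aggregated as mean and sd.
#'
#' @param dataset An \linkS4class{InteractionDataset} with both labels.
#' @param cfg A \linkS4class{PaacConfig}.
#' @param spec A \linkS4class{ClassifierSpec}.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param cache Optional per-sequence encoding matrix from
#'   \code{\link{encodeStore}}.
#' @return An \linkS4class{EvaluationReport} with one row per fold.
#' @export
crossValidate <- function(dataset, cfg = paacConfig(), spec = classifierSpec(),
                          k = 10L, seed = 1L, cache = NULL) {
  if (k < 2L) userError("k must be >= 2")
  recs <- records(dataset)
  y <- labelsToBinary(recs$label)
  if (min(table(y)) < k)
    userError("k = %d exceeds the size of the smaller class (%d)",
              k, min(table(y)))
  fold <- integer(nrow(recs))
  fold[y == 1L] <- withr::with_seed(seed,
    sample(rep_len(seq_len(k), sum(y == 1L))))
  fold[y == 0L] <- withr::with_seed(seed + 1L,
    sample(rep_len(seq_len(k), sum(y == 0L))))
  if (is.null(cache))
    cache <- encodeStore(sequenceStore(dataset)[unique(c(recs$idpId,
                                                         recs$partnerId))],
                         cfg)
  rows <- lapply(seq_len(k), function(i) {
    train <- subsetRecords(dataset, fold != i)
    test <- subsetRecords(dataset, fold == i)
    if (length(unique(records(test)$label)) < 2L)
      userError("fold %d lacks one of the classes", i)
    model <- trainModel(train, cfg, spec, cache = cache)
    sc <- predictPairs(model, records(test), cfg,
                       store = sequenceStore(dataset), cache = cache)
    metricRow(sc, records(test)$label)
  })
  evaluationReport(as.data.frame(do.call(rbind, rows)),
                   meta = list(k = k, seed = seed,
                               algorithm = spec@algorithm))
}

#' Repeated C2 holdout evaluation with imbalance sweep
#'
#' The full evaluation protocol: for each C2 repeat, training negatives are
#' drawn degree-balanced against the training positives, a model is fitted,
#' and the held-out positives are scored against randomly sampled test
#' negatives at each requested negatives-per-positive ratio. Ratios are
#' evaluated on nested draws (the smaller sets are subsets of the largest),
#' so differences across ratios reflect the imbalance itself rather than
#' sampling noise. The C2 property is re-asserted on every repeat; leakage
#' is a hard error.
#'
#' @param positives An \linkS4class{InteractionDataset} of positive pairs.
#' @param cfg A \linkS4class{PaacConfig}.
#' @param clsSpec A \linkS4class{ClassifierSpec}.
#' @param spec A \linkS4class{SplitSpec} (nRepeats, testFraction, seed).
#' @param negativeRatios Negatives-per-positive ratios to score (default
#'   \code{c(1, 10, 100)}).
#' @param testIdps,testPartnerPool Optional candidate pools for test
#'   negatives; defaults are all IDPs of the dataset and every non-IDP
#'   sequence of the store absent from the training pairs (test-side
#'   partners included), i.e. proteins completely new to the model.
#' @param cache Optional per-sequence encoding matrix.
#' @return Named list of \linkS4class{EvaluationReport}s, one per ratio
#'   (names \code{"1N"}, \code{"10N"}, ...), each with one row per repeat.
#' @export
evaluateHoldout <- function(positives, cfg = paacConfig(),
                            clsSpec = classifierSpec(),
                            spec = splitSpec(), negativeRatios = c(1, 10, 100),
                            testIdps = NULL, testPartnerPool = NULL,
                            cache = NULL) {
  negativeRatios <- sort(negativeRatios)
  recs <- records(positives)
  if (any(recs$label != "positive"))
    userError("evaluateHoldout expects a positives-only dataset; negatives are sampled internally")
  if (is.null(cache))  # whole store: test negatives may use unseen proteins
    cache <- encodeStore(sequenceStore(positives), cfg)
  splits <- splitC2(positives, spec)
  allPositiveKeys <- paste(recs$idpId, recs$partnerId)
  rows <- lapply(splits, function(s) {
    checkC2(s$train, s$test)
    seed <- s$report$seed
    trainNeg <- sampleNegatives(s$train, ratio = 1, mode = "balanced",
                                knownPositives = allPositiveKeys,
                                seed = seed + 1000L)
    trainSet <- bindRecords(s$train, trainNeg)
    checkC2(trainSet, s$test)
    model <- trainModel(trainSet, cfg, clsSpec, cache = cache)
    testPos <- records(s$test)
    idpsPool <- if (is.null(testIdps)) idpIds(positives) else testIdps
    partnerPool <- if (is.null(testPartnerPool)) {
      trainProteins <- unique(c(records(trainSet)$idpId,
                                records(trainSet)$partnerId))
      setdiff(names(sequenceStore(positives)),
              union(trainProteins, idpIds(positives)))
    } else testPartnerPool
    maxRatio <- max(negativeRatios)
    testNeg <- sampleNegatives(s$test, ratio = maxRatio, mode = "random",
                               knownPositives = allPositiveKeys,
                               seed = seed + 2000L,
                               candidateIdps = idpsPool,
                               candidatePartners = partnerPool)
    negRecs <- records(testNeg)
    posScores <- predictPairs(model, testPos, cfg,
                              store = sequenceStore(positives), cache = cache)
    negScores <- predictPairs(model, negRecs, cfg,
                              store = sequenceStore(positives), cache = cache)
    nPos <- nrow(testPos)
    perRatio <- lapply(negativeRatios, function(ratio) {
      nNeg <- as.integer(round(ratio * nPos))
      sc <- c(posScores, negScores[seq_len(nNeg)])
      yy <- c(rep(1L, nPos), rep(0L, nNeg))
      metricRow(sc, yy)
    })
    names(perRatio) <- sprintf("%gN", negativeRatios)
    perRatio
  })
  reports <- lapply(sprintf("%gN", negativeRatios), function(nm) {
    evaluationReport(as.data.frame(do.call(rbind, lapply(rows, `[[`, nm))),
                     meta = list(ratio = nm, nRepeats = spec@nRepeats,
                                 seed = spec@seed,
                                 algorithm = clsSpec@algorithm))
  })
  setNames(reports, sprintf("%gN", negativeRatios))
}

#' Write an evaluation report
#'
#' Tab-delimited per-repeat table plus a JSON summary with the aggregate
#' mean/sd and the meta fields.
#'
#' @param report An \linkS4class{EvaluationReport}.
#' @param prefix Output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return Invisibly, the JSON path.
#' @export
writeReport <- function(report, prefix) {
  write.table(perRepeat(report), paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(list(aggregate = aggregated(report),
                            meta = report@meta),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-pair scores
#'
#' @param recs Record \code{data.frame} (idpId, partnerId, label).
#' @param scores Numeric scores aligned with \code{recs}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeScores <- function(recs, scores, path) {
  out <- data.frame(idp_id = recs$idpId, partner_id = recs$partnerId,
                    label = as.integer(recs$label == "positive"),
                    score = scores)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
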