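# S4 class definitions. Validity methods enforce the structural contracts
# that the rest of the package relies on; constructors live next to the
# methods for each class.

#' PropensityScale: a per-residue property scale
#'
#' A named mapping of the 20 standard residues to numeric values, such as the
#' TOP-IDP disorder propensity or per-residue net charge. Scales are
#' standardized (zero mean, unit population variance over the 20 residues)
#' before entering the PAAC correlation function.
#'
#' @slot name Scale identifier.
#' @slot values Named numeric vector, one value per standard residue.
#' @slot standardized Logical; \code{TRUE} once the values have zero mean and
#'   unit population standard deviation over the 20 residues.
#' @export
setClass("PropensityScale",
  representation(name = "character", values = "numeric",
                 standardized = "logical"))

setValidity("PropensityScale", function(object) {
  v <- object@values
  if (length(v) != 20L)
    return("a propensity scale must have exactly 20 entries")
  if (!setequal(names(v), .AA20))
    return("scale entries must be named by the 20 standard one-letter codes")
  if (anyNA(v) || any(!is.finite(v)))
    return("scale values must be finite")
  if (isTRUE(object@standardized)) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (abs(m) > 1e-9 || abs(s - 1) > 1e-9)
      return("standardized scale must have mean 0 and population sd 1")
  }
  TRUE
})

#' PaacConfig: configuration of the pseudo amino acid composition encoder
#'
#' @slot lambda Number of sequence-order correlation tiers (tier j correlates
#'   residues j positions apart); the minimum encodable sequence length is
#'   \code{lambda + 1}.
#' @slot weight Non-negative weight factor balancing the correlation tiers
#'   against the residue frequencies in the normalization.
#' @slot scales List of \linkS4class{PropensityScale} objects; standardized on
#'   construction.
#' @slot nonstandard Policy for nonstandard residue letters (B, J, O, U, X,
#'   Z, ...): \code{"delete"} removes them with a warning, \code{"error"}
#'   refuses the sequence.
#' @slot maxDeletedFrac Deleting more than this fraction of a sequence under
#'   the \code{"delete"} policy is an error.
#' @export
setClass("PaacConfig",
  representation(lambda = "integer", weight = "numeric", scales = "list",
                 nonstandard = "character", maxDeletedFrac = "numeric"))

setValidity("PaacConfig", function(object) {
  if (length(object@lambda) != 1L || object@lambda < 1L)
    return("lambda must be a single integer >= 1")
  if (length(object@weight) != 1L || object@weight < 0)
    return("weight must be a single non-negative number")
  if (length(object@scales) == 0L)
    return("at least one propensity scale is required")
  if (!all(vapply(object@scales, is, logical(1), "PropensityScale")))
    return("scales must be PropensityScale objects")
  if (!object@nonstandard %in% c("delete", "error"))
    return("nonstandard policy must be 'delete' or 'error'")
  if (object@maxDeletedFrac < 0 || object@maxDeletedFrac > 1)
    return("maxDeletedFrac must be in [0, 1]")
  TRUE
})

#' InteractionDataset: labelled protein pairs plus their sequences
#'
#' Records are oriented pairs with a designated IDP side; the partner side of
#' a negative pair is never an IDP (negatives contain exactly one IDP
#' component by construction).
#'
#' @slot records \code{data.frame} with columns \code{idpId},
#'   \code{partnerId}, \code{label} ("positive"/"negative") and
#'   \code{confidence} (numeric, \code{NA} when absent).
#' @slot sequences \code{AAStringSet} holding every referenced sequence,
#'   named by protein id.
#' @slot idpIds Character vector of ids flagged as intrinsically disordered.
#' @export
setClass("InteractionDataset",
  representation(records = "data.frame", sequences = "AAStringSet",
                 idpIds = "character"))

setValidity("InteractionDataset", function(object) {
  r <- object@records
  need <- c("idpId", "partnerId", "label", "confidence")
  if (!all(need %in% names(r)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (!all(r$label %in% c("positive", "negative")))
      return("labels must be 'positive' or 'negative'")
    ids <- unique(c(r$idpId, r$partnerId))
    missing <- setdiff(ids, names(object@sequences))
    if (length(missing))
      return(sprintf("unresolved sequence ids: %s",
                     paste(head(missing, 5L), collapse = ", ")))
    if (!all(r$idpId %in% object@idpIds))
      return("every record's idpId must be a flagged IDP")
    neg <- r[r$label == "negative", , drop = FALSE]
    if (nrow(neg) && any(neg$partnerId %in% object@idpIds))
      return("negative pairs must contain exactly one IDP component")
    key <- paste(r$idpId, r$partnerId, sep = "\r")
    if (anyDuplicated(paste(key, r$label)))
      return("duplicate (idp, partner) pair within a label class")
    if (any(key[r$label == "positive"] %in% key[r$label == "negative"]))
      return("a pair appears as both positive and negative")
  }
  TRUE
})

#' SplitSpec: configuration of the component-disjoint split engine
#'
#' @slot nRepeats Number of independent holdout repetitions.
#' @slot mode Split mode; only \code{"component_disjoint_C2"} is defined:
#'   partner proteins are partitioned so every test pair's partner is absent
#'   from training, while the IDP side may be shared.
#' @slot negativeRatio Negatives per positive in sampled negative sets.
#' @slot testFraction Fraction of partner proteins assigned to the test side.
#' @slot seed Base RNG seed; repeat r uses \code{seed + r}.
#' @export
setClass("SplitSpec",
  representation(nRepeats = "integer", mode = "character",
                 negativeRatio = "numeric", testFraction = "numeric",
                 seed = "integer"))

setValidity("SplitSpec", function(object) {
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  if (object@mode != "component_disjoint_C2")
    return("mode must be 'component_disjoint_C2'")
  if (object@negativeRatio < 1) return("negativeRatio must be >= 1")
  if (object@testFraction <= 0 || object@testFraction >= 1)
    return("testFraction must be in (0, 1)")
  TRUE
})

#' ClassifierSpec: choice of learning algorithm and hyperparameter search
#'
#' @slot algorithm One of \code{"random_forest"}, \code{"gradient_boosting"},
#'   \code{"linear_model"}, \code{"svm"}.
#' @slot hyperparameters Named list overriding the documented defaults.
#' @slot search \code{"none"}, \code{"grid"} or \code{"random"}.
#' @slot searchSpace Named list of candidate values per hyperparameter.
#' @slot nIter Number of draws for random search.
#' @slot innerFolds Folds of the inner cross-validation that scores
#'   hyperparameter candidates by AUC.
#' @slot seed RNG seed for fitting and search.
#' @export
setClass("ClassifierSpec",
  representation(algorithm = "character", hyperparameters = "list",
                 search = "character", searchSpace = "list",
                 nIter = "integer", innerFolds = "integer", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
  algos <- c("random_forest", "gradient_boosting", "linear_model", "svm")
  if (!object@algorithm %in% algos)
    return(sprintf("algorithm must be one of %s", paste(algos, collapse = ", ")))
  if (!object@search %in% c("none", "grid", "random"))
    return("search must be 'none', 'grid' or 'random'")
  if (object@search != "none" && length(object@searchSpace) == 0L)
    return("a non-trivial search requires a non-empty searchSpace")
  if (object@innerFolds < 2L) return("innerFolds must be >= 2")
  TRUE
})

#' TrainedModel: a fitted classifier bound to its feature schema
#'
#' @slot algorithm Algorithm family of the fit.
#' @slot spec The \linkS4class{ClassifierSpec} used (with any searched
#'   hyperparameters resolved).
#' @slot fit Opaque fitted object of the backing library.
#' @slot featureSchema Character vector naming the 940 pair features seen at
#'   fit time; prediction refuses vectors with a different schema.
#' @slot fingerprint Training-data fingerprint (size, label counts, checksum,
#'   seed) recorded for reproducibility.
#' @export
setClass("TrainedModel",
  representation(algorithm = "character", spec = "ClassifierSpec",
                 fit = "ANY", featureSchema = "character",
                 fingerprint = "character"))

#' EvaluationReport: per-repeat metrics with mean/sd aggregation
#'
#' @slot perRepeat \code{data.frame}, one row per repeat/fold, one column per
#'   metric plus a \code{repeat.} index column.
#' @slot aggregate \code{data.frame} with columns \code{metric}, \code{mean},
#'   \code{sd}; always the exact arithmetic mean/sd of the per-repeat rows.
#' @slot meta List of provenance fields (seed, split sizes, ratio, ...).
#' @export
setClass("EvaluationReport",
  representation(perRepeat = "data.frame", aggregate = "data.frame",
                 meta = "list"))

setValidity("EvaluationReport", function(object) {
  pr <- object@perRepeat
  ag <- object@aggregate
  metrics <- setdiff(names(pr), "repeat.")
  if (!identical(sort(as.character(ag$metric)), sort(metrics)))
    return("aggregate rows must match per-repeat metric columns")
  for (m in metrics) {
    i <- match(m, ag$metric)
    mu <- mean(pr[[m]])
    s <- if (nrow(pr) > 1L) sd(pr[[m]]) else 0
    if (abs(ag$mean[i] - mu) > 1e-12 || abs(ag$sd[i] - s) > 1e-12)
      return(sprintf("aggregate row '%s' is not the mean/sd of the repeats", m))
  }
  TRUE
})

#' SyntheticConfig: parameters of the synthetic sequence/network generator
#'
#' @slot nIdps,nPartners Number of IDP-like and ordered-like proteins.
#' @slot idpLengthRange,partnerLengthRange Inclusive sequence-length ranges;
#'   minima must respect the PAAC minimum length (lambda + 1).
#' @slot disorderBias In [0, 1]; 0 makes IDP and partner residue
#'   distributions identical, larger values enrich IDP sequences for
#'   disorder-promoting residues (TOP-IDP ranking).
#' @slot hubExponent Power-law exponent shaping IDP hub weights (smaller =
#'   heavier tail).
#' @slot meanDegree Mean number of interactions per IDP.
#' @slot plantedRule \code{"none"} or \code{"charge_complementarity"}: edges
#'   preferentially connect positively charged IDPs to negatively charged
#'   partners, giving a sequence-level signal the classifier can recover.
#' @slot ruleStrength Log-linear strength of the planted rule.
#' @slot chargeAmp Amplitude of the per-sequence charge tilt (compositional
#'   heterogeneity present whether or not a rule is planted).
#' @slot seed RNG seed.
#' @export
setClass("SyntheticConfig",
  representation(nIdps = "integer", nPartners = "integer",
                 idpLengthRange = "integer", partnerLengthRange = "integer",
                 disorderBias = "numeric", hubExponent = "numeric",
                 meanDegree = "numeric", plantedRule = "character",
                 ruleStrength = "numeric", chargeAmp = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nIdps < 1L || object@nPartners < 2L)
    return("need at least 1 IDP and 2 partners")
  if (length(object@idpLengthRange) != 2L ||
      length(object@partnerLengthRange) != 2L)
    return("length ranges must have two elements")
  if (object@idpLengthRange[1] < 51L || object@partnerLengthRange[1] < 51L)
    return("minimum sequence length is 51 (PAAC lambda = 50 requires length >= lambda + 1)")
  if (any(diff(object@idpLengthRange) < 0) ||
      any(diff(object@partnerLengthRange) < 0))
    return("length ranges must be increasing")
  if (object@disorderBias < 0 || object@disorderBias > 1)
    return("disorderBias must be in [0, 1]")
  if (object@hubExponent <= 1) return("hubExponent must be > 1")
  if (object@meanDegree <= 0) return("meanDegree must be positive")
  if (!object@plantedRule %in% c("none", "charge_complementarity"))
    return("plantedRule must be 'none' or 'charge_complementarity'")
  if (object@meanDegree > object@nPartners)
    return("meanDegree cannot exceed the number of partners")
  TRUE
})
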