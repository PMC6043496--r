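# Negative sampling and component-disjoint splitting. These two operations
# carry the study design: degree-balanced negatives keep hub proteins from
# dominating learning, and C2 splits guarantee every test partner is unseen
# at training time.

#' Split specification
#'
#' @param nRepeats Number of holdout repetitions (default 5).
#' @param negativeRatio Negatives per positive when sampling test negatives.
#' @param testFraction Fraction of partner proteins assigned to the test
#'   side of each repeat (default 0.3).
#' @param seed Base RNG seed; repeat r uses \code{seed + r} so the repeats
#'   are distinct but reproducible.
#' @return A \linkS4class{SplitSpec}.
#' @export
splitSpec <- function(nRepeats = 5L, negativeRatio = 1, testFraction = 0.3,
                      seed = 1L) {
  new("SplitSpec", nRepeats = as.integer(nRepeats),
      mode = "component_disjoint_C2", negativeRatio = negativeRatio,
      testFraction = testFraction, seed = as.integer(seed))
}

pairKey <- function(idp, partner) paste(idp, partner, sep = "\r")

#' Sample negative (non-interacting) pairs
#'
#' Two sampling modes, matching their two uses:
#' \describe{
#'   \item{balanced (training)}{Degree-preserving: the IDP side of the
#'     negatives is the multiset of IDPs with their positive degrees, the
#'     partner side the multiset of partners with theirs; the two multisets
#'     are paired by random permutation, rejecting known positives and
#'     duplicates and re-pairing the leftovers, so every protein appears
#'     exactly as often among negatives as among positives. Requires
#'     \code{ratio = 1} (parity is only defined there).}
#'   \item{random (testing)}{Uniform sampling without replacement from all
#'     (IDP, partner) combinations with exactly one IDP component, excluding
#'     known positives, until \code{ratio * N} negatives are drawn.}
#' }
#'
#' @param positives An \linkS4class{InteractionDataset} whose positive
#'   records define degrees, candidate proteins and \code{N}.
#' @param ratio Negatives per positive.
#' @param mode \code{"balanced"} or \code{"random"}.
#' @param knownPositives Optional character vector of additional forbidden
#'   pairs, formatted \code{"idpId partnerId"}; the positives of
#'   \code{positives} are always excluded.
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @param candidateIdps,candidatePartners Candidate pools for random mode;
#'   default to the proteins of the positive records.
#' @param maxTries Bounded retries for the balanced re-pairing before the
#'   sampler declares the configuration infeasible.
#' @return An \linkS4class{InteractionDataset} holding only the sampled
#'   negative records (store and IDP flags shared with \code{positives}).
#' @export
sampleNegatives <- function(positives, ratio = 1,
                            mode = c("balanced", "random"),
                            knownPositives = NULL, seed = 1L,
                            candidateIdps = NULL, candidatePartners = NULL,
                            maxTries = NULL) {
  mode <- match.arg(mode)
  recs <- records(positives)
  pos <- recs[recs$label == "positive", , drop = FALSE]
  if (nrow(pos) == 0L) userError("no positive pairs to sample against")
  forbidden <- unique(c(pairKey(pos$idpId, pos$partnerId),
                        if (!is.null(knownPositives))
                          sub(" ", "\r", knownPositives, fixed = TRUE)))
  negs <- withr::with_seed(as.integer(seed), {
    if (mode == "balanced") {
      if (abs(ratio - 1) > 1e-12)
        configError("balanced sampling implies ratio = 1 (per-protein degree parity)")
      sampleBalanced(pos, forbidden, idpSet = idpIds(positives),
                     maxTries = if (is.null(maxTries)) 100L * nrow(pos)
                                else maxTries)
    } else {
      sampleRandomNegatives(pos, ratio, forbidden, idpSet = idpIds(positives),
                            candidateIdps = candidateIdps,
                            candidatePartners = candidatePartners)
    }
  })
  negs$label <- "negative"
  negs$confidence <- NA_real_
  initialize(positives, records = negs)
}

# Degree-multiset random pairing with rejection and bounded re-pairing.
# IDP-IDP candidates are rejected too: a negative must keep exactly one IDP
# component. Leftovers that random re-pairing cannot place (a hub partner
# whose remaining IDPs are all its interactors) are repaired by swapping
# with an already accepted pair when both resulting pairs are valid.
sampleBalanced <- function(pos, forbidden, idpSet, maxTries) {
  idpSide <- pos$idpId          # multiset with positive degrees
  partnerSide <- pos$partnerId
  n <- length(idpSide)
  accepted <- character(0)
  acceptedIdp <- character(0)
  acceptedPartner <- character(0)
  leftIdp <- idpSide
  leftPartner <- partnerSide
  tries <- 0L
  while (length(leftIdp) && tries < maxTries) {
    tries <- tries + length(leftIdp)
    perm <- sample.int(length(leftPartner))
    lp <- leftPartner[perm]
    cand <- pairKey(leftIdp, lp)
    ok <- !(cand %in% forbidden) & !(cand %in% accepted) &
      !duplicated(cand) & !(lp %in% idpSet)
    accepted <- c(accepted, cand[ok])
    acceptedIdp <- c(acceptedIdp, leftIdp[ok])
    acceptedPartner <- c(acceptedPartner, lp[ok])
    leftIdp <- leftIdp[!ok]
    leftPartner <- lp[!ok]
    if (length(leftIdp) && length(leftIdp) <= max(2L, n %/% 5L)) {
      # swap repair: place leftover (i, p) by exchanging partners with an
      # accepted pair (i2, p2) such that (i, p2) and (i2, p) are both valid
      placed <- logical(length(leftIdp))
      for (u in seq_along(leftIdp)) {
        i <- leftIdp[u]; p <- leftPartner[u]
        if (p %in% idpSet) next
        for (j in sample.int(length(acceptedIdp))) {
          k1 <- pairKey(i, acceptedPartner[j])
          k2 <- pairKey(acceptedIdp[j], p)
          if (k1 != k2 && !(k1 %in% forbidden) && !(k2 %in% forbidden) &&
              !(k1 %in% accepted) && !(k2 %in% accepted)) {
            accepted <- c(setdiff(accepted, pairKey(acceptedIdp[j],
                                                    acceptedPartner[j])),
                          k1, k2)
            freed <- acceptedPartner[j]
            acceptedPartner[j] <- p
            acceptedIdp <- c(acceptedIdp, i)
            acceptedPartner <- c(acceptedPartner, freed)
            placed[u] <- TRUE
            break
          }
        }
      }
      leftIdp <- leftIdp[!placed]
      leftPartner <- leftPartner[!placed]
    }
  }
  if (length(leftIdp))
    userError("balanced negative sampling infeasible: %d of %d pairs placed after %d tries (network too dense or degrees too concentrated)",
              n - length(leftIdp), n, tries)
  data.frame(idpId = acceptedIdp, partnerId = acceptedPartner,
             stringsAsFactors = FALSE)
}

sampleRandomNegatives <- function(pos, ratio, forbidden, idpSet,
                                  candidateIdps = NULL,
                                  candidatePartners = NULL) {
  idps <- if (is.null(candidateIdps)) unique(pos$idpId) else candidateIdps
  partners <- if (is.null(candidatePartners)) unique(pos$partnerId)
              else candidatePartners
  partners <- setdiff(partners, idpSet)
  need <- as.integer(round(ratio * nrow(pos)))
  grid <- expand.grid(idpId = idps, partnerId = partners,
                      stringsAsFactors = FALSE)
  grid <- grid[!(pairKey(grid$idpId, grid$partnerId) %in% forbidden), ,
               drop = FALSE]
  if (nrow(grid) < need)
    userError("random negative sampling infeasible: need %d pairs but only %d non-positive combinations exist",
              need, nrow(grid))
  grid[sample.int(nrow(grid), need), , drop = FALSE]
}

#' Component-disjoint (C2) train/test splits
#'
#' For each repeat, partner proteins are partitioned into a train side and a
#' test side; a record goes to the test set iff its partner is a test
#' partner. Every test pair's partner therefore appears in no training pair
#' (on either side), while the IDP component may be shared - the C2
#' evaluation design for proteome-scale prediction on unseen partners. The
#' verified property is part of each split's report, and
#' \code{\link{checkC2}} re-asserts it as a hard error.
#'
#' @param dataset An \linkS4class{InteractionDataset} (positives only or
#'   already containing negatives).
#' @param spec A \linkS4class{SplitSpec}.
#' @return List of length \code{nRepeats}; each element has \code{train} and
#'   \code{test} (\linkS4class{InteractionDataset}s) and \code{report} (test
#'   partner count, pair counts, verified C2 flag, seed used).
#' @export
splitC2 <- function(dataset, spec = splitSpec()) {
  stopifnot(is(spec, "SplitSpec"))
  recs <- records(dataset)
  if (nrow(recs) == 0L) userError("cannot split an empty dataset")
  partners <- unique(recs$partnerId)
  if (length(partners) < 2L)
    userError("C2 split degenerate: only %d distinct partner protein(s)",
              length(partners))
  lapply(seq_len(spec@nRepeats), function(r) {
    seed <- spec@seed + r
    testPartners <- withr::with_seed(seed, {
      nTest <- max(1L, round(spec@testFraction * length(partners)))
      sample(partners, nTest)
    })
    inTest <- recs$partnerId %in% testPartners
    train <- subsetRecords(dataset, !inTest)
    test <- subsetRecords(dataset, inTest)
    if (nPairs(test) == 0L)
      userError("C2 split repeat %d produced an empty test set", r)
    if (nPairs(train) == 0L)
      userError("C2 split repeat %d produced an empty training set", r)
    checkC2(train, test)
    list(train = train, test = test,
         report = list(repeat. = r, seed = seed,
                       nTestPartners = length(testPartners),
                       nTrain = nPairs(train), nTest = nPairs(test),
                       c2Verified = TRUE))
  })
}

#' Assert the C2 zero-leakage property
#'
#' Errors (it does not warn) if any unordered pair occurs in both train and
#' test, or if any test partner occurs anywhere in the training records (as
#' partner or as IDP).
#'
#' @param train,test \linkS4class{InteractionDataset}s (or record
#'   \code{data.frame}s).
#' @return Invisibly \code{TRUE} when the property holds.
#' @export
checkC2 <- function(train, test) {
  tr <- if (is(train, "InteractionDataset")) records(train) else train
  te <- if (is(test, "InteractionDataset")) records(test) else test
  shared <- intersect(pairKey(tr$idpId, tr$partnerId),
                      pairKey(te$idpId, te$partnerId))
  if (length(shared))
    userError("leakage: %d pair(s) occur in both train and test", length(shared))
  trainProteins <- unique(c(tr$idpId, tr$partnerId))
  leaked <- intersect(unique(te$partnerId), trainProteins)
  if (length(leaked))
    userError("leakage: test partner(s) present in training pairs: %s",
              paste(head(leaked, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Check per-protein degree parity between positives and negatives
#'
#' @param dataset An \linkS4class{InteractionDataset} containing both
#'   labels.
#' @return Invisibly \code{TRUE}; errors listing offending proteins if any
#'   protein's negative appearance count differs from its positive count.
#' @export
checkDegreeBalance <- function(dataset) {
  recs <- records(dataset)
  degs <- function(rows) table(c(rows$idpId, rows$partnerId))
  p <- degs(recs[recs$label == "positive", , drop = FALSE])
  n <- degs(recs[recs$label == "negative", , drop = FALSE])
  all <- union(names(p), names(n))
  pd <- as.integer(p[all]); pd[is.na(pd)] <- 0L
  nd <- as.integer(n[all]); nd[is.na(nd)] <- 0L
  bad <- all[pd != nd]
  if (length(bad))
    userError("degree parity violated for %d protein(s): %s", length(bad),
              paste(head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Write split manifests
#'
#' One tab-separated manifest per repeat (record lists with a train/test
#' column) plus a JSON summary of counts, seeds and the verified C2 flags.
#'
#' @param splits Result of \code{\link{splitC2}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the summary file path.
#' @export
writeSplits <- function(splits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    tab <- rbind(cbind(records(s$train), set = "train"),
                 cbind(records(s$test), set = "test"))
    write.table(tab, file.path(dir, sprintf("split_%02d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- lapply(splits, `[[`, "report")
  path <- file.path(dir, "splits.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
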