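# Feature encoders: dipeptide composition, pseudo amino acid composition
# (PAAC), and their concatenation into per-protein (470) and per-pair (940)
# vectors. Feature order is fixed and documented by the schema functions so
# exported vectors are stable across runs.

.DIPEPTIDES <- as.vector(outer(.AA20, .AA20,
                               function(a, b) paste0(a, b)))[order(
  as.vector(outer(.AA20, .AA20, function(a, b) paste0(a, b))))]

#' PAAC configuration
#'
#' @param lambda Number of sequence-order correlation tiers; the default 50
#'   fixes the minimum encodable sequence length at 51 and, with the 20
#'   residue frequencies, gives 70 PAAC components.
#' @param weight PAAC weight factor balancing correlation tiers against
#'   residue counts in the shared normalization; default 0.05, the standard
#'   PAAC convention.
#' @param scales List of \linkS4class{PropensityScale}; standardized here if
#'   they are not already. Default: the five packaged scales.
#' @param nonstandard Policy for nonstandard residue letters.
#' @param maxDeletedFrac Maximum tolerated deleted fraction under the
#'   \code{"delete"} policy.
#' @return A \linkS4class{PaacConfig}.
#' @export
#' @examples
#' cfg <- paacConfig()
#' length(featureSchema(cfg))  # 470
paacConfig <- function(lambda = 50L, weight = 0.05, scales = defaultScales(),
                       nonstandard = c("delete", "error"),
                       maxDeletedFrac = 0.05) {
  nonstandard <- match.arg(nonstandard)
  scales <- lapply(scales, function(s) {
    if (!is(s, "PropensityScale"))
      configError("scales must be PropensityScale objects")
    if (isStandardized(s)) s else standardizeScale(s)
  })
  new("PaacConfig", lambda = as.integer(lambda), weight = as.numeric(weight),
      scales = unname(scales), nonstandard = nonstandard,
      maxDeletedFrac = maxDeletedFrac)
}

# 20 x 20 correlation matrix: Theta[a, b] = mean over scales of the squared
# difference of the standardized scale values of residues a and b.
thetaMatrix <- function(scales) {
  mats <- lapply(scales, function(s) {
    v <- scaleValues(s)
    outer(v, v, function(x, y) (y - x)^2)
  })
  Reduce(`+`, mats) / length(mats)
}

#' Dipeptide composition of a protein sequence
#'
#' Counts every ordered pair of consecutive residues and normalizes by the
#' number of dipeptides (L - 1), giving a 400-component vector over all
#' ordered residue pairs in fixed lexicographic order (first residue, then
#' second). Components sum to 1.
#'
#' @param seq Character string, \code{AAString} or 1-element
#'   \code{AAStringSet}.
#' @param id Sequence id used in error messages.
#' @param nonstandard,maxDeletedFrac Nonstandard-letter policy.
#' @return Named numeric vector of length 400.
#' @export
#' @examples
#' v <- dipeptideComposition("ACAC")
#' v[c("AC", "CA")]  # 2/3, 1/3
dipeptideComposition <- function(seq, id = NULL, nonstandard = "delete",
                                 maxDeletedFrac = 0.05) {
  res <- asResidues(seq, id = id, policy = nonstandard,
                    maxFrac = maxDeletedFrac)
  if (is.null(id)) id <- "<sequence>"
  L <- nchar(res)
  if (L < 2L)
    userError("sequence '%s': dipeptide composition needs >= 2 valid residues (has %d)",
              id, L)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  dp <- paste0(chars[-L], chars[-1L])
  counts <- table(factor(dp, levels = .DIPEPTIDES))
  out <- as.numeric(counts) / (L - 1L)
  names(out) <- .DIPEPTIDES
  out
}

#' Pseudo amino acid composition (PAAC) of a protein sequence
#'
#' Type-I PAAC with a single correlation function averaged over the
#' configured propensity scales: each scale is standardized over the 20
#' residues; the pair correlation of residues a and b is the mean squared
#' difference of their standardized scale values; tier j averages that
#' correlation over all residue pairs j positions apart (j = 1..lambda); and
#' the final vector normalizes the 20 raw residue counts f and the weighted
#' tiers w*theta by their common sum, so all 20 + lambda components sum to 1.
#'
#' @inheritParams dipeptideComposition
#' @param cfg A \linkS4class{PaacConfig}.
#' @return Named numeric vector of length \code{20 + lambda} (70 under the
#'   default configuration).
#' @export
#' @examples
#' v <- paacComposition(strrep("A", 51), paacConfig())
#' v[["A"]]  # 1: a homopolymer has zero correlation at every tier
paacComposition <- function(seq, cfg = paacConfig(), id = NULL) {
  stopifnot(is(cfg, "PaacConfig"))
  res <- asResidues(seq, id = id, policy = cfg@nonstandard,
                    maxFrac = cfg@maxDeletedFrac)
  if (is.null(id)) id <- "<sequence>"
  L <- nchar(res)
  lam <- cfg@lambda
  if (L < lam + 1L)
    userError("sequence '%s': PAAC with lambda = %d needs length >= %d (has %d)",
              id, lam, lam + 1L, L)
  idx <- match(strsplit(res, "", fixed = TRUE)[[1]], .AA20)
  Theta <- thetaMatrix(cfg@scales)
  theta <- vapply(seq_len(lam), function(j)
    mean(Theta[cbind(idx[seq_len(L - j)], idx[seq_len(L - j) + j])]),
    numeric(1))
  f <- tabulate(idx, nbins = 20L)
  denom <- sum(f) + cfg@weight * sum(theta)
  out <- c(f, cfg@weight * theta) / denom
  names(out) <- c(.AA20, paste0("theta", seq_len(lam)))
  out
}

#' Feature schema of the single-sequence encoding
#'
#' @param cfg A \linkS4class{PaacConfig}.
#' @return Character vector naming, in order, the 20 residue-frequency
#'   components, the lambda correlation tiers, and the 400 dipeptides
#'   (470 names under the defaults).
#' @export
featureSchema <- function(cfg = paacConfig()) {
  c(paste0("paac.", c(.AA20, paste0("theta", seq_len(cfg@lambda)))),
    paste0("dpc.", .DIPEPTIDES))
}

#' Feature schema of the pair encoding
#'
#' @param cfg A \linkS4class{PaacConfig}.
#' @return Character vector of length \code{2 * (20 + lambda + 400)} (940
#'   under the defaults); the IDP occupies the first half, the partner the
#'   second.
#' @export
pairSchema <- function(cfg = paacConfig()) {
  s <- featureSchema(cfg)
  c(paste0("idp.", s), paste0("partner.", s))
}

#' Encode one protein sequence
#'
#' Concatenation of the PAAC vector (20 + lambda components) and the
#' dipeptide composition (400 components); 470 features under the default
#' configuration.
#'
#' @inheritParams paacComposition
#' @return Named numeric vector following \code{\link{featureSchema}}.
#' @export
encodeSequence <- function(seq, cfg = paacConfig(), id = NULL) {
  res <- asResidues(seq, id = id, policy = cfg@nonstandard,
                    maxFrac = cfg@maxDeletedFrac)
  v <- c(paacComposition(res, cfg, id = id),
         dipeptideComposition(res, id = id))
  names(v) <- featureSchema(cfg)
  v
}

#' Encode an ordered (IDP, partner) pair
#'
#' Concatenates the two per-protein encodings; the IDP always occupies the
#' first half so that models see a fixed orientation. Ids are recorded as
#' attributes.
#'
#' @param idp,partner Sequences (character, \code{AAString} or 1-element
#'   \code{AAStringSet}).
#' @param cfg A \linkS4class{PaacConfig}.
#' @param idpId,partnerId Ids recorded on the result and used in errors.
#' @return Named numeric vector of length 940 under the defaults, with
#'   attributes \code{idpId} and \code{partnerId}.
#' @export
encodePair <- function(idp, partner, cfg = paacConfig(),
                       idpId = NULL, partnerId = NULL) {
  v <- c(encodeSequence(idp, cfg, id = idpId),
         encodeSequence(partner, cfg, id = partnerId))
  names(v) <- pairSchema(cfg)
  attr(v, "idpId") <- if (is.null(idpId)) NA_character_ else idpId
  attr(v, "partnerId") <- if (is.null(partnerId)) NA_character_ else partnerId
  v
}

#' Encode every sequence of a store
#'
#' Encodes each sequence once; the resulting matrix serves as a cache when
#' many pairs share proteins (pair vectors are then plain row
#' concatenations).
#'
#' @param store An \code{AAStringSet} named by id.
#' @param cfg A \linkS4class{PaacConfig}.
#' @return Numeric matrix, one row per sequence (rownames = ids), columns
#'   following \code{\link{featureSchema}}.
#' @export
encodeStore <- function(store, cfg = paacConfig()) {
  stopifnot(is(store, "AAStringSet"))
  ids <- names(store)
  if (is.null(ids)) userError("sequence store must be named by protein id")
  mat <- t(vapply(seq_along(store),
                  function(i) encodeSequence(as.character(store[[i]]), cfg,
                                             id = ids[i]),
                  numeric(length(featureSchema(cfg)))))
  rownames(mat) <- ids
  mat
}

# Pair feature matrix for a record table, from a per-sequence cache.
pairFeatureMatrix <- function(recs, store, cfg = paacConfig(), cache = NULL) {
  if (is.null(cache)) {
    need <- unique(c(recs$idpId, recs$partnerId))
    cache <- encodeStore(store[need], cfg)
  }
  missing <- setdiff(unique(c(recs$idpId, recs$partnerId)), rownames(cache))
  if (length(missing))
    userError("no encoding for: %s", paste(head(missing, 5L), collapse = ", "))
  X <- cbind(cache[recs$idpId, , drop = FALSE],
             cache[recs$partnerId, , drop = FALSE])
  colnames(X) <- pairSchema(cfg)
  rownames(X) <- paste(recs$idpId, recs$partnerId, sep = "~")
  X
}

#' Write a feature table
#'
#' Tab-delimited export with a header row naming every feature and the id
#' column(s) first.
#'
#' @param mat Feature matrix with rownames (ids) and colnames (schema).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
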