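# Baseline encoders used by published sequence-only PPI predictors:
# physicochemical autocorrelation profiles and reduced-alphabet triad
# composition. Included so baseline methods can be benchmarked through the
# same pipeline as the main encoder.

# Conjoint-triad reduced alphabet (7 classes grouping residues by dipole and
# side-chain volume, Shen et al. 2007).
.TRIAD_CLASSES <- list(c("A", "G", "V"),
                       c("I", "L", "F", "P"),
                       c("Y", "M", "T", "S"),
                       c("H", "N", "Q", "W"),
                       c("R", "K"),
                       c("D", "E"),
                       c("C"))

.triadClassOf <- local({
  map <- integer(20)
  names(map) <- .AA20
  for (k in seq_along(.TRIAD_CLASSES)) map[.TRIAD_CLASSES[[k]]] <- k
  map
})

#' Autocorrelation features of physicochemical scales
#'
#' For each scale and each lag d = 1..maxLag, the average product of the
#' deviations (from the sequence mean of that scale) of residues d positions
#' apart. The classic 7-scale, lag-30 configuration gives a 210-component
#' vector per protein.
#'
#' @inheritParams dipeptideComposition
#' @param scales List of \linkS4class{PropensityScale} (standardization is
#'   irrelevant here: deviations are taken from the sequence mean).
#' @param maxLag Largest lag; the sequence must be longer than this.
#' @return Named numeric vector of length \code{length(scales) * maxLag}.
#' @export
autocorrelationFeatures <- function(seq, scales, maxLag = 30L, id = NULL,
                                    nonstandard = "delete",
                                    maxDeletedFrac = 0.05) {
  res <- asResidues(seq, id = id, policy = nonstandard,
                    maxFrac = maxDeletedFrac)
  if (is.null(id)) id <- "<sequence>"
  L <- nchar(res)
  if (L <= maxLag)
    userError("sequence '%s': autocorrelation with maxLag = %d needs length > %d (has %d)",
              id, maxLag, maxLag, L)
  idx <- match(strsplit(res, "", fixed = TRUE)[[1]], .AA20)
  out <- numeric(0)
  nms <- character(0)
  for (s in scales) {
    v <- scaleValues(s)[idx]
    dev <- v - mean(v)
    ac <- vapply(seq_len(maxLag), function(d)
      sum(dev[seq_len(L - d)] * dev[seq_len(L - d) + d]) / (L - d),
      numeric(1))
    out <- c(out, ac)
    nms <- c(nms, paste0(scaleName(s), ".lag", seq_len(maxLag)))
  }
  setNames(out, nms)
}

#' Conjoint-triad composition
#'
#' Residues are mapped to a 7-class reduced alphabet (grouping by dipole and
#' side-chain volume); the normalized frequencies of all 343 ordered class
#' triads form the feature vector.
#'
#' @inheritParams dipeptideComposition
#' @return Named numeric vector of length 343 summing to 1.
#' @export
conjointTriadFeatures <- function(seq, id = NULL, nonstandard = "delete",
                                  maxDeletedFrac = 0.05) {
  res <- asResidues(seq, id = id, policy = nonstandard,
                    maxFrac = maxDeletedFrac)
  if (is.null(id)) id <- "<sequence>"
  L <- nchar(res)
  if (L < 3L)
    userError("sequence '%s': triad composition needs >= 3 valid residues (has %d)",
              id, L)
  cls <- .triadClassOf[strsplit(res, "", fixed = TRUE)[[1]]]
  tri <- (cls[seq_len(L - 2L)] - 1L) * 49L +
         (cls[seq_len(L - 2L) + 1L] - 1L) * 7L +
          cls[seq_len(L - 2L) + 2L]
  counts <- tabulate(tri, nbins = 343L)
  nms <- paste0("t", rep(1:7, each = 49L),
                rep(rep(1:7, each = 7L), times = 7L),
                rep(1:7, times = 49L))
  setNames(counts / sum(counts), nms)
}

#' Raw tripeptide composition
#'
#' Normalized frequencies of all 8000 ordered residue triplets; the
#' unreduced alternative to \code{\link{conjointTriadFeatures}}.
#'
#' @inheritParams dipeptideComposition
#' @return Named numeric vector of length 8000 summing to 1.
#' @export
tripeptideComposition <- function(seq, id = NULL, nonstandard = "delete",
                                  maxDeletedFrac = 0.05) {
  res <- asResidues(seq, id = id, policy = nonstandard,
                    maxFrac = maxDeletedFrac)
  if (is.null(id)) id <- "<sequence>"
  L <- nchar(res)
  if (L < 3L)
    userError("sequence '%s': tripeptide composition needs >= 3 valid residues (has %d)",
              id, L)
  idx <- match(strsplit(res, "", fixed = TRUE)[[1]], .AA20)
  tri <- (idx[seq_len(L - 2L)] - 1L) * 400L +
         (idx[seq_len(L - 2L) + 1L] - 1L) * 20L +
          idx[seq_len(L - 2L) + 2L]
  counts <- tabulate(tri, nbins = 8000L)
  nms <- paste0(rep(.AA20, each = 400L),
                rep(rep(.AA20, each = 20L), times = 20L),
                rep(.AA20, times = 400L))
  setNames(counts / sum(counts), nms)
}
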