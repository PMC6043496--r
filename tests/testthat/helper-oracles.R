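# Brute-force reference implementations, written independently of the
# package internals (explicit loops, no shared helpers), plus small fixture
# builders. Expected values in the tests come from these.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomSeq <- function(len, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA, len, replace = TRUE, prob = freqs), collapse = "")
}

# Naive Type-I PAAC: loops only. rawScales is a list of named numeric
# vectors (unstandardized).
paacOracle <- function(res, rawScales, lambda, w) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  std <- lapply(rawScales, function(v) {
    m <- sum(v) / 20
    s <- sqrt(sum((v - m)^2) / 20)
    (v - m) / s
  })
  corr <- function(a, b) {
    tot <- 0
    for (sv in std) tot <- tot + (sv[[b]] - sv[[a]])^2
    tot / length(std)
  }
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - j)) acc <- acc + corr(chars[i], chars[i + j])
    theta[j] <- acc / (L - j)
  }
  f <- numeric(20)
  names(f) <- AA
  for (ch in chars) f[ch] <- f[ch] + 1
  denom <- sum(f) + w * sum(theta)
  unname(c(f, w * theta) / denom)
}

# Naive autocorrelation profile: double loop per scale and lag.
acOracle <- function(res, rawScales, maxLag) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (sv in rawScales) {
    vals <- numeric(L)
    for (i in seq_len(L)) vals[i] <- sv[[chars[i]]]
    m <- sum(vals) / L
    for (d in seq_len(maxLag)) {
      acc <- 0
      for (i in seq_len(L - d)) acc <- acc + (vals[i] - m) * (vals[i + d] - m)
      out <- c(out, acc / (L - d))
    }
  }
  out
}

# AUC as explicit concordance count over all (positive, negative) pairs,
# ties counted one half.
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (n in neg)
    acc <- acc + if (p > n) 1 else if (p == n) 0.5 else 0
  acc / (length(pos) * length(neg))
}

# Average precision by walking the unique thresholds in descending order
# and recomputing the confusion table from scratch at each.
apOracle <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prevRec <- 0
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / P
    ap <- ap + (rec - prevRec) * prec
    prevRec <- rec
  }
  ap
}

mccOracle <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

rawDefaultScales <- function() {
  lapply(defaultScales(standardize = FALSE), scaleValues)
}

# A small labelled dataset with a hand-built store; all sequences long
# enough for the default encoder.
toyDataset <- function(nIdps = 3, nPartners = 6, degrees = c(2, 1, 1),
                       seed = 42) {
  withr::with_seed(seed, {
    ids <- c(sprintf("idp%d", seq_len(nIdps)),
             sprintf("prt%d", seq_len(nPartners)))
    store <- Biostrings::AAStringSet(vapply(ids, function(i) randomSeq(60),
                                            character(1)))
    names(store) <- ids
    idps <- ids[seq_len(nIdps)]
    partners <- ids[-seq_len(nIdps)]
    # round-robin partner assignment keeps degree-balanced negative
    # sampling feasible by construction
    offset <- 0L
    recs <- do.call(rbind, lapply(seq_len(nIdps), function(i) {
      sel <- partners[(offset + seq_len(degrees[i]) - 1L) %%
                        length(partners) + 1L]
      offset <<- offset + degrees[i]
      data.frame(idpId = idps[i], partnerId = sel,
                 label = "positive", stringsAsFactors = FALSE)
    }))
    interactionDataset(recs, store, idpIds = idps)
  })
}
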