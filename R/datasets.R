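# Dataset construction: the InteractionDataset container, pair-list I/O,
# the length/name filters, and 40% identity redundancy reduction.

#' Construct an interaction dataset
#'
#' @param records \code{data.frame} with columns \code{idpId},
#'   \code{partnerId}, \code{label} (accepts "positive"/"negative" or 1/0)
#'   and optionally \code{confidence}.
#' @param sequences \code{AAStringSet} named by protein id.
#' @param idpIds Ids flagged as intrinsically disordered.
#' @param dedupe Drop duplicated (idp, partner, label) records with a
#'   warning instead of failing validity.
#' @return An \linkS4class{InteractionDataset}.
#' @export
interactionDataset <- function(records, sequences, idpIds, dedupe = FALSE) {
  stopifnot(is.data.frame(records))
  if (!all(c("idpId", "partnerId", "label") %in% names(records)))
    userError("records need columns idpId, partnerId, label")
  label <- records$label
  if (is.numeric(label)) label <- ifelse(label > 0, "positive", "negative")
  recs <- data.frame(idpId = as.character(records$idpId),
                     partnerId = as.character(records$partnerId),
                     label = as.character(label),
                     confidence = if ("confidence" %in% names(records))
                       as.numeric(records$confidence) else NA_real_,
                     stringsAsFactors = FALSE)
  if (dedupe) {
    key <- paste(recs$idpId, recs$partnerId, recs$label)
    if (anyDuplicated(key)) {
      warning(sprintf("dropping %d duplicated record(s)", sum(duplicated(key))),
              call. = FALSE)
      recs <- recs[!duplicated(key), , drop = FALSE]
    }
  }
  rownames(recs) <- NULL
  new("InteractionDataset", records = recs, sequences = sequences,
      idpIds = as.character(idpIds))
}

#' @describeIn InteractionDataset-class The record table.
#' @export
setMethod("records", "InteractionDataset", function(x) x@records)

#' @describeIn InteractionDataset-class The sequence store.
#' @export
setMethod("sequenceStore", "InteractionDataset", function(x) x@sequences)

#' @describeIn InteractionDataset-class Ids flagged as IDPs.
#' @export
setMethod("idpIds", "InteractionDataset", function(x) x@idpIds)

#' @describeIn InteractionDataset-class Number of pair records.
#' @export
setMethod("nPairs", "InteractionDataset", function(x) nrow(x@records))

setMethod("show", "InteractionDataset", function(object) {
  r <- object@records
  cat(sprintf("InteractionDataset: %d pairs (%d positive, %d negative)\n",
              nrow(r), sum(r$label == "positive"), sum(r$label == "negative")))
  cat(sprintf("  %d sequences (%d IDPs), %d distinct partners\n",
              length(object@sequences), length(object@idpIds),
              length(unique(r$partnerId))))
})

#' Keep a subset of records
#'
#' Returns a dataset restricted to the given record rows; the sequence store
#' and IDP flags are shared unchanged.
#'
#' @param dataset An \linkS4class{InteractionDataset}.
#' @param which Row index (logical or integer) into \code{records(dataset)}.
#' @return An \linkS4class{InteractionDataset}.
#' @export
subsetRecords <- function(dataset, which) {
  recs <- dataset@records[which, , drop = FALSE]
  rownames(recs) <- NULL
  initialize(dataset, records = recs)
}

#' Merge the records of two datasets sharing a sequence store
#'
#' @param a,b \linkS4class{InteractionDataset}s with compatible stores.
#' @return An \linkS4class{InteractionDataset}.
#' @export
bindRecords <- function(a, b) {
  recs <- rbind(a@records, b@records)
  rownames(recs) <- NULL
  store <- a@sequences
  extra <- setdiff(names(b@sequences), names(store))
  if (length(extra)) store <- c(store, b@sequences[extra])
  new("InteractionDataset", records = recs, sequences = store,
      idpIds = union(a@idpIds, b@idpIds))
}

#' Read an interaction pair list
#'
#' Tab-separated text with a header row, columns \code{idp_id},
#' \code{partner_id}, optional \code{label} (0/1) and \code{confidence};
#' lines starting with \code{#} are comments. Without a label column all
#' pairs are taken as positives.
#'
#' @param path File path.
#' @return \code{data.frame} with columns \code{idpId}, \code{partnerId},
#'   \code{label}, \code{confidence}.
#' @export
readPairList <- function(path) {
  if (!file.exists(path)) userError("pair list not found: %s", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    userError("pair list %s needs at least two columns (idp_id, partner_id)",
              path)
  names(tab)[1:2] <- c("idpId", "partnerId")
  lab <- if ("label" %in% names(tab)) {
    ifelse(tab$label > 0, "positive", "negative")
  } else rep("positive", nrow(tab))
  data.frame(idpId = as.character(tab$idpId),
             partnerId = as.character(tab$partnerId),
             label = lab,
             confidence = if ("confidence" %in% names(tab))
               as.numeric(tab$confidence) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write an interaction pair list
#'
#' @param records Record \code{data.frame} (or an
#'   \linkS4class{InteractionDataset}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePairList <- function(records, path) {
  if (is(records, "InteractionDataset")) records <- records(records)
  out <- data.frame(idp_id = records$idpId, partner_id = records$partnerId,
                    label = as.integer(records$label == "positive"),
                    confidence = records$confidence)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter sequences by length and description words
#'
#' Removes sequences shorter than \code{minLength} residues and sequences
#' whose description contains any banned word (case-insensitive substring
#' match), the standard cleanup applied to interaction-partner lists before
#' training. Removal counts per rule are reported via \code{message()}.
#'
#' @param store \code{AAStringSet} with an optional \code{description}
#'   metadata column.
#' @param minLength Minimum retained length (a sequence of exactly
#'   \code{minLength} residues is kept).
#' @param bannedWords Words that disqualify a sequence by its description.
#' @param verbose Emit the removal log.
#' @return The filtered store (always a subset of the input).
#' @export
filterSequences <- function(store, minLength = 50L,
                            bannedWords = c("putative", "potential",
                                            "uncharacterized"),
                            verbose = TRUE) {
  stopifnot(is(store, "AAStringSet"))
  if (length(store) == 0L) userError("sequence store is empty")
  shortDrop <- width(store) < minLength
  desc <- mcols(store)$description
  if (is.null(desc)) desc <- rep("", length(store))
  desc <- tolower(desc)
  nameDrop <- rep(FALSE, length(store))
  for (w in bannedWords)
    nameDrop <- nameDrop | grepl(tolower(w), desc, fixed = TRUE)
  if (verbose)
    message(sprintf("filterSequences: removed %d short (< %d aa) and %d banned-word sequence(s); %d retained",
                    sum(shortDrop), minLength, sum(nameDrop & !shortDrop),
                    sum(!shortDrop & !nameDrop)))
  out <- store[!shortDrop & !nameDrop]
  if (length(out) == 0L)
    warning("all sequences were removed by the filters", call. = FALSE)
  out
}

# Global-alignment percent identity between two residue strings:
# matches / alignment length (gapped columns included), BLOSUM62,
# gapOpening 10, gapExtension 0.5.
pairIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(AAStringSet(a), AAStringSet(b),
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5,
                                       type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Greedy incremental clustering in the style of CD-HIT: sequences are
#' visited longest first (ties broken by id); a sequence joins the first
#' existing cluster whose representative it matches with pairwise identity
#' above the threshold, otherwise it founds a new cluster. Identity is
#' matches / alignment length from a global alignment (BLOSUM62, gap open
#' 10, gap extend 0.5). Only cluster representatives are returned.
#'
#' Full-scale datasets are better clustered with CD-HIT itself; pass its
#' \code{.clstr} output via \code{clstrFile} to use those clusters instead
#' of the internal alignment.
#'
#' @param store \code{AAStringSet} named by id.
#' @param identityThreshold Identity above which two sequences are
#'   redundant; in (0, 1].
#' @param clstrFile Optional CD-HIT \code{.clstr} file; when given, its
#'   representatives are used and no alignments are computed.
#' @return The reduced store (a subset of the input).
#' @export
reduceRedundancy <- function(store, identityThreshold = 0.40,
                             clstrFile = NULL) {
  stopifnot(is(store, "AAStringSet"))
  if (identityThreshold <= 0 || identityThreshold > 1)
    configError("identityThreshold must be in (0, 1]")
  if (!is.null(clstrFile)) {
    reps <- readClstr(clstrFile)$representatives
    keep <- intersect(names(store), reps)
    return(store[keep])
  }
  ord <- order(-width(store), names(store))
  reps <- character(0)
  seqs <- as.character(store)
  for (i in ord) {
    id <- names(store)[i]
    joined <- FALSE
    for (r in reps) {
      if (pairIdentity(seqs[[id]], seqs[[r]]) > identityThreshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, id)
  }
  store[intersect(names(store), reps)]
}

#' Read a CD-HIT cluster file
#'
#' Parses the \code{.clstr} dialect (cluster headers \code{>Cluster n};
#' member lines ending in \code{*} mark the representative).
#'
#' @param path Path to a \code{.clstr} file.
#' @return List with \code{clusters} (list of member id vectors) and
#'   \code{representatives} (character vector).
#' @export
readClstr <- function(path) {
  if (!file.exists(path)) userError("cluster file not found: %s", path)
  lines <- readLines(path)
  clusters <- list()
  reps <- character(0)
  current <- character(0)
  flush <- function() {
    if (length(current)) clusters[[length(clusters) + 1L]] <<- current
    current <<- character(0)
  }
  for (ln in lines) {
    if (grepl("^>", ln)) { flush(); next }
    if (!nzchar(trimws(ln))) next
    if (!grepl(">", ln, fixed = TRUE) || !grepl("...", ln, fixed = TRUE))
      userError("unparseable .clstr line: %s", ln)
    id <- sub("\\.\\.\\..*$", "", sub("^[^>]*>\\s*", "", ln))
    current <- c(current, id)
    if (grepl("\\*\\s*$", ln)) reps <- c(reps, id)
  }
  flush()
  if (length(reps) != length(clusters))
    userError("cluster file %s: %d clusters but %d representatives",
              path, length(clusters), length(reps))
  list(clusters = clusters, representatives = reps)
}

#' Drop records whose sequences are absent from a store
#'
#' Utility for re-synchronizing a pair table after sequence filtering;
#' reports how many records were dropped.
#'
#' @param records Record \code{data.frame}.
#' @param store Filtered \code{AAStringSet}.
#' @param verbose Emit the removal count.
#' @return The restricted record \code{data.frame}.
#' @export
restrictRecords <- function(records, store, verbose = TRUE) {
  keep <- records$idpId %in% names(store) &
    records$partnerId %in% names(store)
  if (verbose && any(!keep))
    message(sprintf("restrictRecords: dropped %d record(s) with filtered sequences",
                    sum(!keep)))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
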