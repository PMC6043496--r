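# Sequence I/O and the nonstandard-residue policy.

#' Read a protein FASTA file
#'
#' Multi-record FASTA with wrapped lines; residues are upper-cased. The
#' record id is the first whitespace-delimited token of the header; the rest
#' of the header is kept as the description (used by the name-word filter).
#'
#' @param path FASTA file path.
#' @return An \code{AAStringSet} named by id, with a \code{description}
#'   metadata column.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) userError("FASTA file not found: %s", path)
  set <- tryCatch(readAAStringSet(path),
                  error = function(e) userError("malformed FASTA %s: %s",
                                                path, conditionMessage(e)))
  if (length(set) == 0L) userError("FASTA file %s contains no records", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    userError("duplicate sequence ids in %s: %s", path,
              paste(head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  desc <- sub("^\\S+\\s*", "", headers)
  set <- AAStringSet(toupper(as.character(set)))
  names(set) <- ids
  mcols(set)$description <- desc
  set
}

#' Write a protein FASTA file
#'
#' @param store An \code{AAStringSet}; a \code{description} metadata column,
#'   if present, is appended to the headers.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeProteinFasta <- function(store, path) {
  out <- store
  desc <- mcols(store)$description
  if (!is.null(desc)) {
    has <- !is.na(desc) & nzchar(desc)
    names(out)[has] <- paste(names(store)[has], desc[has])
  }
  writeXStringSet(out, path)
  invisible(path)
}

# Apply the nonstandard-letter policy to one residue string. Returns the
# cleaned string; warns with counts under "delete", errors under "error" or
# when more than maxFrac of the sequence would be deleted.
cleanResidues <- function(residues, id = "<sequence>",
                          policy = c("delete", "error"),
                          maxFrac = 0.05) {
  policy <- match.arg(policy)
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L)
    userError("sequence '%s' is empty", id)
  bad <- !(chars %in% .AA20)
  if (!any(bad)) return(residues)
  if (policy == "error")
    userError("sequence '%s' contains %d nonstandard letter(s): %s", id,
              sum(bad), paste(unique(chars[bad]), collapse = ""))
  frac <- sum(bad) / length(chars)
  if (frac > maxFrac)
    userError(
      "sequence '%s': %.1f%% nonstandard letters exceeds the %.0f%% limit",
      id, 100 * frac, 100 * maxFrac)
  warning(sprintf("sequence '%s': deleted %d nonstandard letter(s) (%s)",
                  id, sum(bad), paste(unique(chars[bad]), collapse = "")),
          call. = FALSE)
  kept <- paste(chars[!bad], collapse = "")
  if (!nzchar(kept))
    userError("sequence '%s' has no standard residues", id)
  kept
}

# Coerce the various sequence representations (character scalar, AAString,
# 1-element AAStringSet) to a cleaned residue string.
asResidues <- function(seq, id = NULL, policy = "delete", maxFrac = 0.05) {
  if (is(seq, "AAStringSet")) {
    if (length(seq) != 1L)
      userError("expected a single sequence, got %d", length(seq))
    if (is.null(id) && !is.null(names(seq))) id <- names(seq)
    seq <- as.character(seq[[1L]])
  } else if (is(seq, "AAString")) {
    seq <- as.character(seq)
  } else if (!is.character(seq) || length(seq) != 1L) {
    userError("sequence must be a character string, AAString or AAStringSet")
  }
  if (is.null(id)) id <- "<sequence>"
  cleanResidues(seq, id = id, policy = policy, maxFrac = maxFrac)
}
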