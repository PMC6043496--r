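# Propensity scales: construction, packaged defaults, standardization.

#' Create a propensity scale
#'
#' @param name Scale identifier.
#' @param values Named numeric vector with one value per standard residue.
#' @param standardize Standardize to zero mean / unit population variance
#'   over the 20 residues.
#' @return A \linkS4class{PropensityScale}.
#' @export
#' @examples
#' charge <- propensityScale("net-charge",
#'   setNames(ifelse(aminoAcids() %in% c("K", "R"), 1,
#'            ifelse(aminoAcids() %in% c("D", "E"), -1, 0)), aminoAcids()))
propensityScale <- function(name, values, standardize = FALSE) {
  if (is.null(names(values)) || !setequal(names(values), .AA20))
    configError("scale '%s' must provide values named by all 20 standard residues",
                name)
  obj <- new("PropensityScale", name = name,
             values = values[.AA20], standardized = FALSE)
  if (standardize) obj <- standardizeScale(obj) else obj
}

#' Standardize a propensity scale
#'
#' Centers and scales the 20 residue values to zero mean and unit
#' population (divide-by-n) standard deviation, the convention used before
#' the PAAC correlation function. Standardizing an already standardized
#' scale is a no-op.
#'
#' @param scale A \linkS4class{PropensityScale}.
#' @return The standardized scale.
#' @export
standardizeScale <- function(scale) {
  stopifnot(is(scale, "PropensityScale"))
  v <- scale@values
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0)
    configError("scale '%s' is constant and cannot be standardized", scale@name)
  new("PropensityScale", name = scale@name, values = (v - m) / s,
      standardized = TRUE)
}

#' Read a propensity scale from a two-column delimited file
#'
#' The file format is tab- or whitespace-delimited text with a header row
#' (\code{residue}, \code{value}) and optional \code{#} comment lines.
#'
#' @param path File path.
#' @param name Scale name; defaults to the file name without extension.
#' @param standardize Standardize after reading.
#' @return A \linkS4class{PropensityScale}.
#' @export
readScale <- function(path, name = NULL, standardize = FALSE) {
  if (!file.exists(path)) userError("scale file not found: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab)))
    configError("scale file %s must have columns 'residue' and 'value'", path)
  propensityScale(name, setNames(as.numeric(tab$value), toupper(tab$residue)),
                  standardize = standardize)
}

#' The five packaged propensity scales
#'
#' Returns the scales used by the default PAAC configuration: TOP-IDP
#' (disorder propensity), B-values (flexibility), FoldUnfold (contact
#' capacity; synthetic reconstruction, see the packaged file header),
#' DisProt (composition bias; synthetic reconstruction) and net charge.
#'
#' @param standardize Standardize each scale (the default, as required by
#'   the PAAC correlation function).
#' @return Named list of \linkS4class{PropensityScale} objects.
#' @export
#' @examples
#' names(defaultScales())
defaultScales <- function(standardize = TRUE) {
  dir <- system.file("extdata", "scales", package = "disoPPI", mustWork = TRUE)
  files <- c("TOP-IDP" = "top_idp.tsv",
             "B-values" = "b_values.tsv",
             "FoldUnfold" = "foldunfold_synthetic.tsv",
             "DisProt" = "disprot_synthetic.tsv",
             "net-charge" = "net_charge.tsv")
  out <- lapply(seq_along(files), function(i)
    readScale(file.path(dir, files[[i]]), name = names(files)[i],
              standardize = standardize))
  setNames(out, names(files))
}

#' @describeIn PropensityScale-class Scale name.
#' @export
setMethod("scaleName", "PropensityScale", function(x) x@name)

#' @describeIn PropensityScale-class Named numeric values in residue order.
#' @export
setMethod("scaleValues", "PropensityScale", function(x) x@values)

#' @describeIn PropensityScale-class Whether the scale is standardized.
#' @export
setMethod("isStandardized", "PropensityScale", function(x) x@standardized)

setMethod("show", "PropensityScale", function(object) {
  cat(sprintf("PropensityScale '%s'%s\n", object@name,
              if (object@standardized) " (standardized)" else ""))
  print(round(object@values, 3))
})
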