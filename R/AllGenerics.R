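#' Chain length of an object carrying per-residue information
#'
#' @param x a ContactMap, TopologyProfile, SSProfile, StructureModel or
#'   SyntheticProtein.
#' @return integer(1), the number of residues L.
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))

#' Contact table of a ContactMap
#'
#' @param x a ContactMap (or SyntheticProtein, whose true map is returned).
#' @return data.frame with columns \code{i}, \code{j}, \code{score},
#'   canonicalised so that \code{i < j}.
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @export
setMethod("chainLength", "ContactMap", function(x) x@L)
#' @export
setMethod("chainLength", "TopologyProfile", function(x) nchar(x@labels))
#' @export
setMethod("chainLength", "SSProfile", function(x) nchar(x@states))
#' @export
setMethod("chainLength", "StructureModel", function(x) length(x@resno))
#' @export
setMethod("chainLength", "SyntheticProtein", function(x) nchar(x@sequence))

#' @export
setMethod("contacts", "ContactMap", function(x) x@contacts)
#' @export
setMethod("contacts", "SyntheticProtein", function(x) x@trueMap@contacts)

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: L = %d, %d contacts", object@L, nrow(object@contacts)))
  if (nrow(object@contacts))
    cat(sprintf(", scores in [%.3f, %.3f]",
                min(object@contacts$score), max(object@contacts$score)))
  cat("\n")
})

setMethod("show", "TopologyProfile", function(object) {
  seg <- topoSegments(object)
  cat(sprintf("TopologyProfile: L = %d, %d segments (%d membrane)\n",
              chainLength(object), nrow(seg), sum(seg$label == "M")))
})

setMethod("show", "SSProfile", function(object) {
  s <- strsplit(object@states, "")[[1]]
  cat(sprintf("SSProfile: L = %d (H: %d, E: %d, C: %d)\n",
              length(s), sum(s == "H"), sum(s == "E"), sum(s == "C")))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d residues (%d with C-beta)\n",
              length(object@resno), sum(!is.na(object@cb[, 1]))))
})

setMethod("show", "SyntheticProtein", function(object) {
  cat(sprintf("SyntheticProtein '%s': L = %d, %d true / %d noisy contacts\n",
              object@id, chainLength(object),
              nrow(object@trueMap@contacts), nrow(object@noisyMap@contacts)))
  el <- object@truth$elements
  if (!is.null(el))
    cat("  elements:", paste(el$kind, collapse = " - "), "\n")
})

setMethod("show", "BoundaryResult", function(object) {
  cat(sprintf("BoundaryResult: L = %d, %d candidate boundaries",
              length(object@profile), length(object@minima)))
  if (length(object@minima))
    cat(":", paste(object@minima, collapse = ", "))
  cat("\n")
})

setMethod("show", "RepeatHit", function(object) {
  cat(sprintf(
    "RepeatHit: split = %d, offset = %+d, Jaccard = %.3f, p = %.4g (%d permutations)\n",
    object@split, object@offset, object@score, object@pValue, object@nPerm))
})

setMethod("show", "PrecisionReport", function(object) {
  cat(sprintf(
    "PrecisionReport: %d / %d top contacts satisfied (%.1f%%) at d <= %.1f A, |i-j| >= %d\n",
    object@nSatisfied, object@nConsidered, 100 * object@fraction,
    object@dCut, object@sMin))
})

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d entries, z_cut = %.2f, %d components\n",
              length(object@ids), object@zCut, length(unique(object@membership))))
})
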