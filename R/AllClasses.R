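#' @import methods
NULL

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y","X")

#' Scored residue-residue contact predictions over one chain
#'
#' A sparse set of scored residue pairs \code{(i, j, score)} over a chain of
#' length \code{L}. All indices are 1-based, every stored pair satisfies
#' \code{i < j}, pairs are unique and scores lie in \eqn{[0, 1]}.
#'
#' @slot L integer(1), chain length.
#' @slot contacts data.frame with integer columns \code{i}, \code{j} and a
#'   numeric \code{score} column.
#'
#' @seealso [ContactMap()] for the user-facing constructor,
#'   [readCaspRR()] to read the CASP-RR text format.
#' @export
setClass("ContactMap",
  representation(L = "integer", contacts = "data.frame"),
  validity = function(object) {
    msg <- character()
    ct <- object@contacts
    if (length(object@L) != 1L || is.na(object@L) || object@L < 1L)
      msg <- c(msg, "L must be a single positive integer")
    if (!all(c("i", "j", "score") %in% names(ct)))
      msg <- c(msg, "contacts must have columns i, j, score")
    else if (nrow(ct)) {
      if (any(ct$i >= ct$j)) msg <- c(msg, "every contact must have i < j")
      if (any(ct$i < 1L) || any(ct$j > object@L))
        msg <- c(msg, "contact indices outside [1, L]")
      if (anyDuplicated(ct[c("i", "j")]))
        msg <- c(msg, "duplicate (i, j) pairs")
      if (any(ct$score < 0 | ct$score > 1))
        msg <- c(msg, "scores must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-residue membrane topology labels
#'
#' One label per residue over the TOPCONS alphabet: \code{i} (inside),
#' \code{o} (outside), \code{M} (membrane-embedded) and \code{S} (signal
#' peptide). Maximal runs of one label form the derived segmentation
#' returned by [topoSegments()].
#'
#' @slot labels character(1), the per-residue label string.
#' @export
setClass("TopologyProfile",
  representation(labels = "character"),
  validity = function(object) {
    if (length(object@labels) != 1L)
      return("labels must be a single string")
    bad <- setdiff(strsplit(object@labels, "")[[1]], c("i", "o", "M", "S"))
    if (length(bad))
      return(paste0("unknown topology labels: ", paste(unique(bad), collapse = ", ")))
    TRUE
  })

#' Per-residue secondary-structure states
#'
#' Three-state secondary structure (\code{H} helix, \code{E} strand,
#' \code{C} coil), optionally with per-residue confidence triples
#' (coil, helix, strand) summing to 1 as in PSIPRED ss2 output.
#'
#' @slot states character(1), the per-residue state string.
#' @slot conf numeric matrix with L rows and columns \code{C,H,E}, or a
#'   0-row matrix when confidences are unavailable.
#' @export
setClass("SSProfile",
  representation(states = "character", conf = "matrix"),
  validity = function(object) {
    if (length(object@states) != 1L)
      return("states must be a single string")
    bad <- setdiff(strsplit(object@states, "")[[1]], c("H", "E", "C"))
    if (length(bad))
      return(paste0("unknown ss states: ", paste(unique(bad), collapse = ", ")))
    if (nrow(object@conf)) {
      if (nrow(object@conf) != nchar(object@states))
        return("conf rows must match states length")
      s <- rowSums(object@conf)
      if (any(abs(s - 1) > 0.01))
        return("confidence triples must sum to 1 (+/- 0.01)")
    }
    TRUE
  })

#' Reduced 3D model: one C-alpha / C-beta pair per residue
#'
#' A per-residue coordinate model sufficient for contact evaluation:
#' residue numbers (strictly increasing), one-letter amino-acid codes,
#' C-alpha coordinates and C-beta coordinates (an NA row where C-beta is
#' absent, e.g. glycine; [effectiveCB()] falls back to C-alpha there).
#'
#' @slot resno integer vector of residue numbers.
#' @slot aa character vector of one-letter codes.
#' @slot ca numeric matrix (n x 3) of C-alpha coordinates in Angstrom.
#' @slot cb numeric matrix (n x 3) of C-beta coordinates; NA rows allowed.
#' @export
setClass("StructureModel",
  representation(resno = "integer", aa = "character",
                 ca = "matrix", cb = "matrix"),
  validity = function(object) {
    n <- length(object@resno)
    if (length(object@aa) != n || nrow(object@ca) != n || nrow(object@cb) != n)
      return("resno, aa, ca, cb must agree in length")
    if (n > 1L && any(diff(object@resno) <= 0L))
      return("residue numbers must be strictly increasing")
    if (n && any(!is.finite(object@ca)))
      return("C-alpha coordinates must be finite")
    if (n) {
      cbna <- is.na(object@cb)
      mixed <- rowSums(cbna) %in% c(1L, 2L)
      if (any(mixed)) return("C-beta rows must be fully present or fully NA")
      if (any(!is.finite(object@cb[!cbna]))) return("C-beta coordinates must be finite")
    }
    TRUE
  })

#' Membrane region annotations for one chain (PDBTM-style)
#'
#' @slot chain character(1) chain identifier.
#' @slot regions data.frame with columns \code{start}, \code{end},
#'   \code{code}; regions are non-overlapping and \code{start <= end}.
#' @export
setClass("RegionAnnotation",
  representation(chain = "character", regions = "data.frame"),
  validity = function(object) {
    rg <- object@regions
    if (!all(c("start", "end", "code") %in% names(rg)))
      return("regions must have columns start, end, code")
    if (nrow(rg)) {
      if (any(rg$start > rg$end)) return("region start must be <= end")
      o <- order(rg$start)
      if (nrow(rg) > 1L && any(rg$start[o][-1L] <= rg$end[o][-nrow(rg)]))
        return("regions overlap within the chain")
    }
    TRUE
  })

#' Synthetic membrane protein with planted ground truth
#'
#' The full fixture produced by [buildProtein()]: ideal coordinates, a
#' hydrophobicity-patterned sequence, topology and secondary-structure
#' tracks, the geometric true contact map, a noise-corrupted "predicted"
#' map, and the truth labels every downstream test checks against.
#'
#' @slot id character(1).
#' @slot sequence character(1) one-letter residue string.
#' @slot model a [StructureModel-class].
#' @slot topology a [TopologyProfile-class].
#' @slot ss an [SSProfile-class].
#' @slot trueMap,noisyMap [ContactMap-class] objects.
#' @slot truth named list: \code{boundaries} (integer), \code{repeats}
#'   (data.frame start,end,orientation), \code{reentrant} (data.frame
#'   start,end,turnStart,turnEnd), \code{amphipathic} (data.frame start,end),
#'   \code{elements} (per-element table).
#' @export
setClass("SyntheticProtein",
  representation(id = "character", sequence = "character",
                 model = "StructureModel", topology = "TopologyProfile",
                 ss = "SSProfile", trueMap = "ContactMap",
                 noisyMap = "ContactMap", truth = "list"),
  validity = function(object) {
    L <- nchar(object@sequence)
    if (length(object@model@resno) != L) return("model length != sequence length")
    if (nchar(object@topology@labels) != L) return("topology length != sequence length")
    if (nchar(object@ss@states) != L) return("ss length != sequence length")
    if (object@trueMap@L != L || object@noisyMap@L != L)
      return("contact map L != sequence length")
    TRUE
  })

#' Contact-density boundary analysis result
#'
#' @slot profile numeric(L), the smoothed spanning-contact density; entry k
#'   counts (smoothed) selected contacts with i < k <= j.
#' @slot minima integer vector of candidate boundary positions, ranked by
#'   increasing smoothed density (deepest first).
#' @slot params named list of the parameters used (nTop, bandwidth, margin).
#' @export
setClass("BoundaryResult",
  representation(profile = "numeric", minima = "integer", params = "list"))

#' Internal tandem-repeat test result
#'
#' @slot split integer(1), best split point b (last residue of the N-half).
#' @slot offset integer(1), best register offset between the half maps.
#' @slot score numeric(1), Jaccard similarity of the binarised half maps.
#' @slot pValue numeric(1), permutation p-value.
#' @slot nPerm integer(1), number of permutations.
#' @slot nCross integer(1), cross-half contacts discarded at the best split.
#' @export
setClass("RepeatHit",
  representation(split = "integer", offset = "integer", score = "numeric",
                 pValue = "numeric", nPerm = "integer", nCross = "integer"),
  validity = function(object) {
    if (object@score < 0 || object@score > 1) return("score outside [0,1]")
    if (object@nPerm > 0L && object@pValue < 1 / (object@nPerm + 1) - 1e-12)
      return("pValue below permutation resolution")
    TRUE
  })

#' Top-L contact satisfaction report
#'
#' @slot nConsidered,nSatisfied integer counts.
#' @slot fraction numeric(1) in [0,1].
#' @slot dCut,sMin the contact definition used (Angstrom cut-off, minimum
#'   sequence separation).
#' @slot matches data.frame of the considered predicted contacts with a
#'   logical \code{matched} column.
#' @export
setClass("PrecisionReport",
  representation(nConsidered = "integer", nSatisfied = "integer",
                 fraction = "numeric", dCut = "numeric", sMin = "integer",
                 matches = "data.frame"),
  validity = function(object) {
    if (object@nConsidered > 0L &&
        abs(object@fraction - object@nSatisfied / object@nConsidered) > 1e-9)
      return("fraction inconsistent with counts")
    TRUE
  })

#' Thresholded structural-similarity graph with its components
#'
#' @slot ids character vector of entry identifiers.
#' @slot z symmetric numeric matrix of pairwise similarity Z-scores.
#' @slot zCut numeric(1), the edge threshold.
#' @slot membership integer vector: connected-component id per entry under
#'   edges \code{Z >= zCut}.
#' @export
setClass("SimilarityGraph",
  representation(ids = "character", z = "matrix", zCut = "numeric",
                 membership = "integer"),
  validity = function(object) {
    n <- length(object@ids)
    if (nrow(object@z) != n || ncol(object@z) != n)
      return("z must be n x n")
    if (n && max(abs(object@z - t(object@z)), na.rm = TRUE) > 1e-6)
      return("z must be symmetric within 1e-6")
    if (length(object@membership) != n)
      return("membership length must match ids")
    TRUE
  })
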