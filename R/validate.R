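# Model validation by predicted-contact satisfaction: the fraction of the
# top-L predicted contacts realised in the 3D model is the model-quality
# statistic (values around 0.8 indicate a model consistent with the
# prediction).

#' Geometric contacts of a 3D model
#'
#' All residue pairs with sequence separation >= \code{sMin} whose C-beta
#' atoms (C-alpha for glycine or where C-beta is missing) are within
#' \code{dCut} Angstrom. Scores are 1.0.
#'
#' @param model a [StructureModel-class] with >= 2 residues.
#' @param dCut distance cut-off in Angstrom (default 8.0).
#' @param sMin minimum sequence separation |i - j| (default 5).
#' @return a [ContactMap-class] indexed by position in the model
#'   (1..n residues); residue numbering gaps are respected through the
#'   model's \code{resno} for the separation filter.
#' @export
modelContacts <- function(model, dCut = 8.0, sMin = 5L) {
  n <- length(model@resno)
  if (n < 2L) stop("model must have at least 2 residues")
  xyz <- effectiveCB(model)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(model@resno, model@resno, "-"))
  hit <- which(upper.tri(d) & d <= dCut & sep >= sMin, arr.ind = TRUE)
  ContactMap(n, hit[, 1], hit[, 2], rep(1, nrow(hit)))
}

#' Fraction of top-n predicted contacts satisfied by a model
#'
#' Selects the \code{n} highest-scoring predicted contacts (default n = L,
#' the chain length) and reports the fraction present among the model's
#' geometric contacts under the given contact definition. The per-contact
#' match list supports the standard overlay plot classes (matched,
#' mismatched, and model contacts not predicted).
#'
#' @param pred predicted [ContactMap-class].
#' @param model a [StructureModel-class] of the same chain length.
#' @param n number of top predicted contacts to evaluate (default L).
#' @param dCut,sMin contact definition, as in [modelContacts()].
#' @return a [PrecisionReport-class].
#' @export
topLPrecision <- function(pred, model, n = pred@L, dCut = 8.0, sMin = 5L) {
  if (pred@L != length(model@resno))
    stop("prediction and model disagree in chain length")
  mc <- modelContacts(model, dCut = dCut, sMin = sMin)
  top <- suppressWarnings(selectTop(pred, n))
  ct <- top@contacts
  modelKey <- .pairKeys(mc@contacts$i, mc@contacts$j)
  matched <- .pairKeys(ct$i, ct$j) %in% modelKey
  nC <- nrow(ct)
  nS <- sum(matched)
  ct$matched <- matched
  new("PrecisionReport", nConsidered = as.integer(nC),
      nSatisfied = as.integer(nS),
      fraction = if (nC) nS / nC else 0,
      dCut = dCut, sMin = as.integer(sMin), matches = ct)
}
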