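# Canonical synthetic study conditions. These fixtures are the package's
# reference test-beds; their dimensions follow the archetypes the analyses
# target: a ~170-residue chain splitting into a ~60-residue N-domain, a
# two-fold pseudo-inverted repeat of ~60-residue units, a DedA-like
# architecture (amphipathic helix -> re-entrant hairpin -> TM helix, twice,
# with inverted orientation), and a plain four-TM bundle negative control.

#' Reference synthetic protein specifications
#'
#' \describe{
#'   \item{\code{two_domain}}{Three-TM N-domain (60 residues) and five-TM
#'     C-domain joined by a 5-residue linker; L = 167, planted boundary at
#'     residue 63. For boundary-recovery experiments.}
#'   \item{\code{tandem60}}{A 60-residue three-TM unit duplicated with
#'     inverted orientation; L = 124, planted split near residue 60-64. For
#'     repeat-detection experiments.}
#'   \item{\code{deda}}{Amphipathic helix (15), re-entrant hairpin (26,
#'     4-residue turn), TM helix (21), duplicated with inverted
#'     orientation; L = 140. The full architecture fixture.}
#'   \item{\code{bundle4}}{Four TM helices with connecting loops and no
#'     hairpin; the negative control for re-entrant detection.}
#' }
#'
#' @param type fixture name (see Details).
#' @param pTP,nFP,seed noise plan forwarded to [syntheticSpec()]; \code{nFP
#'   = NULL} (default) injects \code{0.2 * L} false positives.
#' @return a [syntheticSpec()] ready for [buildProtein()].
#' @export
exampleSpec <- function(type = c("two_domain", "tandem60", "deda", "bundle4"),
                        pTP = 0.8, nFP = NULL, seed = 1L) {
  type <- match.arg(type)
  tmUnit60 <- rbind(element("tm", 18), element("loop", 3), element("tm", 18),
                    element("loop", 3), element("tm", 18))
  built <- switch(type,
    two_domain = list(
      elements = rbind(tmUnit60, element("loop", 5, gap = TRUE),
                       element("tm", 18), element("loop", 3),
                       element("tm", 18), element("loop", 3),
                       element("tm", 18), element("loop", 3),
                       element("tm", 18), element("loop", 3),
                       element("tm", 18)),
      repeatUnit = NULL),
    tandem60 = list(elements = tmUnit60, repeatUnit = 1:5),
    deda = list(
      elements = rbind(element("amphipathic", 15),
                       element("reentrant", 26, turn = 4),
                       element("loop", 3), element("tm", 21),
                       element("loop", 3)),
      repeatUnit = 1:5),
    bundle4 = list(
      elements = do.call(rbind, rep(list(rbind(element("tm", 21),
                                               element("loop", 4))), 4)),
      repeatUnit = NULL))
  L <- sum(built$elements$length) +
    if (is.null(built$repeatUnit)) 0L else
      sum(built$elements$length[built$repeatUnit]) + 4L
  if (is.null(nFP)) nFP <- round(0.2 * L)
  syntheticSpec(built$elements, repeatUnit = built$repeatUnit,
                pTP = pTP, nFP = nFP, seed = seed, id = type)
}
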