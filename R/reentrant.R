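# Re-entrant helix detection.
#
# Topology predictors tend to report a membrane re-entrant hairpin as one
# ordinary TM helix; the give-away is a short coil break near the middle of
# that "helix" in the secondary-structure track (observed break lengths of
# 2 and 6 residues motivate the default [2, 8] window), plus a packing
# signature in the contact map: the limb nearer a flanking TM helix packs
# antiparallel against it while the returning limb packs parallel.

.emptyCandidates <- function() {
  data.frame(segStart = integer(0), segEnd = integer(0),
             breakStart = integer(0), breakEnd = integer(0),
             limb1Start = integer(0), limb1End = integer(0),
             limb2Start = integer(0), limb2End = integer(0),
             partnerStart = integer(0), partnerEnd = integer(0),
             rho1 = numeric(0), rho2 = numeric(0),
             n1 = integer(0), n2 = integer(0), score = numeric(0))
}

#' Find TM-predicted segments broken by an internal coil run
#'
#' Scans every membrane (\code{M}) topology segment for the re-entrant
#' geometry signature: exactly one maximal coil run in the
#' secondary-structure states, of length within \code{[minBreak,
#' maxBreak]}, flanked on both sides by helical runs of at least
#' \code{minLimb} residues, with the run's centre inside the middle 50% of
#' the segment. The rule is deterministic; scoring against the contact map
#' is done by [scoreReentrant()].
#'
#' @param topology a [TopologyProfile-class].
#' @param ss an [SSProfile-class] of the same length.
#' @param minBreak,maxBreak allowed coil-run length range (defaults 2, 8).
#' @param minLimb minimum helical run on each side of the break (default 4).
#' @return data.frame of candidates (zero rows if none): segment, break and
#'   limb intervals, with scoring columns set to NA.
#' @export
findBrokenTM <- function(topology, ss, minBreak = 2L, maxBreak = 8L,
                         minLimb = 4L) {
  if (chainLength(topology) != chainLength(ss))
    stop("topology and secondary-structure profiles differ in length")
  segs <- topoSegments(topology)
  segs <- segs[segs$label == "M", , drop = FALSE]
  states <- strsplit(ss@states, "")[[1]]
  out <- .emptyCandidates()
  for (k in seq_len(nrow(segs))) {
    s0 <- segs$start[k]; s1 <- segs$end[k]
    st <- states[s0:s1]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    coil <- which(r$values == "C")
    if (length(coil) != 1L) next
    cl <- r$lengths[coil]
    if (cl < minBreak || cl > maxBreak) next
    if (coil == 1L || coil == length(r$values)) next
    if (r$values[coil - 1L] != "H" || r$lengths[coil - 1L] < minLimb) next
    if (r$values[coil + 1L] != "H" || r$lengths[coil + 1L] < minLimb) next
    n <- s1 - s0 + 1L
    centre <- (starts[coil] + ends[coil]) / 2
    if (centre < 0.25 * n || centre > 0.75 * n) next
    bS <- s0 + starts[coil] - 1L
    bE <- s0 + ends[coil] - 1L
    out <- rbind(out, data.frame(
      segStart = s0, segEnd = s1, breakStart = bS, breakEnd = bE,
      limb1Start = s0, limb1End = bS - 1L,
      limb2Start = bE + 1L, limb2End = s1,
      partnerStart = NA_integer_, partnerEnd = NA_integer_,
      rho1 = NA_real_, rho2 = NA_real_,
      n1 = NA_integer_, n2 = NA_integer_, score = NA_real_))
  }
  rownames(out) <- NULL
  out
}

#' Packing orientation between two segments from inter-segment contacts
#'
#' Over the top-n contacts linking the two disjoint intervals, computes the
#' Spearman rank correlation of the segA-side index against the segB-side
#' index: -1 indicates antiparallel packing, +1 parallel. With fewer than 3
#' supporting contacts the correlation is undefined and returned as NA.
#'
#' @param map a [ContactMap-class].
#' @param segA,segB integer length-2 vectors (start, end); must be disjoint.
#' @param nTop number of top-scoring contacts considered; default twice the
#'   chain length.
#' @return list(rho = numeric(1) or NA, n = integer(1)).
#' @export
packingOrientation <- function(map, segA, segB, nTop = 2L * map@L) {
  if (max(segA[1], segB[1]) <= min(segA[2], segB[2]))
    stop("segments must be disjoint")
  top <- suppressWarnings(selectTop(map, min(nTop, nrow(map@contacts))))
  ct <- top@contacts
  inA_i <- ct$i >= segA[1] & ct$i <= segA[2]
  inB_j <- ct$j >= segB[1] & ct$j <= segB[2]
  inB_i <- ct$i >= segB[1] & ct$i <= segB[2]
  inA_j <- ct$j >= segA[1] & ct$j <= segA[2]
  a <- c(ct$i[inA_i & inB_j], ct$j[inB_i & inA_j])
  b <- c(ct$j[inA_i & inB_j], ct$i[inB_i & inA_j])
  n <- length(a)
  if (n < 3L) return(list(rho = NA_real_, n = n))
  rho <- suppressWarnings(stats::cor(a, b, method = "spearman"))
  if (is.na(rho)) rho <- 0  # ties can make rank variance zero
  list(rho = rho, n = n)
}

#' Score re-entrant candidates against the contact map
#'
#' For each candidate from [findBrokenTM()], chooses the flanking membrane
#' helix with the most supporting contacts as the packing partner and
#' computes the composite score
#' \code{wGeom + wPack * max(0, (-rho_anti + rho_para) / 2)}, where
#' \code{rho_anti} is the orientation correlation of the limb expected to
#' pack antiparallel against the partner (the N-side limb when the partner
#' precedes the candidate, by hairpin geometry) and \code{rho_para} that of
#' the other limb. Undefined correlations (support < 3) contribute 0.
#' Candidates are returned ranked by decreasing score.
#'
#' @param candidates data.frame from [findBrokenTM()].
#' @param map a [ContactMap-class].
#' @param topology the [TopologyProfile-class] used to find flanking
#'   membrane segments.
#' @param nTop contacts considered for packing; see [packingOrientation()].
#' @param wGeom,wPack weights of the geometric and packing components
#'   (defaults 0.4 / 0.6).
#' @return the candidates data.frame with partner, rho, support and score
#'   columns filled, ranked by score.
#' @export
scoreReentrant <- function(candidates, map, topology, nTop = 2L * map@L,
                           wGeom = 0.4, wPack = 0.6) {
  if (!nrow(candidates)) return(candidates)
  segs <- topoSegments(topology)
  segs <- segs[segs$label == "M", , drop = FALSE]
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    flank <- segs[segs$end < cand$segStart | segs$start > cand$segEnd, ,
                  drop = FALSE]
    # exclude flanking segments that are themselves broken candidates
    flank <- flank[!(flank$start %in% candidates$segStart), , drop = FALSE]
    if (!nrow(flank)) {
      warning("candidate at ", cand$segStart,
              " has no flanking membrane helix; packing component set to 0")
      candidates$score[k] <- wGeom
      next
    }
    best <- NULL
    for (f in seq_len(nrow(flank))) {
      p <- c(flank$start[f], flank$end[f])
      o1 <- packingOrientation(map, c(cand$limb1Start, cand$limb1End), p, nTop)
      o2 <- packingOrientation(map, c(cand$limb2Start, cand$limb2End), p, nTop)
      if (is.null(best) || o1$n + o2$n > best$n1 + best$n2)
        best <- list(p = p, rho1 = o1$rho, rho2 = o2$rho,
                     n1 = o1$n, n2 = o2$n)
    }
    precedes <- best$p[2] < cand$segStart
    rhoAnti <- if (precedes) best$rho1 else best$rho2
    rhoPara <- if (precedes) best$rho2 else best$rho1
    if (is.na(rhoAnti)) rhoAnti <- 0
    if (is.na(rhoPara)) rhoPara <- 0
    pack <- max(0, (-rhoAnti + rhoPara) / 2)
    candidates$partnerStart[k] <- best$p[1]
    candidates$partnerEnd[k] <- best$p[2]
    candidates$rho1[k] <- best$rho1
    candidates$rho2[k] <- best$rho2
    candidates$n1[k] <- best$n1
    candidates$n2[k] <- best$n2
    candidates$score[k] <- wGeom + wPack * pack
  }
  candidates[order(-candidates$score), , drop = FALSE]
}

#' Detect and score re-entrant helix candidates in one call
#'
#' Convenience wrapper: [findBrokenTM()] then [scoreReentrant()].
#'
#' @inheritParams findBrokenTM
#' @inheritParams scoreReentrant
#' @return ranked candidates data.frame.
#' @export
findReentrant <- function(map, topology, ss, minBreak = 2L, maxBreak = 8L,
                          minLimb = 4L, nTop = 2L * map@L,
                          wGeom = 0.4, wPack = 0.6) {
  cand <- findBrokenTM(topology, ss, minBreak, maxBreak, minLimb)
  scoreReentrant(cand, map, topology, nTop, wGeom, wPack)
}
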