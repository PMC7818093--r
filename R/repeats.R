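# Internal tandem-repeat detection from contact maps.
#
# A two-unit repeat leaves near-identical intra-unit contact patterns in
# the N- and C-terminal halves of the map. The statistic is the Jaccard
# similarity of the binarised half maps, maximised over a register offset
# and candidate split points; significance comes from a permutation null
# that preserves each half's multiset of sequence separations |i - j|
# (contact maps are strongly banded, so a separation-preserving null is
# far stricter than uniform pair shuffling).

#' Split a contact map at residue b into two intra-half maps
#'
#' @param map a [ContactMap-class].
#' @param b split point, 1 < b < L: the N-half covers residues 1..b, the
#'   C-half b+1..L (re-indexed to start at 1). Contacts crossing the split
#'   are discarded and counted.
#' @return list with elements \code{first}, \code{second} (ContactMaps) and
#'   \code{nCross} (discarded cross-half contacts).
#' @export
splitMap <- function(map, b) {
  b <- as.integer(b)
  L <- map@L
  if (is.na(b) || b <= 1L || b >= L) stop("split b must satisfy 1 < b < L")
  ct <- map@contacts
  inN <- ct$j <= b
  inC <- ct$i > b
  first <- ContactMap(b, ct$i[inN], ct$j[inN], ct$score[inN])
  second <- ContactMap(L - b, ct$i[inC] - b, ct$j[inC] - b, ct$score[inC])
  list(first = first, second = second,
       nCross = sum(!inN & !inC))
}

.pairKeys <- function(i, j) i * 100000L + j

# Jaccard of two contact sets at register offset delta, restricted to
# pairs valid in both index frames (symmetric: f(A,B,d) == f(B,A,-d))
.jaccardShift <- function(iA, jA, LA, iB, jB, LB, delta) {
  okA <- (iA + delta) >= 1L & (jA + delta) <= LB
  okB <- (iB - delta) >= 1L & (jB - delta) <= LA
  nA <- sum(okA); nB <- sum(okB)
  if (nA + nB == 0L) return(0)
  inter <- sum(.pairKeys(iA[okA] + delta, jA[okA] + delta) %in%
                 .pairKeys(iB[okB], jB[okB]))
  inter / (nA + nB - inter)
}

#' Jaccard similarity of two (binarised) contact maps at an offset
#'
#' Shifts map A by \code{delta} residues and computes the Jaccard index of
#' the two contact sets over the pairs valid in both index ranges. Scores
#' are ignored: the maps are treated as binary (select the top contacts
#' upstream). Degenerate inputs (empty union) give 0.
#'
#' @param A,B [ContactMap-class] objects.
#' @param delta integer register offset applied to A.
#' @return Jaccard score in [0, 1].
#' @export
repeatScore <- function(A, B, delta = 0L) {
  a <- A@contacts; b <- B@contacts
  .jaccardShift(a$i, a$j, A@L, b$i, b$j, B@L, as.integer(delta))
}

# top-n binarisation of one half (all contacts if fewer)
.binariseHalf <- function(half, topFactor) {
  n <- min(nrow(half@contacts), max(1L, round(topFactor * half@L)))
  if (nrow(half@contacts) == 0L) return(half)
  suppressWarnings(selectTop(half, n))
}

# random contact set preserving the |i-j| multiset within a chain of
# length n: for each distinct separation, sample start positions without
# replacement (pairs are then unique by construction)
.randSepPairs <- function(seps, n) {
  if (!length(seps)) return(list(i = integer(0), j = integer(0)))
  i <- integer(length(seps))
  for (s in unique(seps)) {
    w <- which(seps == s)
    avail <- n - s
    i[w] <- sample.int(avail, length(w))
  }
  list(i = i, j = i + seps)
}

#' Test a contact map for an internal two-unit tandem repeat
#'
#' For each candidate split b the map is cut into intra-half submaps, each
#' binarised to its top \code{topFactor * half-length} contacts, and the
#' Jaccard similarity of the halves is maximised over register offsets
#' \code{|delta| <= deltaMax}. The best (b, delta) over all candidates is
#' reported. The permutation null replays the identical selection: in each
#' of \code{nPerm} draws, both halves at every candidate split are replaced
#' by random contact sets preserving their \code{|i - j|} multisets and the
#' same maximisation is applied, so the p-value is calibrated under the
#' (b, delta) optimisation. p = (1 + #null >= observed) / (1 + nPerm).
#'
#' @param map a [ContactMap-class] (typically already a prediction's top
#'   contacts).
#' @param splits integer vector of candidate split points (e.g. the minima
#'   from [densityProfile()]).
#' @param nPerm number of permutations (>= 19).
#' @param seed integer seed for the permutation draws (required; logged in
#'   the result).
#' @param deltaMax largest register offset tried (default 10).
#' @param topFactor binarisation depth per half, in units of the half
#'   length (default 1.5).
#' @return a [RepeatHit-class].
#' @export
detectRepeat <- function(map, splits, nPerm = 199L, seed,
                         deltaMax = 10L, topFactor = 1.5) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 19L) stop("nPerm must be >= 19 (p-value resolution)")
  if (missing(seed)) stop("seed is required for the permutation null")
  splits <- as.integer(splits)
  if (!length(splits)) stop("at least one candidate split is required")
  deltas <- seq.int(-deltaMax, deltaMax)

  halves <- lapply(splits, function(b) {
    sm <- splitMap(map, b)
    A <- .binariseHalf(sm$first, topFactor)
    B <- .binariseHalf(sm$second, topFactor)
    list(b = b, nCross = sm$nCross,
         iA = A@contacts$i, jA = A@contacts$j, LA = A@L,
         iB = B@contacts$i, jB = B@contacts$j, LB = B@L)
  })

  scoreHalves <- function(h) {
    sc <- vapply(deltas, function(d)
      .jaccardShift(h$iA, h$jA, h$LA, h$iB, h$jB, h$LB, d), 0)
    k <- which.max(sc)
    c(score = sc[k], delta = deltas[k])
  }

  obs <- vapply(halves, scoreHalves, c(score = 0, delta = 0))
  bestIdx <- which.max(obs["score", ])
  best <- halves[[bestIdx]]
  obsScore <- obs["score", bestIdx]

  nullMax <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(p) {
      max(vapply(halves, function(h) {
        pa <- .randSepPairs(h$jA - h$iA, h$LA)
        pb <- .randSepPairs(h$jB - h$iB, h$LB)
        hp <- list(iA = pa$i, jA = pa$j, LA = h$LA,
                   iB = pb$i, jB = pb$j, LB = h$LB)
        scoreHalves(hp)["score"]
      }, 0))
    }, 0)
  })
  pValue <- (1 + sum(nullMax >= obsScore - 1e-12)) / (1 + nPerm)

  new("RepeatHit", split = best$b,
      offset = as.integer(obs["delta", bestIdx]),
      score = as.numeric(obsScore), pValue = pValue,
      nPerm = nPerm, nCross = as.integer(best$nCross))
}
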