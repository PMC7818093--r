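# Contact-density domain-boundary analysis.
#
# The density at position k counts selected contacts that span k
# (i < k <= j). A compact domain produces a plateau; few contacts span the
# linker between two domains, so candidate boundaries are local minima of
# the Gaussian-smoothed profile.

#' Keep the n highest-scoring contacts
#'
#' Ties are broken deterministically by smaller \code{i}, then smaller
#' \code{j}. Asking for more contacts than the map holds returns the whole
#' map with a warning. The usual choice is \code{n = L} ("top-L").
#'
#' @param map a [ContactMap-class].
#' @param n number of contacts to keep (>= 1).
#' @return a [ContactMap-class] with at most n contacts.
#' @export
selectTop <- function(map, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  ct <- map@contacts
  if (n > nrow(ct)) {
    warning(sprintf("requested %d contacts but map holds %d; returning all",
                    n, nrow(ct)))
    n <- nrow(ct)
  }
  o <- order(-ct$score, ct$i, ct$j)
  ContactMap(map@L, ct$i[o][seq_len(n)], ct$j[o][seq_len(n)],
             ct$score[o][seq_len(n)])
}

# discrete Gaussian smoothing with reflective edge handling
.gaussSmooth <- function(x, bw) {
  half <- max(1L, ceiling(3 * bw))
  kern <- stats::dnorm(-half:half, sd = bw)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rev(x[seq_len(min(half, n))]), x,
          rev(x[seq.int(max(1L, n - half + 1L), n)]))
  sm <- stats::filter(xp, kern, sides = 2)
  as.numeric(sm[(half + 1L):(half + n)])
}

#' Contact-density profile and candidate domain boundaries
#'
#' Computes the raw spanning count \eqn{S(k) = |\{(i,j) : i < k \le j\}|}
#' over the top-n contacts, smooths it with a Gaussian kernel, and reports
#' the local minima of the smoothed profile as candidate domain
#' boundaries, ranked deepest first. A terminal margin is excluded at both
#' ends, and minima within one bandwidth of each other are merged keeping
#' the deeper one. The reported position k is the first residue of the
#' C-terminal side of the putative cut.
#'
#' @param map a [ContactMap-class]; must be non-empty.
#' @param nTop number of top-scoring contacts used; default L.
#' @param bandwidth Gaussian kernel standard deviation in residues
#'   (default 3).
#' @param margin number of terminal residues excluded from boundary calls
#'   (default 10).
#' @return a [BoundaryResult-class].
#' @export
densityProfile <- function(map, nTop = map@L, bandwidth = 3, margin = 10L) {
  if (!nrow(map@contacts)) stop("contact map is empty")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  margin <- as.integer(margin)
  top <- suppressWarnings(selectTop(map, nTop))
  L <- map@L
  ct <- top@contacts
  # spanning count via difference array: contact (i, j) covers k in (i, j]
  d <- tabulate(ct$i + 1L, L + 1L) - tabulate(ct$j + 1L, L + 1L)
  raw <- cumsum(d[seq_len(L)])
  prof <- .gaussSmooth(raw, bandwidth)
  # strict local minima (plateaus take their first position)
  lo <- max(2L, margin)
  hi <- min(L - 1L, L - margin)
  cand <- integer(0)
  k <- lo
  while (k <= hi) {
    if (prof[k] < prof[k - 1L]) {
      k2 <- k
      while (k2 < L && prof[k2 + 1L] == prof[k]) k2 <- k2 + 1L
      if (k2 < L && prof[k2 + 1L] > prof[k]) cand <- c(cand, k)
      k <- k2 + 1L
    } else k <- k + 1L
  }
  if (length(cand)) {
    cand <- cand[order(prof[cand], cand)]
    # merge minima closer than one bandwidth, keeping the deeper
    kept <- integer(0)
    for (m in cand)
      if (!length(kept) || all(abs(kept - m) > bandwidth))
        kept <- c(kept, m)
    cand <- kept
  }
  new("BoundaryResult", profile = prof, minima = as.integer(cand),
      params = list(nTop = nTop, bandwidth = bandwidth, margin = margin,
                    raw = raw))
}
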