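# Eisenberg hydrophobic moment: the magnitude of the vector sum of
# per-residue hydrophobicities placed around the helical wheel at 100 deg
# per residue, normalised by window length. Amphipathic helices (separated
# hydrophobic and polar faces) give large moments.

#' The Fauchere-Pliska hydrophobicity scale
#'
#' Side-chain octanol/water partition free energies relative to glycine
#' (so H(G) = 0), loaded from the packaged data file. This is the scale
#' behind HELIQUEST-style hydrophobic-moment calculations.
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
fpScale <- function() {
  path <- system.file("extdata", "fauchere_pliska_scale.tsv",
                      package = "memscope", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           col.names = c("residue", "H"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$H, tab$residue)
}

#' Hydrophobic moment of one helical window
#'
#' \deqn{\mu_H = \frac{1}{N}\sqrt{\left(\sum_n H_n \sin(\delta n)\right)^2 +
#'   \left(\sum_n H_n \cos(\delta n)\right)^2}, \quad n = 0..N-1}
#' with \eqn{\delta} the wheel angle per residue (100 degrees for an ideal
#' alpha-helix). The direction angle is reported in the wheel frame with
#' residue 0 at 0 degrees.
#'
#' @param window residue string (one-letter codes).
#' @param scale named hydrophobicity vector; default [fpScale()].
#' @param deltaDeg wheel angle per residue in degrees (default 100).
#' @return list: \code{muH} (normalised moment), \code{angleDeg} (moment
#'   direction), \code{meanH} (mean hydrophobicity).
#' @export
hydrophobicMoment <- function(window, scale = fpScale(), deltaDeg = 100) {
  res <- strsplit(window, "")[[1]]
  if (!length(res)) stop("window must be non-empty")
  missing <- setdiff(res, names(scale))
  if (length(missing))
    stop("residue(s) absent from the hydrophobicity scale: ",
         paste(unique(missing), collapse = ", "))
  H <- unname(scale[res])
  n <- seq_along(res) - 1
  ang <- n * deltaDeg * pi / 180
  sSum <- sum(H * sin(ang))
  cSum <- sum(H * cos(ang))
  N <- length(res)
  list(muH = sqrt(sSum^2 + cSum^2) / N,
       angleDeg = atan2(sSum, cSum) * 180 / pi,
       meanH = mean(H))
}

.windowRow <- function(sequence, start, end, scale, deltaDeg) {
  m <- hydrophobicMoment(substr(sequence, start, end), scale, deltaDeg)
  data.frame(start = start, end = end, N = end - start + 1L,
             meanH = m$meanH, muH = m$muH, angleDeg = m$angleDeg)
}

#' Hydrophobic moments of the windows preceding re-entrant candidates
#'
#' For each candidate, scores the \code{w} residues immediately preceding
#' the first limb (the putative surface-bound amphipathic helix feeding the
#' hairpin): window \code{[limb1Start - w, limb1Start - 1]}. Candidates
#' whose window would start before residue 1 are skipped with a warning.
#'
#' @param sequence residue string (or anything coercible by
#'   \code{as.character}).
#' @param candidates data.frame from [findBrokenTM()] / [scoreReentrant()].
#' @param w window length (default 15).
#' @param scale,deltaDeg see [hydrophobicMoment()].
#' @return data.frame of scored windows (possibly zero rows).
#' @export
windowsBeforeReentrants <- function(sequence, candidates, w = 15L,
                                    scale = fpScale(), deltaDeg = 100) {
  sequence <- as.character(sequence)
  out <- NULL
  for (k in seq_len(nrow(candidates))) {
    s <- candidates$limb1Start[k] - w
    if (s < 1L) {
      warning("window before candidate at ", candidates$limb1Start[k],
              " would start before residue 1; skipped")
      next
    }
    out <- rbind(out, .windowRow(sequence, s, candidates$limb1Start[k] - 1L,
                                 scale, deltaDeg))
  }
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0), N = integer(0),
                      meanH = numeric(0), muH = numeric(0),
                      angleDeg = numeric(0))
  out
}

#' Scan a sequence with a sliding hydrophobic-moment window
#'
#' @param sequence residue string.
#' @param w window length (>= 3, <= L).
#' @param step window step (default 1).
#' @param scale,deltaDeg see [hydrophobicMoment()].
#' @return data.frame with one row per window, sortable by \code{muH}.
#' @export
scanMoments <- function(sequence, w = 15L, step = 1L, scale = fpScale(),
                        deltaDeg = 100) {
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  if (w < 3L) stop("window length must be >= 3")
  if (w > L) stop("window length exceeds sequence length")
  starts <- seq.int(1L, L - w + 1L, by = step)
  do.call(rbind, lapply(starts, function(s)
    .windowRow(sequence, s, s + w - 1L, scale, deltaDeg)))
}
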