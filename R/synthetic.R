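# Idealised helical membrane-protein generator with planted ground truth.
#
# Geometry conventions (only relative geometry matters for the analyses):
#   - membrane slab z in [-15, 15] Angstrom (30 A thick)
#   - ideal alpha-helix: 1.5 A rise / residue, 100 deg turn / residue,
#     C-alpha radius 2.3 A, C-beta radius 3.3 A
#   - membrane elements occupy "slots" along x, 9.5 A apart, so only
#     adjacent elements pack (slot distance 19 A is beyond contact range)
#   - re-entrant hairpins descend to mid-membrane (15 A depth) and return
#     to the side they entered from
#   - amphipathic helices lie parallel to the membrane surface
# Backbone continuity between elements is not enforced.

.HELIX_RISE <- 1.5
.HELIX_TWIST <- 100 * pi / 180
.CA_RADIUS <- 2.3
.CB_RADIUS <- 3.3
.SLOT_SPACING <- 9.5
.SLAB_HALF <- 15

# residue assignment cycles by hydrophobicity class
.TM_CYCLE <- c("L", "I", "V", "F", "M")          # uniformly hydrophobic: low moment
.AMPHI_HYDRO <- c("L", "F", "I", "W", "V")       # hydrophobic face
.AMPHI_POLAR <- c("S", "K", "E", "Q", "N", "T")  # polar face
.LOOP_CYCLE <- c("G", "S", "P", "N", "D")

#' Declare one structural element of a synthetic protein
#'
#' @param kind one of \code{"tm"} (membrane-spanning helix),
#'   \code{"reentrant"} (helix-turn-helix hairpin re-entering the same
#'   side), \code{"amphipathic"} (surface helix), \code{"loop"}.
#' @param length number of residues (>= 3).
#' @param turn for \code{"reentrant"}: length of the coil turn at
#'   mid-membrane (default 4).
#' @param gap for \code{"loop"}: if TRUE, the loop is a domain linker and
#'   the next membrane element is placed one slot further away, spatially
#'   separating the flanking domains.
#' @return a one-row data.frame understood by [syntheticSpec()].
#' @export
element <- function(kind = c("tm", "reentrant", "amphipathic", "loop"),
                    length, turn = 4L, gap = FALSE) {
  kind <- match.arg(kind)
  if (length < 3) stop("element lengths must be >= 3")
  if (kind == "reentrant" && length < turn + 8)
    stop("reentrant element too short for turn + two limbs")
  data.frame(kind = kind, length = as.integer(length),
             turn = as.integer(turn), gap = gap, stringsAsFactors = FALSE)
}

#' Specification of a synthetic membrane protein
#'
#' Bundles an ordered element list, an optional tandem-repeat plan, and the
#' contact-noise plan applied to the true geometric map.
#'
#' @param elements data.frame from rbind-ing [element()] rows.
#' @param repeatUnit optional integer vector of element indices; the unit is
#'   duplicated after a short linker loop with inverted membrane
#'   orientation (the second copy starts from the opposite side), planting
#'   a two-fold pseudo-inverted repeat.
#' @param pTP true-positive retention rate in [0, 1] for the noisy map.
#' @param nFP number of false-positive contacts injected.
#' @param seed random seed for the noise.
#' @param id sequence identifier.
#' @return a list with class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(elements, repeatUnit = NULL, pTP = 1, nFP = 0L,
                          seed = 1L, id = "synthetic") {
  stopifnot(is.data.frame(elements), nrow(elements) >= 1)
  if (pTP < 0 || pTP > 1) stop("pTP must lie in [0, 1]")
  if (nFP < 0) stop("nFP must be >= 0")
  if (any(elements$length < 3)) stop("element lengths must be >= 3")
  if (!is.null(repeatUnit)) {
    repeatUnit <- as.integer(repeatUnit)
    if (any(repeatUnit < 1) || any(repeatUnit > nrow(elements)))
      stop("repeatUnit indices out of range")
  }
  structure(list(elements = elements, repeatUnit = repeatUnit,
                 pTP = pTP, nFP = as.integer(nFP), seed = as.integer(seed),
                 id = id),
            class = "syntheticSpec")
}

# evaluate expr under a fixed seed without disturbing the global RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ideal helix: n residues from 'origin' along unit vector 'dir';
# returns list(ca, cb) n x 3 matrices
.helixCoords <- function(n, origin, dir, phase = 0) {
  dir <- dir / sqrt(sum(dir^2))
  # orthonormal frame perpendicular to dir
  up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- up - sum(up * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  t <- seq_len(n) - 1
  ang <- phase + t * .HELIX_TWIST
  axis <- outer(t * .HELIX_RISE, dir) +
    matrix(origin, n, 3, byrow = TRUE)
  radial <- outer(cos(ang), u) + outer(sin(ang), v)
  list(ca = axis + .CA_RADIUS * radial,
       cb = axis + .CB_RADIUS * radial)
}

.sideZ <- function(side) if (side == "i") -.SLAB_HALF else .SLAB_HALF

# amphipathic residue pattern: hydrophobic where the side chain points to
# the membrane (wheel angle within 90 deg of the reference face)
.amphiSeq <- function(n) {
  ang <- (seq_len(n) - 1) * 100 %% 360
  hydro <- cos(ang * pi / 180) >= 0
  out <- character(n)
  out[hydro] <- rep_len(.AMPHI_HYDRO, sum(hydro))
  out[!hydro] <- rep_len(.AMPHI_POLAR, sum(!hydro))
  out
}

#' Build a synthetic membrane protein with planted truth
#'
#' Lays the elements of \code{spec} out as an idealised helical bundle,
#' assigns a hydrophobicity-patterned sequence (amphipathic elements get a
#' two-faced pattern with a high hydrophobic moment; membrane cores a
#' uniformly hydrophobic one), derives topology and secondary-structure
#' tracks, computes the true geometric contact map (C-beta within 8 A,
#' separation >= 5), and corrupts it per the requested noise plan. Re-entrant
#' hairpins are labelled \code{M} across their whole span, mimicking
#' topology predictors that report them as a single membrane helix, while
#' the secondary-structure track shows the coil turn at mid-membrane.
#'
#' Deterministic: the same spec (including seed) yields an identical
#' protein.
#'
#' @param spec a [syntheticSpec()].
#' @return a [SyntheticProtein-class].
#' @export
buildProtein <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  el <- spec$elements
  if (!is.null(spec$repeatUnit)) {
    unit <- el[spec$repeatUnit, , drop = FALSE]
    # the linker separates the units spatially: quasi-independent modules
    el <- rbind(el, element("loop", 4L, gap = TRUE), unit)
    nUnit <- length(spec$repeatUnit)
    unitTag <- c(seq_len(nrow(spec$elements)) %in% spec$repeatUnit,
                 FALSE, rep(TRUE, nUnit))
    unitCopy <- c(ifelse(seq_len(nrow(spec$elements)) %in% spec$repeatUnit, 1L, NA),
                  NA, rep(2L, nUnit))
  } else {
    unitCopy <- rep(NA_integer_, nrow(el))
  }
  L <- sum(el$length)
  if (L < 30) stop("element list produces L < 30")

  side <- "i"
  slot <- 0
  pos <- 1L
  ca <- matrix(NA_real_, L, 3)
  cb <- matrix(NA_real_, L, 3)
  aa <- character(L)
  topo <- character(L)
  ss <- character(L)
  elRows <- list()
  reent <- list()
  amphi <- list()
  bounds <- integer(0)
  sideAtElement <- character(nrow(el))

  for (k in seq_len(nrow(el))) {
    n <- el$length[k]
    kind <- el$kind[k]
    idx <- pos:(pos + n - 1L)
    sideAtElement[k] <- side
    x0 <- slot * .SLOT_SPACING
    if (kind == "tm") {
      dir <- if (side == "i") c(0, 0, 1) else c(0, 0, -1)
      z0 <- .sideZ(side)
      h <- .helixCoords(n, c(x0, 0, z0), dir)
      ca[idx, ] <- h$ca; cb[idx, ] <- h$cb
      aa[idx] <- rep_len(.TM_CYCLE, n)
      topo[idx] <- "M"; ss[idx] <- "H"
      side <- if (side == "i") "o" else "i"
      slot <- slot + 1
    } else if (kind == "reentrant") {
      turn <- el$turn[k]
      limb1 <- (n - turn) %/% 2L
      limb2 <- n - turn - limb1
      zin <- .sideZ(side)
      dirIn <- if (side == "i") c(0, 0, 1) else c(0, 0, -1)
      h1 <- .helixCoords(limb1, c(x0, 0, zin), dirIn)
      x1 <- (slot + 1) * .SLOT_SPACING
      # limb2 returns to the entry side from mid-membrane
      zMid <- zin + dirIn[3] * .SLAB_HALF
      h2 <- .helixCoords(limb2, c(x1, 0, zMid), -dirIn)
      i1 <- idx[seq_len(limb1)]
      iT <- idx[limb1 + seq_len(turn)]
      i2 <- idx[limb1 + turn + seq_len(limb2)]
      ca[i1, ] <- h1$ca; cb[i1, ] <- h1$cb
      ca[i2, ] <- h2$ca; cb[i2, ] <- h2$cb
      # coil turn arcs between the limb tips at mid-membrane
      tt <- seq_len(turn) / (turn + 1)
      turnPath <- outer(1 - tt, h1$ca[limb1, ]) + outer(tt, h2$ca[1, ])
      turnPath[, 2] <- turnPath[, 2] + 3 * sin(pi * tt)
      ca[iT, ] <- turnPath; cb[iT, ] <- turnPath
      aa[i1] <- rep_len(.TM_CYCLE, limb1)
      aa[i2] <- rep_len(rev(.TM_CYCLE), limb2)
      aa[iT] <- rep_len(.LOOP_CYCLE, turn)
      topo[idx] <- "M"  # predictors see the hairpin as one membrane helix
      ss[i1] <- "H"; ss[i2] <- "H"; ss[iT] <- "C"
      reent[[length(reent) + 1L]] <- data.frame(
        start = idx[1], end = idx[n],
        turnStart = iT[1], turnEnd = iT[turn])
      slot <- slot + 2
    } else if (kind == "amphipathic") {
      z <- .sideZ(side) + (if (side == "i") -4 else 4)
      h <- .helixCoords(n, c(x0 - 2, 5, z), c(1, 0, 0))
      ca[idx, ] <- h$ca; cb[idx, ] <- h$cb
      aa[idx] <- .amphiSeq(n)
      topo[idx] <- side; ss[idx] <- "H"
      amphi[[length(amphi) + 1L]] <- data.frame(start = idx[1], end = idx[n])
    } else { # loop
      z <- .sideZ(side) + (if (side == "i") -3.5 else 3.5)
      t <- seq_len(n) - 1
      pts <- cbind(x0 - 3 + 2.0 * t, 6 + 1.5 * sin(t), z)
      ca[idx, ] <- pts; cb[idx, ] <- pts
      aa[idx] <- rep_len(.LOOP_CYCLE, n)
      topo[idx] <- side; ss[idx] <- "C"
      if (isTRUE(el$gap[k])) {
        bounds <- c(bounds, idx[1] + (n - 1L) %/% 2L)
        slot <- slot + 1
      }
    }
    elRows[[k]] <- data.frame(kind = kind, start = idx[1], end = idx[n],
                              side = sideAtElement[k],
                              copy = unitCopy[k], stringsAsFactors = FALSE)
    pos <- pos + n
  }

  elements <- do.call(rbind, elRows)
  repeats <- NULL
  if (!is.null(spec$repeatUnit)) {
    for (cp in 1:2) {
      rows <- elements[which(!is.na(elements$copy) & elements$copy == cp), ,
                       drop = FALSE]
      ori <- if (rows$side[1] == "i") 1L else -1L
      repeats <- rbind(repeats, data.frame(
        start = min(rows$start), end = max(rows$end), orientation = ori))
    }
    # the linker between the two units is a natural boundary
    if (!length(bounds))
      bounds <- repeats$end[1] + (repeats$start[2] - repeats$end[1]) %/% 2L
  }

  model <- StructureModel(resno = seq_len(L), aa = aa, ca = ca, cb = cb)
  trueMap <- modelContacts(model, dCut = 8.0, sMin = 5L)
  noisy <- corruptMap(trueMap, pTP = spec$pTP, nFP = spec$nFP,
                      seed = spec$seed)
  new("SyntheticProtein",
      id = spec$id, sequence = paste(aa, collapse = ""), model = model,
      topology = TopologyProfile(topo), ss = SSProfile(ss),
      trueMap = trueMap, noisyMap = noisy,
      truth = list(boundaries = bounds, repeats = repeats,
                   reentrant = if (length(reent)) do.call(rbind, reent) else NULL,
                   amphipathic = if (length(amphi)) do.call(rbind, amphi) else NULL,
                   elements = elements))
}

#' Corrupt a true contact map into a simulated prediction
#'
#' Each true contact is retained independently with probability \code{pTP}
#' (retained contacts get high scores, uniform on [0.55, 0.95]); \code{nFP}
#' false positives are drawn uniformly from the non-contact pairs with
#' sequence separation >= 5 and get lower scores (uniform on [0.05, 0.5]).
#' Deterministic per seed; with \code{pTP = 1} and \code{nFP = 0} the input
#' is returned unchanged.
#'
#' @param map the true [ContactMap-class].
#' @param pTP retention probability in [0, 1].
#' @param nFP number of false positives to inject.
#' @param seed integer seed.
#' @return a [ContactMap-class].
#' @export
corruptMap <- function(map, pTP, nFP = 0L, seed = 1L) {
  if (pTP < 0 || pTP > 1) stop("pTP must lie in [0, 1]")
  nFP <- as.integer(nFP)
  if (nFP < 0) stop("nFP must be >= 0")
  if (pTP == 1 && nFP == 0L) return(map)  # exact identity: no noise requested
  ct <- map@contacts
  L <- map@L
  .withSeed(seed, {
    keep <- if (nrow(ct)) stats::runif(nrow(ct)) < pTP else logical(0)
    kept <- ct[keep, , drop = FALSE]
    if (nrow(kept)) kept$score <- stats::runif(nrow(kept), 0.55, 0.95)
    if (nFP > 0L) {
      # all candidate pairs with |i - j| >= 5 that are not true contacts
      idx <- which(outer(seq_len(L), seq_len(L), function(a, b) b - a >= 5L),
                   arr.ind = TRUE)
      key <- idx[, 1] * (L + 1L) + idx[, 2]
      trueKey <- ct$i * (L + 1L) + ct$j
      avail <- which(!(key %in% trueKey))
      if (nFP > length(avail))
        stop("nFP exceeds the number of available non-contact pairs")
      pick <- sample(avail, nFP)
      fp <- data.frame(i = idx[pick, 1], j = idx[pick, 2],
                       score = stats::runif(nFP, 0.05, 0.5))
      kept <- rbind(kept, fp)
    }
    ContactMap(L, kept$i, kept$j, kept$score)
  })
}

#' Write a synthetic protein as a full on-disk fixture
#'
#' Emits the formats the analysis consumes: FASTA sequence, CASP-RR
#' contacts (the noisy map), PSIPRED ss2, TOPCONS-style topology string and
#' a PDB coordinate file, so the pipeline runs on fixtures exactly as on
#' real inputs.
#'
#' @param sp a [SyntheticProtein-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name stem; default the protein id.
#' @return named character vector of the written paths.
#' @export
writeFixture <- function(sp, dir, prefix = sp@id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
             rr = file.path(dir, paste0(prefix, ".rr")),
             ss2 = file.path(dir, paste0(prefix, ".ss2")),
             topo = file.path(dir, paste0(prefix, ".topo")),
             pdb = file.path(dir, paste0(prefix, ".pdb")))
  aaset <- Biostrings::AAStringSet(sp@sequence)
  names(aaset) <- sp@id
  Biostrings::writeXStringSet(aaset, paths["fasta"])
  writeCaspRR(sp@noisyMap, paths["rr"])
  writeSS2(sp@ss, sp@sequence, paths["ss2"])
  writeLines(sp@topology@labels, paths["topo"])
  writePDBModel(sp@model, paths["pdb"])
  paths
}

#' Write an SSProfile in PSIPRED ss2 (VFORMAT) layout
#' @param ss an [SSProfile-class].
#' @param sequence residue string of matching length.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSS2 <- function(ss, sequence, path) {
  states <- strsplit(ss@states, "")[[1]]
  aa <- strsplit(sequence, "")[[1]]
  conf <- ss@conf
  if (!nrow(conf)) {
    conf <- matrix(0, length(states), 3, dimnames = list(NULL, c("C", "H", "E")))
    conf[cbind(seq_along(states), match(states, c("C", "H", "E")))] <- 1
  }
  lines <- c("# PSIPRED VFORMAT (synthetic)", "",
             sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                     seq_along(states), aa, states,
                     conf[, 1], conf[, 2], conf[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a StructureModel as a minimal PDB file (C-alpha / C-beta only)
#' @param model a [StructureModel-class].
#' @param path output file.
#' @param chain chain identifier to write.
#' @return invisibly, the path.
#' @export
writePDBModel <- function(model, path, chain = "A") {
  n <- length(model@resno)
  lines <- character(0)
  serial <- 0L
  fmt <- "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00"
  for (r in seq_len(n)) {
    aa3 <- bio3d::aa123(model@aa[r])
    if (is.na(aa3)) aa3 <- "UNK"
    serial <- serial + 1L
    lines <- c(lines, sprintf(fmt, serial, "CA", aa3, chain,
                              model@resno[r], model@ca[r, 1],
                              model@ca[r, 2], model@ca[r, 3]))
    if (!is.na(model@cb[r, 1])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, "CB", aa3, chain,
                                model@resno[r], model@cb[r, 1],
                                model@cb[r, 2], model@cb[r, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
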