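# Re-entrant loop library construction: extract every annotated re-entrant
# loop together with the 30 preceding residues (the TM helix that packs
# against it), remove redundancy at 40% sequence identity, and cluster the
# segments from a supplied pairwise structural-similarity Z matrix at a
# fixed threshold (connected components at Z >= 4.5).

#' Extract re-entrant loop library entries
#'
#' One entry per annotated re-entrant region: the loop plus the \code{pad}
#' residues preceding it, clipped at residue 1. Entries whose extended
#' interval lacks coordinates in the model are kept but flagged.
#'
#' @param annotations list of [RegionAnnotation-class] (e.g. from
#'   [readPDBTMRegions()]).
#' @param models named list of [StructureModel-class], keyed by chain id as
#'   used in the annotations.
#' @param pad residues prepended to the loop (default 30).
#' @param reentrantCode region code treated as re-entrant (default
#'   \code{"reentrant"}, the mapped vocabulary).
#' @return data.frame: sourceId, loopStart, loopEnd, extStart, extEnd,
#'   sequence, complete; plus a \code{coords} list-column of
#'   [StructureModel-class] fragments.
#' @export
extractEntries <- function(annotations, models, pad = 30L,
                           reentrantCode = "reentrant") {
  pad <- as.integer(pad)
  rows <- list(); frags <- list()
  for (ann in annotations) {
    if (!ann@chain %in% names(models))
      stop("no coordinates supplied for annotated chain '", ann@chain, "'")
    model <- models[[ann@chain]]
    rg <- ann@regions
    rg <- rg[rg$code == reentrantCode, , drop = FALSE]
    for (r in seq_len(nrow(rg))) {
      extStart <- max(1L, rg$start[r] - pad)
      extEnd <- rg$end[r]
      keep <- model@resno >= extStart & model@resno <= extEnd
      complete <- sum(keep) == (extEnd - extStart + 1L)
      frag <- StructureModel(model@resno[keep], model@aa[keep],
                             model@ca[keep, , drop = FALSE],
                             model@cb[keep, , drop = FALSE])
      id <- sprintf("%s_%d-%d", ann@chain, rg$start[r], rg$end[r])
      rows[[length(rows) + 1L]] <- data.frame(
        sourceId = id, chain = ann@chain,
        loopStart = rg$start[r], loopEnd = rg$end[r],
        extStart = extStart, extEnd = extEnd,
        sequence = paste(model@aa[keep], collapse = ""),
        complete = complete, stringsAsFactors = FALSE)
      frags[[length(frags) + 1L]] <- frag
    }
  }
  if (!length(rows))
    return(data.frame(sourceId = character(0), chain = character(0),
                      loopStart = integer(0), loopEnd = integer(0),
                      extStart = integer(0), extEnd = integer(0),
                      sequence = character(0), complete = logical(0)))
  out <- do.call(rbind, rows)
  out$coords <- I(frags)
  rownames(out) <- NULL
  out
}

# global-alignment identity: matches / alignment length (gaps included).
# Unitary match matrix, gap opening 10 / extension 0.5 (documented
# constants; the identity threshold, not the aligner, is the contract).
.globalIdentity <- function(a, b) {
  alpha <- Biostrings::AA_ALPHABET
  subMat <- diag(1, length(alpha))
  dimnames(subMat) <- list(alpha, alpha)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = subMat, gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Remove redundant library entries at a sequence-identity threshold
#'
#' Greedy selection in input order: an entry is kept iff its global
#' pairwise identity to every already-kept entry is below the threshold.
#' Order-dependent by design; deterministic for a fixed input order.
#'
#' @param entries data.frame with a \code{sequence} column (as from
#'   [extractEntries()]).
#' @param idThreshold identity threshold in [0, 1] (default 0.4, i.e. 40%).
#' @return the kept subset of \code{entries}, original order preserved.
#' @export
nonredundant <- function(entries, idThreshold = 0.4) {
  if (!nrow(entries)) stop("at least one entry is required")
  keep <- integer(0)
  for (k in seq_len(nrow(entries))) {
    redundant <- FALSE
    for (j in keep) {
      if (.globalIdentity(entries$sequence[k], entries$sequence[j]) >=
          idThreshold) { redundant <- TRUE; break }
    }
    if (!redundant) keep <- c(keep, k)
  }
  entries[keep, , drop = FALSE]
}

#' Cluster library entries from a pairwise Z-score matrix
#'
#' Builds the graph with an edge wherever \code{Z >= zCut} and partitions
#' the entries into its connected components — a deterministic version of
#' threshold-based similarity clustering (membership, not layout, is the
#' contract). Singleton components are allowed.
#'
#' @param z square symmetric numeric matrix of pairwise Z-scores; the
#'   diagonal is ignored.
#' @param zCut edge threshold (default 4.5).
#' @param ids entry identifiers; default rownames(z) or seq_len(n).
#' @return a [SimilarityGraph-class] with the component membership.
#' @export
clusterZ <- function(z, zCut = 4.5, ids = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (ncol(z) != n) stop("Z matrix must be square")
  if (n && max(abs(z - t(z)), na.rm = TRUE) > 1e-6)
    stop("Z matrix asymmetric beyond tolerance (1e-6)")
  if (is.null(ids)) ids <- rownames(z)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  adj <- (z + t(z)) / 2 >= zCut
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- as.integer(igraph::components(g)$membership)
  new("SimilarityGraph", ids = as.character(ids), z = (z + t(z)) / 2,
      zCut = zCut, membership = memb)
}

#' Component membership of a SimilarityGraph as a data.frame
#' @param graph a [SimilarityGraph-class].
#' @return data.frame with columns \code{id}, \code{component}.
#' @export
clusterMembers <- function(graph) {
  data.frame(id = graph@ids, component = graph@membership,
             stringsAsFactors = FALSE)
}
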