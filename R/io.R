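#' Construct a ContactMap
#'
#' Canonicalises pairs so that \code{i < j}, drops self-pairs is an error,
#' and collapses duplicate pairs keeping the maximum score, matching the
#' behaviour of [readCaspRR()].
#'
#' @param L chain length (positive integer).
#' @param i,j integer residue indices (1-based).
#' @param score numeric scores in [0, 1]; defaults to 1 for every pair.
#' @return a [ContactMap-class].
#' @examples
#' ContactMap(10, i = c(2, 5), j = c(5, 7), score = c(0.9, 0.4))
#' @export
ContactMap <- function(L, i = integer(), j = integer(),
                       score = rep(1, length(i))) {
  L <- as.integer(L)
  i <- as.integer(i); j <- as.integer(j); score <- as.numeric(score)
  if (length(i) != length(j) || length(i) != length(score))
    stop("i, j, score must have equal length")
  if (any(i == j)) stop("self-contacts (i == j) are not allowed")
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  ct <- data.frame(i = i, j = j, score = score)
  if (nrow(ct)) {
    # collapse duplicates keeping the maximum score
    key <- paste(ct$i, ct$j)
    if (anyDuplicated(key)) {
      mx <- tapply(ct$score, key, max)
      ct <- ct[!duplicated(key), , drop = FALSE]
      ct$score <- as.numeric(mx[paste(ct$i, ct$j)])
    }
    ct <- ct[order(ct$i, ct$j), , drop = FALSE]
    rownames(ct) <- NULL
  }
  new("ContactMap", L = L, contacts = ct)
}

#' Construct a TopologyProfile from a label string or vector
#' @param labels per-residue labels over \{i, o, M, S\}; a single string or a
#'   character vector of single characters.
#' @return a [TopologyProfile-class].
#' @export
TopologyProfile <- function(labels) {
  if (length(labels) > 1L) labels <- paste(labels, collapse = "")
  new("TopologyProfile", labels = labels)
}

#' Construct an SSProfile
#' @param states per-residue states over \{H, E, C\}; string or vector.
#' @param conf optional L x 3 confidence matrix (columns coil, helix, strand).
#' @return an [SSProfile-class].
#' @export
SSProfile <- function(states, conf = NULL) {
  if (length(states) > 1L) states <- paste(states, collapse = "")
  if (is.null(conf)) conf <- matrix(numeric(), 0L, 3L,
                                    dimnames = list(NULL, c("C", "H", "E")))
  new("SSProfile", states = states, conf = conf)
}

#' Construct a StructureModel
#' @param resno residue numbers (strictly increasing).
#' @param aa one-letter amino-acid codes.
#' @param ca n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param cb n x 3 matrix of C-beta coordinates; rows of NA where absent
#'   (e.g. glycine). Defaults to all-NA.
#' @return a [StructureModel-class].
#' @export
StructureModel <- function(resno, aa, ca, cb = NULL) {
  n <- length(resno)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3L)
  new("StructureModel", resno = as.integer(resno), aa = as.character(aa),
      ca = unname(as.matrix(ca)), cb = unname(as.matrix(cb)))
}

#' C-beta coordinates with C-alpha fallback
#'
#' Returns per-residue coordinates used for contact evaluation: the C-beta
#' atom where present, otherwise the C-alpha (standard convention for
#' glycine and incomplete residues).
#'
#' @param model a [StructureModel-class].
#' @return n x 3 numeric matrix.
#' @export
effectiveCB <- function(model) {
  xyz <- model@cb
  miss <- is.na(xyz[, 1])
  if (any(miss)) xyz[miss, ] <- model@ca[miss, , drop = FALSE]
  xyz
}

#' Maximal-run segmentation of a topology profile
#'
#' @param topology a [TopologyProfile-class].
#' @return data.frame with columns \code{start}, \code{end}, \code{label};
#'   segments tile 1..L without gaps or overlaps.
#' @export
topoSegments <- function(topology) {
  v <- strsplit(topology@labels, "")[[1]]
  r <- rle(v)
  end <- cumsum(r$lengths)
  data.frame(start = c(1L, head(end, -1L) + 1L), end = as.integer(end),
             label = r$values, stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::AAStringSet] with one entry per record, order
#'   preserved. Residues are restricted to the 20 standard one-letter codes
#'   plus X; anything else is a format error naming the offending record.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("FASTA format error: empty file")
  # validate residues from the raw text first: the XStringSet reader
  # silently sanitises letters outside its alphabet
  lines <- readLines(path)
  rec <- cumsum(startsWith(lines, ">"))
  headers <- sub("^>\\s*", "", lines[startsWith(lines, ">")])
  body <- split(lines[!startsWith(lines, ">")], rec[!startsWith(lines, ">")])
  for (k in seq_along(body)) {
    resid <- strsplit(gsub("[[:space:]]", "", paste(body[[k]], collapse = "")),
                      "")[[1]]
    bad <- setdiff(toupper(resid), .AA_ALPHABET)
    if (length(bad))
      stop(sprintf("FASTA format error in record '%s': invalid residue(s) %s",
                   headers[k], paste(unique(bad), collapse = ", ")))
  }
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("FASTA format error: ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA format error: no records")
  seqs
}

#' Read a CASP-RR contact prediction file
#'
#' Parses the standard CASP RR dialect: one contact per line as
#' \code{i j d_low d_high score} (the two distance columns are read and
#' ignored). Header/footer lines (\code{PFRMAT}, \code{TARGET},
#' \code{MODEL}, \code{REMARK}, \code{END}) and embedded sequence lines are
#' skipped. Pairs are canonicalised to \code{i < j}; duplicate pairs keep
#' the maximum score.
#'
#' @param path RR text file.
#' @param L chain length; indices outside [1, L] are a format error.
#' @return a [ContactMap-class].
#' @export
readCaspRR <- function(path, L) {
  if (!file.exists(path)) stop("file not found: ", path)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  skip <- grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)", lines) |
    grepl("^[A-Za-z]+$", lines)  # bare sequence lines
  lines <- lines[!skip]
  i <- integer(0); j <- integer(0); sc <- numeric(0)
  if (length(lines)) {
    tok <- strsplit(lines, "[[:space:]]+")
    nf <- lengths(tok)
    if (any(nf < 3L)) stop("RR format error: line with fewer than 3 fields")
    i <- suppressWarnings(as.integer(vapply(tok, `[`, "", 1L)))
    j <- suppressWarnings(as.integer(vapply(tok, `[`, "", 2L)))
    sc <- suppressWarnings(as.numeric(mapply(function(t, n) t[n], tok, nf)))
    if (any(is.na(i)) || any(is.na(j)) || any(is.na(sc)))
      stop("RR format error: non-numeric contact fields")
    if (any(i < 1L) || any(j < 1L) || any(i > L) || any(j > L))
      stop(sprintf("RR format error: residue index outside [1, %d]", L))
    if (any(sc < 0 | sc > 1))
      stop("RR format error: score outside [0, 1]")
  }
  ContactMap(L, i, j, sc)
}

#' Write a ContactMap in CASP-RR format
#'
#' Scores are written with 6 decimals, so write-then-read round-trips
#' exactly to that precision.
#'
#' @param map a [ContactMap-class].
#' @param path output file.
#' @param dLow,dHigh distance bounds written in columns 3-4 (ignored on read).
#' @return invisibly, the path.
#' @export
writeCaspRR <- function(map, path, dLow = 0, dHigh = 8) {
  ct <- map@contacts
  lines <- c("PFRMAT RR",
             sprintf("%d %d %g %g %.6f", ct$i, ct$j, dLow, dHigh, ct$score),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PSIPRED ss2 (VFORMAT) file
#'
#' @param path ss2 file: a comment header, then one row per residue of
#'   \code{index aa state conf_C conf_H conf_E}.
#' @return an [SSProfile-class] with states and confidence triples.
#' @export
readSS2 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("ss2 format error: no data rows")
  tok <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(tok) < 6L)) stop("ss2 format error: row with fewer than 6 fields")
  idx <- as.integer(vapply(tok, `[`, "", 1L))
  if (any(is.na(idx)) || any(idx != seq_along(idx)))
    stop("ss2 format error: residue indices must run 1..L")
  states <- vapply(tok, `[`, "", 3L)
  conf <- cbind(C = as.numeric(vapply(tok, `[`, "", 4L)),
                H = as.numeric(vapply(tok, `[`, "", 5L)),
                E = as.numeric(vapply(tok, `[`, "", 6L)))
  # psipred confidences are rounded to 3 decimals; renormalise drift
  conf <- conf / rowSums(conf)
  SSProfile(states, conf)
}

#' Read a TOPCONS-style per-residue topology string
#'
#' Concatenates all non-empty, non-comment lines of the file into one label
#' string over \{i, o, M, S\}.
#'
#' @param path text file holding the topology string.
#' @return a [TopologyProfile-class].
#' @export
readTopcons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ">")]
  if (!length(lines)) stop("topology format error: no topology string found")
  TopologyProfile(paste(lines, collapse = ""))
}

#' Read a PDB coordinate file into a StructureModel
#'
#' Reads ATOM records via \pkg{bio3d}, keeps one chain, and reduces each
#' residue to its C-alpha / C-beta pair. Residues without a C-alpha are
#' excluded with a warning; missing C-beta (glycine) is recorded as NA and
#' falls back to C-alpha in [effectiveCB()].
#'
#' @param path PDB file.
#' @param chain chain identifier; default the first chain in the file.
#' @return a [StructureModel-class].
#' @export
readPDBModel <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("PDB format error: no ATOM records")
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain, "' not found")
  ca <- at[at$elety == "CA", , drop = FALSE]
  cb <- at[at$elety == "CB", , drop = FALSE]
  resno <- sort(unique(at$resno))
  noCA <- setdiff(resno, ca$resno)
  if (length(noCA)) {
    warning("residues without C-alpha excluded: ", paste(noCA, collapse = ", "))
    resno <- setdiff(resno, noCA)
  }
  ca <- ca[match(resno, ca$resno), , drop = FALSE]
  cbm <- matrix(NA_real_, length(resno), 3L)
  hit <- match(resno, cb$resno)
  ok <- !is.na(hit)
  cbm[ok, ] <- as.matrix(cb[hit[ok], c("x", "y", "z")])
  aa3 <- ca$resid
  aa1 <- vapply(aa3, function(r) {
    a <- suppressWarnings(bio3d::aa321(r))
    if (is.na(a)) "X" else a
  }, "")
  StructureModel(resno = resno, aa = aa1,
                 ca = as.matrix(ca[, c("x", "y", "z")]), cb = cbm)
}

# PDBTM single-letter region codes -> package region vocabulary
.PDBTM_CODE_MAP <- c(
  "H" = "tm_helix", "B" = "tm_strand", "L" = "reentrant",
  "1" = "side1", "2" = "side2", "F" = "interfacial",
  "C" = "coil", "I" = "inside", "U" = "unknown")

#' Read PDBTM-style XML region annotations
#'
#' Parses the minimal PDBTM XML subset: per-chain \code{REGION} elements
#' with \code{seq_beg}, \code{seq_end} and a one-letter \code{type}. Codes
#' are mapped to the package vocabulary (membrane re-entrant loops default
#' to code \code{L}); unknown codes produce a warning and are preserved
#' verbatim.
#'
#' @param path XML file.
#' @param reentrantCode the XML code treated as a re-entrant loop
#'   (configurable because dialects differ); default \code{"L"}.
#' @return list of [RegionAnnotation-class], chain order preserved.
#' @export
readPDBTMRegions <- function(path, reentrantCode = "L") {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("PDBTM XML format error: ",
                                           conditionMessage(e)))
  chains <- xml2::xml_find_all(doc, ".//*[local-name() = 'CHAIN']")
  codeMap <- .PDBTM_CODE_MAP
  codeMap[reentrantCode] <- "reentrant"
  lapply(chains, function(ch) {
    cid <- xml2::xml_attr(ch, "CHAINID")
    regs <- xml2::xml_find_all(ch, ".//*[local-name() = 'REGION']")
    start <- as.integer(xml2::xml_attr(regs, "seq_beg"))
    end <- as.integer(xml2::xml_attr(regs, "seq_end"))
    type <- xml2::xml_attr(regs, "type")
    code <- unname(codeMap[type])
    unknown <- is.na(code)
    if (any(unknown)) {
      warning("unknown PDBTM region code(s) preserved verbatim: ",
              paste(unique(type[unknown]), collapse = ", "))
      code[unknown] <- type[unknown]
    }
    new("RegionAnnotation", chain = cid,
        regions = data.frame(start = start, end = end, code = code,
                             stringsAsFactors = FALSE))
  })
}
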