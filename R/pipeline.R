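# End-to-end orchestration: boundaries -> repeat test -> re-entrant
# candidates -> amphipathic windows -> optional model validation, with one
# JSON report per stage and a summary of the inferred architecture. Every
# report embeds the seed, the package version and a hash of the resolved
# configuration.

.CONFIG_KEYS <- c("fasta", "rr", "ss2", "topology", "pdb", "outDir", "seed",
                  "nTop", "bandwidth", "margin", "nPerm", "deltaMax",
                  "topFactor", "minBreak", "maxBreak", "minLimb", "window",
                  "dCut", "sMin")

.CONFIG_DEFAULTS <- list(bandwidth = 3, margin = 10L, nPerm = 199L,
                         deltaMax = 10L, topFactor = 1.5, minBreak = 2L,
                         maxBreak = 8L, minLimb = 4L, window = 15L,
                         dCut = 8.0, sMin = 5L)

#' Read a flat key = value pipeline configuration file
#'
#' One \code{key = value} pair per line; blank lines and \code{#} comments
#' ignored. Unknown keys are rejected. Numeric-looking values are coerced.
#'
#' @param path config file.
#' @return named list suitable for [runPipeline()].
#' @export
readConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("config format error: expected key = value")
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.stamp <- function(report, config, hash) {
  report$provenance <- list(seed = config$seed, configHash = hash,
                            package = "memscope",
                            version = as.character(utils::packageVersion("memscope")))
  report
}

#' Run the full contact-map architecture analysis
#'
#' Stages, each writing \code{<outDir>/<stage>.json}:
#' \enumerate{
#'   \item \code{boundaries}: contact-density minima ([densityProfile()]).
#'   \item \code{repeats}: tandem-repeat test at the boundary candidates
#'     ([detectRepeat()]).
#'   \item \code{reentrant}: broken-TM candidates with packing scores
#'     ([findReentrant()]).
#'   \item \code{amphipathic}: moments of the windows preceding each
#'     candidate ([windowsBeforeReentrants()]).
#'   \item \code{validate} (only when \code{pdb} is configured): top-L
#'     contact satisfaction ([topLPrecision()]).
#' }
#' plus \code{summary.json} describing the inferred architecture (element
#' order and, for re-entrant candidates, the membrane side they enter
#' from). A stage failure is recorded in the bundle's \code{errors} and the
#' remaining stages still run where their inputs allow.
#'
#' @param config named list (or [readConfig()] output): input paths
#'   \code{fasta}, \code{rr}, \code{ss2}, \code{topology}, optional
#'   \code{pdb}; \code{outDir}; \code{seed}; stage parameters as in the
#'   individual functions. Unknown keys are rejected.
#' @return invisibly, the report bundle (named list, one element per stage,
#'   plus \code{summary} and \code{errors}).
#' @export
runPipeline <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(.CONFIG_DEFAULTS))
    if (is.null(config[[k]])) config[[k]] <- .CONFIG_DEFAULTS[[k]]
  for (k in c("fasta", "rr", "ss2", "topology", "outDir", "seed"))
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  config$seed <- as.integer(config$seed)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)

  bundle <- list(errors = list())
  fail <- function(stage, e) {
    bundle$errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  emit <- function(stage, report) {
    report <- .stamp(report, config, hash)
    jsonlite::write_json(report, file.path(config$outDir,
                                           paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle[[stage]] <<- report
    report
  }

  seqs <- readFasta(config$fasta)
  sequence <- as.character(seqs[[1]])
  L <- nchar(sequence)
  map <- readCaspRR(config$rr, L)
  ss <- readSS2(config$ss2)
  topo <- readTopcons(config$topology)
  if (chainLength(ss) != L || chainLength(topo) != L)
    stop("inputs disagree in chain length")
  if (is.null(config$nTop)) config$nTop <- L

  bres <- tryCatch({
    r <- densityProfile(map, nTop = config$nTop, bandwidth = config$bandwidth,
                        margin = config$margin)
    emit("boundaries", list(minima = r@minima, profile = r@profile,
                            params = r@params))
    r
  }, error = function(e) fail("boundaries", e))

  repHit <- tryCatch({
    splits <- if (!is.null(bres) && length(bres@minima))
      utils::head(bres@minima, 3L) else as.integer(round(L / 2))
    h <- detectRepeat(selectTop(map, min(config$nTop, nrow(map@contacts))),
                      splits = splits, nPerm = config$nPerm,
                      seed = config$seed, deltaMax = config$deltaMax,
                      topFactor = config$topFactor)
    emit("repeats", list(split = h@split, offset = h@offset,
                         score = h@score, pValue = h@pValue,
                         nPerm = h@nPerm, nCross = h@nCross))
    h
  }, error = function(e) fail("repeats", e))

  cand <- tryCatch({
    cd <- findReentrant(map, topo, ss, minBreak = config$minBreak,
                        maxBreak = config$maxBreak, minLimb = config$minLimb)
    emit("reentrant", list(candidates = cd))
    cd
  }, error = function(e) fail("reentrant", e))

  amph <- tryCatch({
    w <- if (!is.null(cand) && nrow(cand))
      windowsBeforeReentrants(sequence, cand, w = config$window)
    else windowsBeforeReentrants(sequence, .emptyCandidates(),
                                 w = config$window)
    emit("amphipathic", list(windows = w))
    w
  }, error = function(e) fail("amphipathic", e))

  if (!is.null(config$pdb)) {
    tryCatch({
      model <- readPDBModel(config$pdb)
      pr <- topLPrecision(map, model, n = config$nTop,
                          dCut = config$dCut, sMin = config$sMin)
      emit("validate", list(nConsidered = pr@nConsidered,
                            nSatisfied = pr@nSatisfied,
                            fraction = pr@fraction,
                            dCut = pr@dCut, sMin = pr@sMin))
    }, error = function(e) fail("validate", e))
  }

  # architecture summary: membrane side each candidate hairpin enters from
  labels <- strsplit(topo@labels, "")[[1]]
  reentrantSides <- if (!is.null(cand) && nrow(cand)) {
    vapply(seq_len(nrow(cand)), function(k) {
      pre <- cand$segStart[k] - 1L
      if (pre >= 1L && labels[pre] %in% c("i", "o")) labels[pre] else "?"
    }, "")
  } else character(0)
  summary <- list(
    L = L,
    nBoundaries = if (is.null(bres)) NA else length(bres@minima),
    boundaries = if (is.null(bres)) integer(0) else bres@minima,
    repeatSignificant = if (is.null(repHit)) NA else repHit@pValue <= 0.05,
    repeatP = if (is.null(repHit)) NA else repHit@pValue,
    nReentrant = if (is.null(cand)) NA else nrow(cand),
    reentrantSides = reentrantSides,
    invertedTopology = length(unique(reentrantSides[reentrantSides != "?"])) > 1L,
    nAmphipathicWindows = if (is.null(amph)) NA else nrow(amph),
    amphipathicMuH = if (is.null(amph)) numeric(0) else amph$muH,
    nErrors = length(bundle$errors))
  emit("summary", summary)
  if (length(bundle$errors))
    warning("pipeline completed with stage errors: ",
            paste(names(bundle$errors), collapse = ", "))
  invisible(bundle)
}
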