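.annot <- function(chain, ...) {
  regs <- do.call(rbind, lapply(list(...), function(r)
    data.frame(start = r[[1]], end = r[[2]], code = r[[3]],
               stringsAsFactors = FALSE)))
  new("RegionAnnotation", chain = chain, regions = regs)
}

.chainModel <- function(n, seed = 1) {
  set.seed(seed)
  ca <- matrix(cumsum(rnorm(3 * n, sd = 2)), n, 3)
  StructureModel(1:n, sample(c("A", "L", "S", "K", "F"), n, TRUE), ca, ca)
}

test_that("library entries extend loops by the preceding pad, clipped", {
  models <- list(A = .chainModel(80), B = .chainModel(60, seed = 2))
  ann <- list(.annot("A", list(40, 52, "reentrant")),
              .annot("B", list(12, 20, "reentrant"), list(35, 44, "reentrant")))
  ent <- extractEntries(ann, models, pad = 30)
  expect_equal(nrow(ent), 3L)
  expect_equal(ent$extStart, c(10L, 1L, 5L))   # second entry clipped at 1
  expect_equal(ent$extEnd, c(52L, 20L, 44L))
  expect_equal(nchar(ent$sequence), ent$extEnd - ent$extStart + 1L)
  expect_true(all(ent$complete))
  # fragment coordinates span the extended interval
  expect_equal(ent$coords[[1]]@resno, 10:52)

  # missing residues in the extended interval are flagged, not dropped
  short <- models
  keep <- c(1:20, 30:80)
  short$A <- StructureModel(short$A@resno[keep], short$A@aa[keep],
                            short$A@ca[keep, ], short$A@cb[keep, ])
  ent2 <- extractEntries(ann[1], short, pad = 30)
  expect_false(ent2$complete)

  expect_error(extractEntries(list(.annot("Z", list(1, 5, "reentrant"))),
                              models), "chain 'Z'")
  # non-re-entrant regions are ignored
  ann3 <- list(.annot("A", list(5, 15, "tm_helix")))
  expect_equal(nrow(extractEntries(ann3, models)), 0L)
})

test_that("greedy redundancy removal follows the 40% identity rule", {
  blockA <- strrep("ACDEFGHIKL", 4)
  res <- strsplit(blockA, "")[[1]]
  mutate <- function(x, idx) {
    swap <- c(A = "M", C = "W", D = "R", E = "V", F = "Y",
              G = "P", H = "T", I = "N", K = "Q", L = "S")
    x[idx] <- unname(swap[x[idx]])
    paste(x, collapse = "")
  }
  odd <- seq(1, 40, by = 2); even <- seq(2, 40, by = 2)
  seqB <- mutate(res, odd)                      # 50% identical to A
  seqC <- mutate(strsplit(seqB, "")[[1]], even) # 50% to B, 0% to A
  entries <- data.frame(sourceId = c("A", "B", "C"),
                        sequence = c(blockA, seqB, seqC),
                        stringsAsFactors = FALSE)
  kept <- nonredundant(entries, idThreshold = 0.4)
  expect_equal(kept$sourceId, c("A", "C"))

  # identical pair collapses; unrelated pair survives
  two <- data.frame(sourceId = c("x", "y"),
                    sequence = c(blockA, blockA), stringsAsFactors = FALSE)
  expect_equal(nrow(nonredundant(two)), 1L)
  unrel <- data.frame(sourceId = c("x", "y"),
                      sequence = c(blockA, seqC), stringsAsFactors = FALSE)
  expect_equal(nrow(nonredundant(unrel)), 2L)

  # deterministic for fixed input order
  expect_identical(nonredundant(entries), nonredundant(entries))
  expect_error(nonredundant(entries[0, ]), "at least one")
})

test_that("threshold clustering yields hand-computed components", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  z["a", "b"] <- z["b", "a"] <- 6.0
  z["c", "d"] <- z["d", "c"] <- 5.0
  g <- clusterZ(z, zCut = 4.5)
  memb <- clusterMembers(g)
  expect_equal(memb$component[memb$id == "a"], memb$component[memb$id == "b"])
  expect_equal(memb$component[memb$id == "c"], memb$component[memb$id == "d"])
  expect_false(memb$component[1] == memb$component[3])
  expect_equal(length(unique(memb$component)), 2L)

  # clique merges into one component; over-threshold cut isolates everything
  zAll <- matrix(10, 4, 4)
  expect_equal(length(unique(clusterZ(zAll, 4.5)@membership)), 1L)
  expect_equal(length(unique(clusterZ(z, zCut = 7)@membership)), 4L)

  zBad <- z; zBad[1, 2] <- 9
  expect_error(clusterZ(zBad, 4.5), "asymmetric")
})

test_that("raising the cut-off only refines the partition", {
  set.seed(99)
  n <- 12
  z <- matrix(runif(n * n, 0, 8), n, n)
  z <- (z + t(z)) / 2
  cuts <- c(1, 2.5, 4.5, 6, 7.5)
  prev <- NULL
  for (zc in cuts) {
    memb <- clusterZ(z, zCut = zc)@membership
    if (!is.null(prev)) {
      # every cluster at the higher cut lies inside one cluster at the lower
      for (cl in unique(memb)) {
        expect_equal(length(unique(prev[memb == cl])), 1L)
      }
    }
    prev <- memb
  }
})
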