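test_that("building the same spec twice is byte-identical", {
  spec <- exampleSpec("deda", pTP = 0.85, seed = 11)
  a <- buildProtein(spec)
  b <- buildProtein(spec)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # different noise seed changes only the noisy map
  c <- buildProtein(exampleSpec("deda", pTP = 0.85, seed = 12))
  expect_identical(a@trueMap, c@trueMap)
  expect_false(identical(a@noisyMap, c@noisyMap))
})

test_that("bundle topology alternates sides and truth labels are consistent", {
  sp <- buildProtein(exampleSpec("bundle4", pTP = 1, nFP = 0))
  seg <- topoSegments(sp@topology)
  mSeg <- seg[seg$label == "M", ]
  expect_equal(nrow(mSeg), 4L)
  # loops alternate i / o between consecutive TM helices
  nonM <- seg$label[seg$label != "M"]
  expect_equal(nonM, c("o", "i", "o", "i"))
  # element truth matches the topology segmentation
  el <- sp@truth$elements
  tmEl <- el[el$kind == "tm", ]
  expect_equal(tmEl$start, mSeg$start)
  expect_equal(tmEl$end, mSeg$end)
  expect_null(sp@truth$reentrant)
})

test_that("tiny element lists are rejected", {
  expect_error(buildProtein(syntheticSpec(rbind(element("tm", 20)))),
               "L < 30")
  expect_error(element("tm", 2), ">= 3")
})

test_that("packed helix pairs show the expected orientation correlations", {
  # independent geometry: two antiparallel helices 9.5 A apart
  n <- 20
  h1 <- testHelix(n, c(0, 0, -15), zdir = 1)
  h2 <- testHelix(n, c(9.5, 0, 15), zdir = -1)
  model <- StructureModel(1:(2 * n + 10), rep("L", 2 * n + 10),
                          rbind(h1$ca, matrix(500, 10, 3), h2$ca),
                          rbind(h1$cb, matrix(500, 10, 3), h2$cb))
  mc <- modelContacts(model)
  ct <- mc@contacts
  inter <- ct[ct$i <= n & ct$j > n + 10, ]
  expect_gt(nrow(inter), 3)
  expect_lt(cor(inter$i, inter$j, method = "spearman"), -0.5)

  # parallel pair: positive rank correlation
  h3 <- testHelix(n, c(9.5, 0, -15), zdir = 1)
  model2 <- StructureModel(1:(2 * n + 10), rep("L", 2 * n + 10),
                           rbind(h1$ca, matrix(500, 10, 3), h3$ca),
                           rbind(h1$cb, matrix(500, 10, 3), h3$cb))
  ct2 <- modelContacts(model2)@contacts
  inter2 <- ct2[ct2$i <= n & ct2$j > n + 10, ]
  expect_gt(nrow(inter2), 3)
  expect_gt(cor(inter2$i, inter2$j, method = "spearman"), 0.5)

  # the generator's own adjacent TM helices are antiparallel
  sp <- buildProtein(exampleSpec("bundle4", pTP = 1, nFP = 0))
  el <- sp@truth$elements
  tm <- el[el$kind == "tm", ]
  ct3 <- contacts(sp)
  pair <- ct3[ct3$i >= tm$start[1] & ct3$i <= tm$end[1] &
                ct3$j >= tm$start[2] & ct3$j <= tm$end[2], ]
  expect_gt(nrow(pair), 3)
  expect_lt(cor(pair$i, pair$j, method = "spearman"), -0.5)
})

test_that("the true map matches the package contact definition", {
  sp <- buildProtein(exampleSpec("deda", pTP = 1, nFP = 0))
  expect_identical(sp@trueMap, modelContacts(sp@model, dCut = 8, sMin = 5))
  expect_identical(sp@noisyMap, sp@trueMap)  # no noise requested
})

test_that("corruptMap retention follows the binomial expectation", {
  sp <- buildProtein(exampleSpec("deda", pTP = 1, nFP = 0))
  nTrue <- nrow(contacts(sp))
  expect_gt(nTrue, 150)

  # identity and annihilation
  expect_identical(corruptMap(sp@trueMap, 1, 0, seed = 1), sp@trueMap)
  expect_equal(nrow(corruptMap(sp@trueMap, 0, 0, seed = 1)@contacts), 0L)

  pTP <- 0.8
  kept <- vapply(1:200, function(s) {
    m <- corruptMap(sp@trueMap, pTP, nFP = 0, seed = s)
    nrow(m@contacts)
  }, 0L)
  expval <- pTP * nTrue
  se <- sqrt(nTrue * pTP * (1 - pTP) / 200)
  expect_lt(abs(mean(kept) - expval), 4 * se)

  # false positives never collide with true contacts and respect |i-j| >= 5
  m <- corruptMap(sp@trueMap, 0, nFP = 50, seed = 3)
  expect_equal(nrow(m@contacts), 50L)
  expect_true(all(m@contacts$j - m@contacts$i >= 5))
  trueKey <- paste(contacts(sp)$i, contacts(sp)$j)
  expect_false(any(paste(m@contacts$i, m@contacts$j) %in% trueKey))

  # determinism per seed
  expect_identical(corruptMap(sp@trueMap, 0.7, 20, seed = 9),
                   corruptMap(sp@trueMap, 0.7, 20, seed = 9))
  small <- ContactMap(12, c(1, 2), c(7, 9), c(1, 1))
  expect_error(corruptMap(small, 1, nFP = 10000, seed = 1), "exceeds")
})

test_that("fixtures written to disk read back consistently", {
  sp <- buildProtein(exampleSpec("deda", pTP = 0.85, seed = 5))
  dir <- withr::local_tempdir()
  paths <- writeFixture(sp, dir)
  expect_true(all(file.exists(paths)))
  seqs <- readFasta(paths["fasta"])
  expect_equal(as.character(seqs[[1]]), sp@sequence)
  m <- readCaspRR(paths["rr"], chainLength(sp))
  expect_equal(m@contacts[c("i", "j")], sp@noisyMap@contacts[c("i", "j")])
  expect_equal(readTopcons(paths["topo"])@labels, sp@topology@labels)
  expect_equal(readSS2(paths["ss2"])@states, sp@ss@states)
  model <- readPDBModel(paths["pdb"])
  expect_equal(model@ca, sp@model@ca, tolerance = 1e-3)
})
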