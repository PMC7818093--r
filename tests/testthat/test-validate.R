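.lineModel <- function(d, sep = 6L) {
  # two residues at distance d, with enough spacer residues for separation
  n <- sep + 1L
  ca <- cbind(seq(0, d, length.out = n), 0, 0)
  ca[2:(n - 1), 2] <- 100  # spacers far away
  StructureModel(1:n, rep("A", n), ca, ca)
}

test_that("modelContacts applies distance and separation thresholds", {
  m <- .lineModel(7.9)
  ct <- modelContacts(m, dCut = 8, sMin = 5)@contacts
  expect_true(any(ct$i == 1 & ct$j == 7))

  m2 <- .lineModel(8.1)
  ct2 <- modelContacts(m2, dCut = 8, sMin = 5)@contacts
  expect_false(any(ct2$i == 1 & ct2$j == 7))

  # |i-j| = 4 at 5 A is excluded at sMin = 5
  ca <- cbind(c(0, 100, 100, 100, 5), c(0, 100, 200, 300, 0), 0)
  m3 <- StructureModel(1:5, rep("A", 5), ca, ca)
  expect_equal(nrow(modelContacts(m3, dCut = 8, sMin = 5)@contacts), 0L)
  expect_equal(nrow(modelContacts(m3, dCut = 8, sMin = 4)@contacts), 1L)
  expect_error(modelContacts(StructureModel(1L, "A", cbind(0, 0, 0))), "2 residues")
})

test_that("glycine falls back to C-alpha in contact evaluation", {
  ca <- cbind(c(0, 100, 100, 100, 100, 100, 7), 0, 0)
  cb <- ca; cb[, 2] <- 2
  cb[1, ] <- NA  # glycine: no C-beta
  cb[7, ] <- c(7, 0, 0)
  m <- StructureModel(1:7, c("G", rep("A", 6)), ca, cb)
  ct <- modelContacts(m, dCut = 8, sMin = 5)@contacts
  expect_true(any(ct$i == 1 & ct$j == 7))
})

test_that("topLPrecision hits the identity and annihilation cases", {
  sp <- buildProtein(exampleSpec("bundle4", pTP = 1, nFP = 0))
  pr <- topLPrecision(sp@trueMap, sp@model)
  expect_equal(pr@fraction, 1.0)
  expect_equal(pr@nConsidered, pr@nSatisfied)

  # a model with no contacts satisfies nothing
  n <- chainLength(sp)
  far <- cbind(seq(0, 100 * n, length.out = n), 0, 0)
  stretched <- StructureModel(1:n, rep("A", n), far, far)
  expect_equal(topLPrecision(sp@trueMap, stretched)@fraction, 0.0)

  expect_error(topLPrecision(ContactMap(10, 2, 8), sp@model), "length")
})

test_that("precision equals the deterministic expectation under corruption", {
  # retained true contacts outscore injected false positives, so the top-L
  # precision is min(kept, L) / L exactly, computable per seed
  sp <- buildProtein(exampleSpec("deda", pTP = 1, nFP = 0))
  L <- chainLength(sp)
  for (s in 1:5) {
    noisy <- corruptMap(sp@trueMap, pTP = 0.6, nFP = round(0.5 * L), seed = s)
    kept <- sum(noisy@contacts$score > 0.5)
    pr <- topLPrecision(noisy, sp@model, n = min(L, nrow(noisy@contacts)))
    expect_equal(pr@fraction, min(kept, L) / pr@nConsidered)
  }
})

test_that("fast contact evaluation matches a brute-force scan", {
  set.seed(202)
  for (k in 1:10) {
    n <- sample(10:50, 1)
    ca <- matrix(rnorm(3 * n, sd = 6), n, 3)
    cb <- ca + matrix(rnorm(3 * n, sd = 0.8), n, 3)
    gly <- sample(n, max(1, n %/% 10))
    cb[gly, ] <- NA
    m <- StructureModel(1:n, ifelse(seq_len(n) %in% gly, "G", "L"), ca, cb)
    fast <- modelContacts(m)@contacts
    slow <- bruteContacts(ca, cb, 1:n)
    if (is.null(slow)) {
      expect_equal(nrow(fast), 0L)
    } else {
      expect_equal(fast$i, slow[, 1])
      expect_equal(fast$j, slow[, 2])
    }
  }
})

test_that("precision is monotone in true/false additions at fixed depth", {
  sp <- buildProtein(exampleSpec("bundle4", pTP = 1, nFP = 0))
  trueCt <- contacts(sp)
  n0 <- 30L
  base <- ContactMap(chainLength(sp), trueCt$i[1:n0], trueCt$j[1:n0],
                     seq(0.9, 0.5, length.out = n0))
  f0 <- topLPrecision(base, sp@model, n = n0)@fraction
  # appending one more true contact at depth n0+1 cannot decrease precision
  withTP <- ContactMap(chainLength(sp), trueCt$i[1:(n0 + 1)],
                       trueCt$j[1:(n0 + 1)],
                       seq(0.9, 0.5, length.out = n0 + 1))
  expect_gte(topLPrecision(withTP, sp@model, n = n0 + 1)@fraction, f0)
  # appending only a non-contact pair cannot increase it
  fp <- corruptMap(sp@trueMap, 0, nFP = 1, seed = 8)@contacts
  withFP <- ContactMap(chainLength(sp), c(trueCt$i[1:n0], fp$i),
                       c(trueCt$j[1:n0], fp$j),
                       c(seq(0.9, 0.5, length.out = n0), 0.4))
  expect_lte(topLPrecision(withFP, sp@model, n = n0 + 1)@fraction, f0)
})
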