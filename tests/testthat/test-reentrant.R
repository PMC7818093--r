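.mkProfiles <- function(L, mSegs, coil = NULL) {
  topo <- rep("i", L)
  for (s in mSegs) topo[s[1]:s[2]] <- "M"
  ss <- rep("H", L)
  ss[topo == "i"] <- "C"
  if (!is.null(coil)) for (cc in coil) ss[cc[1]:cc[2]] <- "C"
  list(topo = TopologyProfile(topo), ss = SSProfile(ss))
}

test_that("findBrokenTM applies the coil-break rule exactly", {
  # M segment 20-44 with a central 2-residue coil -> candidate
  p <- .mkProfiles(60, list(c(20, 44)), coil = list(c(31, 32)))
  cand <- findBrokenTM(p$topo, p$ss)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$breakStart, cand$breakEnd), c(31L, 32L))
  expect_equal(c(cand$limb1Start, cand$limb1End), c(20L, 30L))
  expect_equal(c(cand$limb2Start, cand$limb2End), c(33L, 44L))

  # fully helical M segment: no candidate
  p2 <- .mkProfiles(60, list(c(20, 44)))
  expect_equal(nrow(findBrokenTM(p2$topo, p2$ss)), 0L)

  # coil run of 10 exceeds maxBreak
  p3 <- .mkProfiles(60, list(c(20, 44)), coil = list(c(28, 37)))
  expect_equal(nrow(findBrokenTM(p3$topo, p3$ss)), 0L)

  # two coil runs: not the single-break signature
  p4 <- .mkProfiles(60, list(c(20, 44)), coil = list(c(26, 27), c(36, 37)))
  expect_equal(nrow(findBrokenTM(p4$topo, p4$ss)), 0L)

  # break too close to the segment edge (outside the middle 50%)
  p5 <- .mkProfiles(60, list(c(20, 44)), coil = list(c(24, 25)))
  expect_equal(nrow(findBrokenTM(p5$topo, p5$ss)), 0L)

  # limb shorter than minLimb
  p6 <- .mkProfiles(60, list(c(20, 36)), coil = list(c(26, 27)))
  expect_equal(nrow(findBrokenTM(p6$topo, p6$ss, minLimb = 8)), 0L)

  expect_error(findBrokenTM(p$topo, SSProfile(strrep("H", 59))), "length")
})

test_that("packingOrientation recovers perfect orientations and support rule", {
  m <- ContactMap(60, c(10, 11, 12), c(40, 39, 38))
  o <- packingOrientation(m, c(8, 14), c(35, 42))
  expect_equal(o$rho, -1)
  expect_equal(o$n, 3L)

  m2 <- ContactMap(60, c(10, 11, 12), c(38, 39, 40))
  o2 <- packingOrientation(m2, c(8, 14), c(35, 42))
  expect_equal(o2$rho, 1)

  # support below 3: rho undefined
  m3 <- ContactMap(60, c(10, 11), c(40, 39))
  o3 <- packingOrientation(m3, c(8, 14), c(35, 42))
  expect_true(is.na(o3$rho))
  expect_equal(o3$n, 2L)

  # symmetric in the segment arguments
  oS <- packingOrientation(m, c(35, 42), c(8, 14))
  expect_equal(oS$rho, o$rho)
  expect_equal(oS$n, o$n)

  expect_error(packingOrientation(m, c(8, 14), c(12, 20)), "disjoint")
})

test_that("perfect anti/parallel packing yields composite score 1", {
  # partner helix 10-20 precedes candidate segment 30-50 (break 39-41)
  p <- .mkProfiles(60, list(c(10, 20), c(30, 50)), coil = list(c(39, 41)))
  cand <- findBrokenTM(p$topo, p$ss)
  expect_equal(nrow(cand), 1L)
  # limb1 (30-38) antiparallel to partner, limb2 (42-50) parallel
  m <- ContactMap(60,
                  i = c(12, 13, 14, 12, 13, 14),
                  j = c(37, 36, 35, 43, 44, 45),
                  score = rep(1, 6))
  scored <- scoreReentrant(cand, m, p$topo)
  expect_equal(scored$score, 1.0)
  expect_equal(scored$rho1, -1)
  expect_equal(scored$rho2, 1)
  expect_equal(c(scored$partnerStart, scored$partnerEnd), c(10L, 20L))

  # no flanking helix: geometric component only, with a warning
  pLone <- .mkProfiles(60, list(c(30, 50)), coil = list(c(39, 41)))
  candLone <- findBrokenTM(pLone$topo, pLone$ss)
  expect_warning(sLone <- scoreReentrant(candLone, m, pLone$topo),
                 "no flanking")
  expect_equal(sLone$score, 0.4)
})

test_that("planted hairpins are recovered and clean bundles give none", {
  sp <- buildProtein(exampleSpec("deda", pTP = 1, nFP = 0))
  tr <- sp@truth$reentrant
  expect_equal(nrow(tr), 2L)
  noisy <- corruptMap(sp@trueMap, pTP = 0.85,
                      nFP = round(0.2 * chainLength(sp)), seed = 31)
  cand <- findReentrant(noisy, sp@topology, sp@ss)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$segStart, tr$start)
  # detected break equals the planted turn
  m <- match(cand$segStart, tr$start)
  expect_equal(cand$breakStart, tr$turnStart[m])
  expect_equal(cand$breakEnd, tr$turnEnd[m])
  # the hairpin packs antiparallel against its following TM partner:
  # the anti limb is limb2, so the packing component is positive
  expect_true(all(cand$score > 0.4))

  spNeg <- buildProtein(exampleSpec("bundle4", pTP = 0.85, seed = 3))
  expect_equal(nrow(findReentrant(spNeg@noisyMap, spNeg@topology, spNeg@ss)),
               0L)
})
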