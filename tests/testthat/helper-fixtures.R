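# Shared test helpers: small generators used across test files.

# uniform random contact map: n distinct pairs with |i - j| >= 5
randomNullMap <- function(L, n, seed) {
  set.seed(seed)
  cand <- which(outer(seq_len(L), seq_len(L), function(a, b) b - a >= 5L),
                arr.ind = TRUE)
  pick <- sample(nrow(cand), n)
  ContactMap(L, cand[pick, 1], cand[pick, 2], stats::runif(n))
}

# ideal alpha-helix C-alpha/C-beta coordinates built independently of the
# package's generator: n residues from 'origin' along +/- z
testHelix <- function(n, origin, zdir = 1, caR = 2.3, cbR = 3.3) {
  t <- seq_len(n) - 1
  ang <- t * 100 * pi / 180
  ca <- cbind(origin[1] + caR * cos(ang), origin[2] + caR * sin(ang),
              origin[3] + zdir * 1.5 * t)
  cb <- cbind(origin[1] + cbR * cos(ang), origin[2] + cbR * sin(ang),
              origin[3] + zdir * 1.5 * t)
  list(ca = ca, cb = cb)
}

# independent brute-force contact scan (the oracle for modelContacts)
bruteContacts <- function(ca, cb, resno, dCut = 8, sMin = 5) {
  xyz <- cb
  miss <- is.na(xyz[, 1])
  xyz[miss, ] <- ca[miss, , drop = FALSE]
  out <- NULL
  n <- nrow(xyz)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (abs(resno[b] - resno[a]) < sMin) next
    if (sqrt(sum((xyz[a, ] - xyz[b, ])^2)) <= dCut)
      out <- rbind(out, c(a, b))
  }
  out
}

# direct complex-sum hydrophobic moment oracle with optional wheel phase
momentOracle <- function(H, deltaDeg = 100, phaseDeg = 0) {
  n <- seq_along(H) - 1
  ang <- (n * deltaDeg + phaseDeg) * pi / 180
  Mod(sum(H * exp(1i * ang))) / length(H)
}
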