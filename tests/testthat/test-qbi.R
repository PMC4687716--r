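# build a one-voxel DWIDataset with prescribed per-direction shell signal
shellDataset <- function(dirs, shellSignal, b = 1000, S0 = 1) {
  n <- nrow(dirs)
  gt <- makeGradientTable(c(0, rep(b, n)), rbind(c(0, 0, 0), dirs))
  sig <- array(c(S0, shellSignal), dim = c(1, 1, 1, n + 1))
  new("DWIDataset", signal = sig, voxelSize = rep(1, 3), affine = diag(4),
      gtab = gt)
}

test_that("SH fitting recovers known coefficient vectors", {
  dirs <- repulsionDirections(60, seed = 6)
  B <- shMatrix(dirs, 4)
  expect_equal(ncol(B), 15)
  expect_equal(ncol(shMatrix(dirs, 8)), 45)

  # constant signal on the sphere loads only the l = 0 term
  shC <- fitSH(shellDataset(dirs, rep(0.7, 60)), order = 8, lambda = 0.006)
  cC <- shC@coefs[[1]][1, 1, 1, ]
  expect_equal(cC[1], 0.7 / shMatrix(matrix(c(0, 0, 1), 1), 0)[1, 1])
  expect_lt(max(abs(cC[-1])), 1e-10)

  # exact least-squares recovery of an order-4 vector at lambda = 0
  set.seed(12)
  c0 <- rnorm(15, sd = 0.1); c0[1] <- 1
  sh0 <- fitSH(shellDataset(dirs, as.vector(B %*% c0)), order = 4,
               lambda = 0)
  expect_equal(sh0@coefs[[1]][1, 1, 1, ], c0, tolerance = 1e-8)
})

test_that("Laplace-Beltrami regularization shrinks high-order energy", {
  dirs <- repulsionDirections(60, seed = 6)
  sig <- compartmentSignal(
    makeGradientTable(c(0, rep(3000, 60)), rbind(c(0, 0, 0), dirs)),
    fiberCompartments(c(1, 1, 0)), S0 = 1)
  noisy <- addRicianNoise(sig[-1], 0.03, seed = 13)
  fit <- function(l) fitSH(shellDataset(dirs, noisy, b = 3000), order = 8,
                           lambda = l)@coefs[[1]][1, 1, 1, ]
  cReg <- fit(0.006); cFree <- fit(0)
  deg <- attr(shMatrix(dirs, 8), "degree")
  hi <- deg >= 6
  expect_lt(sum(cReg[hi]^2), sum(cFree[hi]^2))
})

test_that("SH order is reduced when a shell has few directions", {
  dirs <- repulsionDirections(20, seed = 2)
  expect_message(sh <- fitSH(shellDataset(dirs, rep(1, 20)), order = 8),
                 "order reduced")
  expect_equal(dim(sh@coefs[[1]])[4], 15)   # order 4 fits 20 directions
})

test_that("the analytic Funk-Radon transform matches great-circle integration", {
  sphere <- testSphere()
  dirs <- repulsionDirections(60, seed = 6)
  B <- shMatrix(dirs, 4)
  set.seed(21)
  c0 <- rnorm(15, sd = 0.05); c0[1] <- 2     # positive signal, no flooring
  sh <- fitSH(shellDataset(dirs, as.vector(B %*% c0)), order = 4, lambda = 0)
  odf <- frtODF(sh, sphere)
  expect_equal(odf@nNegative, 0L)

  # brute-force Funk-Radon: 720-point great-circle quadrature of the
  # continuous SH signal, for a subset of grid directions
  gcIntegral <- function(u) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    pts <- outer(cos(th), e1) + outer(sin(th), e2)
    mean(shMatrix(pts, 4) %*% c0) * 2 * pi
  }
  idx <- seq(1, nrow(sphere@vertices), by = 20)
  for (i in idx) {
    ref <- gcIntegral(sphere@vertices[i, ])
    expect_equal(odf@odf[1, 1, 1, i], ref, tolerance = 1e-3 * abs(ref))
  }
})

test_that("FRT nulls odd degrees and keeps isotropic signals constant", {
  # P_l(0) vanishes for odd l, so odd harmonics integrate to zero on every
  # great circle
  expect_equal(hydikit:::legendreP0(1), 0)
  expect_equal(hydikit:::legendreP0(3), 0)
  expect_equal(hydikit:::legendreP0(0), 1)
  expect_equal(hydikit:::legendreP0(2), -0.5)
  expect_equal(hydikit:::legendreP0(4), 0.375)

  dirs <- repulsionDirections(60, seed = 6)
  sphere <- testSphere()
  odf <- frtODF(fitSH(shellDataset(dirs, rep(0.5, 60)), order = 8), sphere)
  v <- odf@odf[1, 1, 1, ]
  expect_lt(max(v) - min(v), 1e-10 * mean(v))
})

test_that("GFA follows the normalized ODF-variation formula", {
  sphere <- testSphere()
  m <- nrow(sphere@vertices)
  mkODF <- function(vals) {
    new("ODFField", odf = array(vals, c(1, 1, 1, m)), sphere = sphere,
        mask = array(TRUE, c(1, 1, 1)), nNegative = 0L)
  }
  expect_equal(gfa(mkODF(rep(3, m)))@values[1, 1, 1], 0)
  one <- c(5, rep(0, m - 1))
  expect_equal(gfa(mkODF(one))@values[1, 1, 1], 1)

  gfaRef <- function(x)    # independent two-line evaluation
    sqrt(length(x) * sum((x - mean(x))^2) / ((length(x) - 1) * sum(x^2)))
  set.seed(30)
  for (r in 1:10) {
    x <- runif(m, 0.1, 2)
    g <- gfa(mkODF(x))@values[1, 1, 1]
    expect_equal(g, gfaRef(x), tolerance = 1e-12)
    expect_equal(gfa(mkODF(7.3 * x))@values[1, 1, 1], g, tolerance = 1e-12)
    expect_true(g >= 0 && g <= 1)
  }
})

test_that("ODF peaks land on the fiber directions", {
  sphere <- testSphere()
  dir0 <- c(1, 0.6, 0.25); dir0 <- dir0 / sqrt(sum(dir0^2))
  ph <- uniformPhantom(fiberCompartments(dir0), gridShape = c(1, 1, 1),
                       shellBvalues = 3000)
  pk <- findPeaks(frtODF(fitSH(ph$dwi), sphere))
  expect_equal(pk@nPeaks[1, 1, 1], 1L)
  expect_lt(angleDeg(pk@peakDirs[1, 1, 1, 1, ], dir0), sphere@maxEdgeDeg)

  # 90-degree crossing resolved into two peaks on the b = 4000 scheme
  cross <- uniformPhantom(tissueCompartments(10)$crossing,
                          gridShape = c(1, 1, 1),
                          shellBvalues = c(1000, 3000, 4000))
  pk2 <- findPeaks(frtODF(fitSH(cross$dwi), sphere))
  expect_equal(pk2@nPeaks[1, 1, 1], 2L)
  sep <- angleDeg(pk2@peakDirs[1, 1, 1, 1, ], pk2@peakDirs[1, 1, 1, 2, ])
  expect_lt(abs(sep - 90), sphere@maxEdgeDeg)

  # flat ODF flagged degenerate with a deterministic placeholder peak
  m <- nrow(sphere@vertices)
  flat <- new("ODFField", odf = array(1, c(1, 1, 1, m)), sphere = sphere,
              mask = array(TRUE, c(1, 1, 1)), nNegative = 0L)
  pkF <- findPeaks(flat)
  expect_true(pkF@degenerate[1, 1, 1])
  expect_equal(pkF@nPeaks[1, 1, 1], 1L)
})

test_that("QA and NQA follow the peak-minus-isotropic convention", {
  sphere <- testSphere()
  m <- nrow(sphere@vertices)
  # two hand-set ODF vectors in one volume
  v1 <- seq(1, 2, length.out = m)          # min 1, max 2
  v2 <- seq(0.5, 4, length.out = m)        # min 0.5, max 4
  odf <- new("ODFField", odf = array(c(rbind(v1, v2)), c(2, 1, 1, m)),
             sphere = sphere, mask = array(TRUE, c(2, 1, 1)),
             nNegative = 0L)
  qn <- qaNQA(findPeaks(odf))
  z0 <- 1 / max(min(v1), min(v2))          # 1 / max of the isotropic levels
  expect_equal(qn$z0, z0)
  qa1 <- z0 * (max(v1) - min(v1))
  qa2 <- z0 * (max(v2) - min(v2))
  expect_equal(qn$qa[1, 1, 1, 1], qa1, tolerance = 1e-12)
  expect_equal(qn$qa[2, 1, 1, 1], qa2, tolerance = 1e-12)
  expect_equal(qn$nqa@values[2, 1, 1], 1)  # normalization contract
  expect_equal(qn$nqa@values[1, 1, 1], qa1 / qa2, tolerance = 1e-12)
  expect_equal(max(qn$nqa@values, na.rm = TRUE), 1)

  # isotropic ODF: QA = 0 in that voxel
  iso <- new("ODFField", odf = array(c(rbind(rep(1.5, m), v2)),
             c(2, 1, 1, m)), sphere = sphere,
             mask = array(TRUE, c(2, 1, 1)), nNegative = 0L)
  qnI <- qaNQA(findPeaks(iso))
  expect_equal(qnI$qa[1, 1, 1, 1], 0, tolerance = 1e-12)

  zero <- new("ODFField", odf = array(0, c(1, 1, 1, m)), sphere = sphere,
              mask = array(TRUE, c(1, 1, 1)), nNegative = 0L)
  expect_error(qaNQA(findPeaks(zero)), "all-zero")
})
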