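test_that("SNR estimation recovers the nominal noise level per shell", {
  # nominal SNR at b = 1000: mean attenuated signal / sigma, computed from
  # the noiseless forward model
  cps <- fiberCompartments()
  noiseless <- uniformPhantom(cps, gridShape = c(10, 10, 5))
  gt <- noiseless$gtab
  meanB1000 <- mean(signalArray(noiseless$dwi)[1, 1, 1, shellIds(gt) == 1L])
  sigma <- meanB1000 / 40
  noisy <- uniformPhantom(cps, gridShape = c(10, 10, 5),
                          noiseSigma = sigma, seed = 60)
  rep0 <- estimateSNR(noisy$dwi, array(TRUE, c(10, 10, 5)))
  expect_equal(unname(rep0$shellSNR["1000"]), 40, tolerance = 0.1 * 40)
  # SNR strictly decreasing across shells on an attenuating phantom
  expect_true(all(diff(rep0$shellSNR) < 0))
  # scheme SNR is the running mean of member shells
  expect_equal(unname(rep0$schemeSNR),
               cumsum(unname(rep0$shellSNR)) / seq_along(rep0$shellSNR))

  expect_warning(estimateSNR(noiseless$dwi, array(TRUE, c(10, 10, 5))),
                 "infinite")
  oneB0 <- uniformPhantom(cps, gridShape = c(2, 1, 1), nB0 = 1)
  expect_error(estimateSNR(oneB0$dwi, array(TRUE, c(2, 1, 1))),
               "at least 2 b0")
})

test_that("Gaussian smoothing is mass-preserving and NaN-aware", {
  dims <- c(9, 9, 9)
  mask <- array(TRUE, dims)
  m <- scalarMap("x", array(2.5, dims), mask)
  expect_identical(gaussianSmooth(m, 0), m)
  sm <- gaussianSmooth(m, 3)
  expect_equal(sm@values, m@values, tolerance = 1e-12)

  # delta far enough from the borders that edge renormalization never
  # touches the kernel support
  dimsBig <- c(17, 17, 17)
  delta <- array(0, dimsBig); delta[9, 9, 9] <- 1
  sd1 <- gaussianSmooth(scalarMap("d", delta, array(TRUE, dimsBig)), 2)
  expect_equal(sum(sd1@values), 1, tolerance = 1e-6)

  # smoothing commutes with global scaling
  set.seed(61)
  r <- array(runif(prod(dims)), dims)
  s1 <- gaussianSmooth(scalarMap("r", r, mask), 3)@values
  s2 <- gaussianSmooth(scalarMap("r", 4 * r, mask), 3)@values
  expect_equal(s2, 4 * s1, tolerance = 1e-12)

  # masked voxels contribute nothing and stay NaN
  mask2 <- mask; mask2[1:3, , ] <- FALSE
  sm2 <- gaussianSmooth(scalarMap("r", r, mask2), 3)
  expect_true(all(is.nan(sm2@values[1:3, , ])))
  expect_true(all(is.finite(sm2@values[4:9, , ])))

  expect_error(gaussianSmooth(m, -1), "nonnegative")
})

test_that("BH-FDR matches the brute-force step-up rule", {
  r1 <- fdrBH(rep(0.001, 100), 0.05)
  expect_true(all(r1$reject))
  expect_equal(r1$criticalP, 0.001)
  r2 <- fdrBH(rep(0.9, 50), 0.05)
  expect_false(any(r2$reject))
  expect_equal(r2$criticalP, 0)

  r3 <- fdrBH(c(0.001, 0.01, 0.02, 0.03, 0.5), 0.05)
  expect_equal(r3$criticalP, 0.03)
  expect_equal(r3$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  bruteBH <- function(p, q) {           # O(m^2) step-up oracle
    m <- length(p); ps <- sort(p)
    crit <- 0
    for (i in m:1) {
      if (ps[i] <= i / m * q) { crit <- ps[i]; break }
    }
    list(criticalP = crit, reject = p <= crit & crit > 0)
  }
  set.seed(62)
  for (r in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- fdrBH(p, 0.05)
    ref <- bruteBH(p, 0.05)
    expect_equal(got$criticalP, ref$criticalP)
    expect_equal(got$reject, ref$reject)
  }

  # rejections monotone in q
  set.seed(63)
  p <- runif(50)^2
  rej <- sapply(c(0.01, 0.05, 0.1, 0.2), function(q) fdrBH(p, q)$reject)
  for (j in 1:3) expect_true(all(rej[, j] <= rej[, j + 1]))

  expect_error(fdrBH(numeric(0)), "empty")
  expect_error(fdrBH(c(0.5, 1.2)), "lie in")
})

test_that("voxel-wise shell regression recovers exact linear trends", {
  dims <- c(6, 6, 2)
  mask <- array(TRUE, dims)
  schemes <- rep(1:5, 3)
  ages <- rep(c(10, 15, 24), each = 5)
  maps <- lapply(schemes, function(k)
    scalarMap("FA", array(0.5 - 0.05 * k, dims), mask))
  vr <- voxelwiseShellRegression(maps, schemes, ages = ages, q = 0.05)
  expect_equal(unname(vr@slope[mask]), rep(-0.05, prod(dims)),
               tolerance = 1e-10)
  expect_true(all(vr@sigMask[mask]))
  expect_lte(vr@criticalP, 0.05)

  # voxels with missing values are excluded from testing and correction
  maps2 <- maps
  maps2[[1]]@values[1, 1, 1] <- NaN
  vr2 <- voxelwiseShellRegression(maps2, schemes, ages = ages)
  expect_false(vr2@mask[1, 1, 1])
  expect_equal(sum(vr2@mask), prod(dims) - 1)

  # pure-noise maps: the significant fraction stays near or below q
  set.seed(64)
  nullMaps <- lapply(schemes, function(k)
    scalarMap("FA", array(rnorm(prod(dims), 0.5, 0.05), dims), mask))
  vr3 <- voxelwiseShellRegression(nullMaps, schemes, ages = ages, q = 0.05)
  expect_lte(sum(vr3@sigMask) / sum(vr3@mask), 0.2)
})

test_that("ROI means equal the brute-force masked average", {
  dims <- c(5, 4, 3)
  mask <- array(TRUE, dims)
  set.seed(65)
  maps <- lapply(1:5, function(k)
    scalarMap("FA", array(runif(prod(dims)), dims), mask))
  roi <- array(FALSE, dims); roi[2:3, 2, 1:2] <- TRUE
  tr <- roiMeanTrend(maps, 1:5, roiMask = roi)
  for (k in 1:5) {
    acc <- 0; n <- 0
    for (i in 1:5) for (j in 1:4) for (l in 1:3)
      if (roi[i, j, l]) { acc <- acc + maps[[k]]@values[i, j, l]; n <- n + 1 }
    expect_equal(tr$table$mean[k], acc / n, tolerance = 1e-12)
  }

  single <- array(FALSE, dims); single[1, 1, 1] <- TRUE
  tr1 <- roiMeanTrend(maps, 1:5, roiMask = single)
  expect_equal(tr1$table$mean[3], maps[[3]]@values[1, 1, 1])

  expect_error(roiMeanTrend(maps, 1:5, roiMask = array(FALSE, dims)),
               "empty ROI")
})
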