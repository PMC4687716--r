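test_that("gradient scheme reproduces the 5-shell acquisition geometry", {
  gt <- makeGradientScheme(acquisitionSpec(), seed = 1)
  expect_equal(length(gt), 305)
  expect_equal(sum(bvalues(gt) > 0), 300)
  expect_equal(sum(shellIds(gt) == 0L), 5)
  # identical angular sampling reused on every shell
  d1 <- gradDirections(gt)[shellIds(gt) == 1L, ]
  for (s in 2:5)
    expect_identical(gradDirections(gt)[shellIds(gt) == s, ], d1)

  minimal <- makeGradientScheme(acquisitionSpec(shellBvalues = 1000,
                                                directionsPerShell = 6,
                                                nB0 = 1), seed = 2)
  expect_equal(length(minimal), 7)
  w <- shellIds(minimal) > 0
  expect_equal(sqrt(rowSums(gradDirections(minimal)[w, ]^2)), rep(1, 6))

  expect_error(acquisitionSpec(directionsPerShell = 5), "at least 6")
})

test_that("repulsion directions are quasi-uniform under a brute-force angle scan", {
  d <- repulsionDirections(60, seed = 3)
  # independent exhaustive pairwise scan over the symmetrized set
  minAngle <- 180
  for (i in 1:59) for (j in (i + 1):60) {
    a <- acos(min(1, abs(sum(d[i, ] * d[j, ])))) * 180 / pi
    minAngle <- min(minAngle, a)
  }
  G <- abs(d %*% t(d)); diag(G) <- 0
  expect_equal(minAngle, acos(min(1, max(G))) * 180 / pi, tolerance = 1e-12)
  # 60 antipodal pairs can be spread with ~18 deg separation; a collapsed or
  # clustered configuration would fall far below this
  expect_gt(minAngle, 12)
})

test_that("compartment signal follows the multi-tensor closed form", {
  gt <- makeGradientScheme(acquisitionSpec(), seed = 1)
  iso <- list(compartmentSpec(rep(1e-3, 3), 1))
  s <- compartmentSignal(gt, iso, S0 = 100)
  expect_equal(s[shellIds(gt) == 0L], rep(100, 5))
  for (sh in 1:5) {
    b <- c(1000, 3000, 4000, 8000, 12000)[sh]
    expect_equal(s[shellIds(gt) == sh], rep(100 * exp(-b * 1e-3), 60))
  }
  # two-compartment mixture at b = 3000, hand evaluation of the closed form
  two <- list(compartmentSpec(rep(2e-3, 3), 0.5),
              compartmentSpec(rep(0.2e-3, 3), 0.5))
  s2 <- compartmentSignal(gt, two, S0 = 1)
  expected <- 0.5 * exp(-3000 * 2e-3) + 0.5 * exp(-3000 * 0.2e-3)
  expect_equal(unique(round(s2[shellIds(gt) == 2L], 14)), round(expected, 14))

  expect_error(compartmentSignal(gt, list(compartmentSpec(rep(1e-3, 3), 0.5)),
                                 1), "sum to 1")
  expect_error(compartmentSpec(c(1, -1, 0) * 1e-3, 1), "semi-definite")
})

test_that("Rician noise has the magnitude-MRI moments and is seeded", {
  x <- c(0, 1, 5, 100)
  expect_identical(addRicianNoise(x, 0, seed = 1), x)
  expect_error(addRicianNoise(x, -1), "nonnegative")
  expect_identical(addRicianNoise(x, 2, seed = 9), addRicianNoise(x, 2, seed = 9))

  n <- 1e5
  z <- addRicianNoise(rep(0, n), 3, seed = 4)
  expect_equal(mean(z), 3 * sqrt(pi / 2), tolerance = 0.02)
  s <- addRicianNoise(rep(50, n), 3, seed = 5)
  # E[out^2] - S^2 = 2 sigma^2 = 18; Monte-Carlo SE of the mean is ~0.95,
  # so allow a 3-sigma band
  expect_lt(abs(mean(s^2) - 50^2 - 2 * 3^2), 2.9)
})

test_that("phantom generation is exact in the noiseless limit and seeded", {
  bg <- list(compartmentSpec(rep(1.2e-3, 3), 1))
  ph <- uniformPhantom(bg, gridShape = c(2, 2, 2))
  gt <- ph$gtab
  sig <- signalArray(ph$dwi)
  for (v in seq_len(length(gt))) {
    b <- bvalues(gt)[v]
    expect_equal(as.vector(sig[, , , v]),
                 rep(100 * exp(-b * 1.2e-3), 8), tolerance = 1e-12)
  }
  # monoexponential region: log-signal linear in b along a fixed direction
  dirRow <- which(shellIds(gt) > 0)[1]
  g0 <- gradDirections(gt)[dirRow, ]
  same <- which(apply(gradDirections(gt), 1, function(r) all(r == g0)))
  fitb <- bvalues(gt)[same]
  logS <- log(sig[1, 1, 1, same])
  expect_equal(max(abs(stats::residuals(lm(logS ~ fitb)))), 0,
               tolerance = 1e-10)

  spec <- phantomSpec(acquisitionSpec(gridShape = c(4, 4, 2)), seed = 11)
  p1 <- buildPhantom(spec)
  p2 <- buildPhantom(spec)
  expect_identical(signalArray(p1$dwi), signalArray(p2$dwi))
  expect_true(all(signalArray(p1$dwi) >= 0))
})

test_that("bundle anisotropy declines monotonically across the age codes", {
  faByAge <- vapply(c(10, 15, 24), function(age) {
    spec <- phantomSpec(acquisitionSpec(gridShape = c(6, 6, 4)),
                        compartments = tissueCompartments(age),
                        ageMonths = age, seed = 7)
    ph <- buildPhantom(spec)
    mean(ph$truth$fa@values[ph$truth$masks$bundle])
  }, numeric(1))
  expect_true(all(diff(faByAge) < 0))
})

test_that("region map labels every voxel and the bundle runs left-right", {
  rm0 <- defaultRegionMap(c(20, 20, 10))
  expect_true(all(rm0 %in% 1:4))
  spec <- phantomSpec(seed = 1)
  ph <- buildPhantom(spec)
  bd <- ph$truth$directions
  vox <- which(ph$truth$masks$bundle)
  nv <- prod(dim(ph$truth$masks$bundle))
  expect_true(all(abs(bd[vox]) == 1))          # x component
  expect_true(all(bd[vox + nv] == 0))          # y component
})
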