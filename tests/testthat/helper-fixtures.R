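# shared fixtures, all generated in code

# a DWIDataset with arbitrary positive signal on a small grid
dummyDWI <- function(gtab, dims = c(2, 2, 2), seed = 1) {
  set.seed(seed)
  sig <- array(stats::runif(prod(dims) * length(gtab), 50, 100),
               dim = c(dims, length(gtab)))
  new("DWIDataset", signal = sig, voxelSize = c(0.15, 0.15, 0.15),
      affine = diag(c(0.15, 0.15, 0.15, 1)), gtab = gtab)
}

# noiseless single-region phantom with the given compartments
uniformPhantom <- function(compartments, gridShape = c(3, 3, 2),
                           shellBvalues = c(1000, 3000, 4000, 8000, 12000),
                           noiseSigma = 0, seed = 2, nB0 = 5,
                           directionsPerShell = 60) {
  acq <- acquisitionSpec(shellBvalues = shellBvalues,
                         directionsPerShell = directionsPerShell,
                         nB0 = nB0, gridShape = gridShape)
  spec <- phantomSpec(acq, regionMap = array(1L, gridShape),
                      compartments = list(tissue = compartments),
                      noiseSigma = noiseSigma, seed = seed)
  buildPhantom(spec)
}

# single-fiber two-compartment model along `direction`
fiberCompartments <- function(direction = c(1, 0, 0)) {
  list(compartmentSpec(c(0.72, 0.12, 0.12) * 1e-3, 0.6, direction),
       compartmentSpec(c(0.12, 0.06, 0.06) * 1e-3, 0.4, direction))
}

# shared default sphere grid (cheap to build, reused across files)
testSphere <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sphereGrid(3)
    cache
  }
})

# angle in degrees between two directions, antipodally invariant
angleDeg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}
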