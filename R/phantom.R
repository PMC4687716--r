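#' Acquisition specification for a multi-shell phantom
#'
#' Describes the q-space sampling geometry: shell b-values, directions per
#' shell, number of unweighted (b0) volumes, and the image grid. Defaults
#' reproduce a 5-shell ex vivo protocol (b = 1000, 3000, 4000, 8000 and
#' 12000 s/mm^2, 60 directions per shell, 5 b0 volumes) on a desk-scale
#' 20 x 20 x 10 grid of 0.15 mm voxels.
#'
#' @slot shellBvalues strictly increasing positive b-values (s/mm^2).
#' @slot directionsPerShell directions per shell (>= 6).
#' @slot nB0 number of b0 volumes (>= 1).
#' @slot voxelSize voxel dimensions, mm.
#' @slot gridShape 3 integers.
#' @slot smallDelta,bigDelta gradient pulse timings delta / Delta in ms
#'   (metadata only).
#' @export
setClass("AcquisitionSpec",
  representation(shellBvalues = "numeric", directionsPerShell = "integer",
                 nB0 = "integer", voxelSize = "numeric", gridShape = "integer",
                 smallDelta = "numeric", bigDelta = "numeric"))

setValidity("AcquisitionSpec", function(object) {
  b <- object@shellBvalues
  if (length(b) < 1 || any(b <= 0) || is.unsorted(b, strictly = TRUE))
    return("shellBvalues must be strictly increasing and positive")
  if (object@directionsPerShell < 6L)
    return("directionsPerShell must be at least 6")
  if (object@nB0 < 1L) return("at least one b0 volume is required")
  if (length(object@gridShape) != 3 || any(object@gridShape < 1))
    return("gridShape must be 3 positive integers")
  TRUE
})

#' @rdname AcquisitionSpec-class
#' @param shellBvalues,directionsPerShell,nB0,voxelSize,gridShape,smallDelta,bigDelta
#'   see slots.
#' @return an \linkS4class{AcquisitionSpec}.
#' @export
acquisitionSpec <- function(shellBvalues = c(1000, 3000, 4000, 8000, 12000),
                            directionsPerShell = 60, nB0 = 5,
                            voxelSize = c(0.15, 0.15, 0.15),
                            gridShape = c(20, 20, 10),
                            smallDelta = 11, bigDelta = 16) {
  new("AcquisitionSpec", shellBvalues = as.numeric(shellBvalues),
      directionsPerShell = as.integer(directionsPerShell),
      nB0 = as.integer(nB0), voxelSize = as.numeric(voxelSize),
      gridShape = as.integer(gridShape),
      smallDelta = smallDelta, bigDelta = bigDelta)
}

#' A Gaussian diffusion compartment
#'
#' One tensor compartment of a multi-compartment voxel signal model, given
#' by its eigenvalues (mm^2/s), principal direction, and volume fraction.
#'
#' @param eigenvalues length-3 nonnegative eigenvalues, descending
#'   (mm^2/s).
#' @param fraction volume fraction in [0, 1].
#' @param direction unit principal direction (axis of the first
#'   eigenvalue).
#' @return a list with elements \code{tensor} (3x3) and \code{fraction}.
#' @export
compartmentSpec <- function(eigenvalues, fraction, direction = c(1, 0, 0)) {
  if (length(eigenvalues) != 3 || any(eigenvalues < 0))
    stop("compartment tensor must be positive semi-definite ",
         "(3 nonnegative eigenvalues)")
  if (fraction < 0 || fraction > 1)
    stop("volume fraction must lie in [0, 1]")
  e1 <- direction / sqrt(sum(direction^2))
  # complete an orthonormal frame around the principal axis
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3)
  D <- R %*% diag(eigenvalues) %*% t(R)
  list(tensor = (D + t(D)) / 2, fraction = fraction,
       eigenvalues = sort(eigenvalues, decreasing = TRUE), direction = e1)
}

#' Quasi-uniform gradient directions by pairwise repulsion
#'
#' Spreads n unit vectors quasi-uniformly over the sphere by iterative
#' electrostatic repulsion acting on the antipodally symmetrized point set
#' (each point and its antipode repel all others), from a seeded random
#' start with a fixed iteration count, so the result is deterministic.
#'
#' @param n number of directions.
#' @param seed integer seed for the starting configuration.
#' @param iterations repulsion iterations.
#' @return an n x 3 matrix of unit vectors.
#' @export
repulsionDirections <- function(n, seed = 1, iterations = 200) {
  set.seed(seed)
  p <- matrix(stats::rnorm(3 * n), n, 3)
  p <- p / sqrt(rowSums(p^2))
  for (it in seq_len(iterations)) {
    # annealed step: force direction only, magnitude decays geometrically
    step <- 0.1 * exp(-4 * (it - 1) / iterations)
    q <- rbind(p, -p)
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- sweep(-q, 2, -p[i, ])          # p_i - q_j
      r2 <- rowSums(d^2)
      r2[r2 < 1e-12] <- Inf               # skip self
      force[i, ] <- colSums(d / r2^1.5)
    }
    # tangential projection keeps points on the sphere
    force <- force - p * rowSums(force * p)
    fn <- sqrt(rowSums(force^2))
    fn[fn < 1e-12] <- 1
    p <- p + step * force / fn
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

#' Build a multi-shell gradient table
#'
#' Generates nB0 zero-weighted entries followed by the shells in ascending
#' b order, reusing one quasi-uniform direction set across all shells (the
#' same angular sampling on every shell).
#'
#' @param spec an \linkS4class{AcquisitionSpec}.
#' @param seed seed for the repulsion starting configuration.
#' @return a \linkS4class{GradientTable}.
#' @export
makeGradientScheme <- function(spec, seed = 1) {
  validObject(spec)
  dirs <- repulsionDirections(spec@directionsPerShell, seed = seed)
  nb <- length(spec@shellBvalues)
  nd <- spec@directionsPerShell
  bvals <- c(rep(0, spec@nB0), rep(spec@shellBvalues, each = nd))
  directions <- rbind(matrix(0, spec@nB0, 3),
                      dirs[rep(seq_len(nd), times = nb), , drop = FALSE])
  shellId <- c(rep(0L, spec@nB0), rep(seq_len(nb), each = nd))
  new("GradientTable", bvalues = bvals, directions = directions,
      shellId = as.integer(shellId), shellBvalues = spec@shellBvalues,
      metadata = list(smallDelta = spec@smallDelta, bigDelta = spec@bigDelta))
}

#' Multi-compartment Gaussian signal
#'
#' Forward model S(g, b) = S0 * sum_k f_k exp(-b g' D_k g). b0 entries
#' return S0 exactly. A two-compartment (fast/slow) mixture gives the
#' non-monoexponential decay characteristic of tissue at high b-values.
#'
#' @param gtab a \linkS4class{GradientTable}.
#' @param compartments list of \code{\link{compartmentSpec}} objects whose
#'   fractions sum to 1.
#' @param S0 unattenuated signal level.
#' @return numeric vector, one value per gradient-table entry.
#' @export
compartmentSignal <- function(gtab, compartments, S0 = 1) {
  fr <- vapply(compartments, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("compartment volume fractions must sum to 1")
  g <- gtab@directions
  b <- gtab@bvalues
  s <- numeric(length(b))
  for (cp in compartments) {
    ev <- eigen(cp$tensor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12 * max(abs(ev), 1e-30))
      stop("compartment tensor must be positive semi-definite")
    adc <- rowSums((g %*% cp$tensor) * g)
    s <- s + cp$fraction * exp(-b * adc)
  }
  s[gtab@shellId == 0L] <- 1
  S0 * s
}

#' Add Rician noise to magnitude signal
#'
#' Returns sqrt((S + e1)^2 + e2^2) with e1, e2 independent zero-mean
#' Gaussians of scale sigma — the magnitude-MRI noise model, which biases
#' low-SNR signal upward. Deterministic for a fixed seed.
#'
#' @param signal numeric vector or array.
#' @param sigma Rician scale (>= 0); 0 returns the input unchanged.
#' @param seed integer seed.
#' @return noisy signal, same shape as the input.
#' @export
addRicianNoise <- function(signal, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(signal)
  set.seed(seed)
  n <- length(signal)
  e1 <- stats::rnorm(n, sd = sigma)
  e2 <- stats::rnorm(n, sd = sigma)
  out <- sqrt((signal + e1)^2 + e2^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Region compartment models mimicking aging white and gray matter
#'
#' Default two-compartment (fast/slow) tensor mixtures for the four phantom
#' regions: an isotropic background, a coherent left-right single-fiber
#' bundle, a 90-degree crossing-fiber block, and a low-anisotropy
#' gray-matter-like region. Diffusivities are on the ex vivo scale (fixed
#' tissue near 20 C diffuses roughly 2-3x slower than in vivo), which
#' keeps usable signal in the b = 8000-12000 s/mm^2 shells as in a
#' high-field fixed-brain acquisition. Anisotropy of the fiber and
#' gray-matter compartments declines with age: the lambda1:lambda2
#' eigenvalue ratio shrinks by \code{declinePerStep} per age step
#' (10 -> 15 -> 24 months), implemented by inflating the radial
#' eigenvalues.
#'
#' @param ageMonths one of 10, 15, 24.
#' @param declinePerStep fractional ratio shrinkage per age step.
#' @return named list of compartment lists, one per region
#'   (background, bundle, crossing, gray).
#' @export
tissueCompartments <- function(ageMonths = 10, declinePerStep = 0.1) {
  step <- match(ageMonths, c(10, 15, 24)) - 1
  if (is.na(step)) stop("ageMonths must be one of 10, 15, 24")
  radial <- function(ev) c(ev[1], ev[2:3] / (1 - declinePerStep)^step)
  fastF <- radial(c(0.72, 0.12, 0.12) * 1e-3)   # extra-axonal-like, fast
  slowF <- radial(c(0.12, 0.06, 0.06) * 1e-3)   # restricted-like, slow
  fastG <- radial(c(0.36, 0.18, 0.18) * 1e-3)   # gray matter: same fast/slow
  slowG <- radial(c(0.112, 0.088, 0.088) * 1e-3) # structure, weaker anisotropy
  list(
    background = list(
      compartmentSpec(rep(0.8e-3, 3), 0.7),
      compartmentSpec(rep(0.12e-3, 3), 0.3)),
    bundle = list(
      compartmentSpec(fastF, 0.6, c(1, 0, 0)),
      compartmentSpec(slowF, 0.4, c(1, 0, 0))),
    crossing = list(
      compartmentSpec(fastF, 0.3, c(1, 0, 0)),
      compartmentSpec(slowF, 0.2, c(1, 0, 0)),
      compartmentSpec(fastF, 0.3, c(0, 1, 0)),
      compartmentSpec(slowF, 0.2, c(0, 1, 0))),
    gray = list(
      compartmentSpec(fastG, 0.5, c(0, 0, 1)),
      compartmentSpec(slowG, 0.5, c(0, 0, 1))))
}

#' Default phantom region layout
#'
#' Labels every voxel of the grid: 1 = isotropic background, 2 = left-right
#' fiber bundle spanning the full x extent, 3 = crossing-fiber block,
#' 4 = gray-matter-like block. Regions are placed by grid fractions so any
#' grid shape works.
#'
#' @param gridShape 3 integers.
#' @return integer 3D array of region labels.
#' @export
defaultRegionMap <- function(gridShape = c(20, 20, 10)) {
  frac <- function(n, lo, hi) seq.int(floor(lo * n) + 1L, floor(hi * n))
  rm <- array(1L, dim = gridShape)
  ny <- gridShape[2]; nz <- gridShape[3]
  rm[, frac(ny, 0.40, 0.65), frac(nz, 0.35, 0.70)] <- 2L
  rm[, frac(ny, 0.05, 0.30), frac(nz, 0.35, 0.70)] <- 3L
  rm[, frac(ny, 0.70, 0.95), frac(nz, 0.25, 0.80)] <- 4L
  rm
}

#' Phantom specification
#'
#' Combines acquisition geometry, a labeled region map, per-region
#' compartment mixtures, signal level, Rician noise scale, an age code that
#' scales the anisotropy decline, and a seed.
#'
#' @slot acquisition an \linkS4class{AcquisitionSpec}.
#' @slot regionMap integer 3D array labeling every voxel 1..nRegions.
#' @slot compartments named list (one entry per region label, in label
#'   order) of compartment lists.
#' @slot S0 unattenuated signal level.
#' @slot noiseSigma Rician scale (>= 0).
#' @slot ageMonths age code, one of 10, 15, 24.
#' @slot edgePartialVolume fraction of background signal blended into
#'   voxels at region boundaries (partial-volume emulation; 0 disables).
#' @slot seed integer seed.
#' @export
setClass("PhantomSpec",
  representation(acquisition = "AcquisitionSpec", regionMap = "array",
                 compartments = "list", S0 = "numeric", noiseSigma = "numeric",
                 ageMonths = "numeric", edgePartialVolume = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  labs <- unique(as.vector(object@regionMap))
  if (any(is.na(labs)) || any(labs < 1) ||
      any(labs > length(object@compartments)))
    return("every voxel must carry a region label with a compartment model")
  if (object@noiseSigma < 0) return("noiseSigma must be nonnegative")
  if (!object@ageMonths %in% c(10, 15, 24))
    return("ageMonths must be one of 10, 15, 24")
  if (object@edgePartialVolume < 0 || object@edgePartialVolume >= 1)
    return("edgePartialVolume must lie in [0, 1)")
  TRUE
})

#' @rdname PhantomSpec-class
#' @param acquisition,regionMap,compartments,S0,noiseSigma,ageMonths,seed
#'   see slots; \code{regionMap} and \code{compartments} default to the
#'   four-region layout of \code{\link{defaultRegionMap}} and
#'   \code{\link{tissueCompartments}}. The default noise scale S0/55 is
#'   calibrated so the bundle's shell SNR profile (about 48 at b = 1000
#'   down to 12 at b = 12000, 5-shell scheme mean near 28) matches a
#'   high-field ex vivo acquisition. \code{edgePartialVolume} blends
#'   background signal into region-boundary voxels; it defaults to 0
#'   because fluid contamination reverses the FA shell trend in the
#'   voxels it touches (the free-water-elimination effect).
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(acquisition = acquisitionSpec(),
                        regionMap = defaultRegionMap(acquisition@gridShape),
                        compartments = tissueCompartments(ageMonths),
                        S0 = 100, noiseSigma = S0 / 55,
                        ageMonths = 10, edgePartialVolume = 0, seed = 1) {
  new("PhantomSpec", acquisition = acquisition, regionMap = regionMap,
      compartments = compartments, S0 = S0, noiseSigma = noiseSigma,
      ageMonths = ageMonths, edgePartialVolume = edgePartialVolume,
      seed = as.integer(seed))
}

# mixture-average tensor of a compartment list (the low-b effective tensor)
mixtureTensor <- function(compartments) {
  D <- matrix(0, 3, 3)
  for (cp in compartments) D <- D + cp$fraction * cp$tensor
  D
}

#' Generate a synthetic multi-shell DWI dataset
#'
#' Evaluates the multi-compartment forward model in every voxel of the
#' region map, blends a configurable fraction of background signal into
#' voxels at region boundaries (emulating partial-volume contamination at
#' tissue borders), adds Rician noise, and returns the dataset together with
#' ground truth aligned to the same grid: the true per-voxel principal
#' direction (NaN for isotropic regions), the true FA of the mixture-average
#' tensor, the region map, and named region masks.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{dwi} (\linkS4class{DWIDataset}),
#'   \code{gtab}, and \code{truth} (list: \code{directions},
#'   \code{fa}, \code{regionMap}, \code{masks}).
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  acq <- spec@acquisition
  gtab <- makeGradientScheme(acq, seed = spec@seed)
  nvol <- length(gtab)
  dims <- dim(spec@regionMap)
  labs <- sort(unique(as.vector(spec@regionMap)))

  sig <- matrix(0, prod(dims), nvol)
  truthDir <- matrix(NaN, prod(dims), 3)
  truthFA <- numeric(prod(dims))
  # voxels at a region boundary (label differs from a 6-neighbor) receive a
  # partial-volume blend with the background (label 1) signal
  edge <- array(FALSE, dims)
  if (spec@edgePartialVolume > 0 && length(labs) > 1) {
    rm0 <- spec@regionMap
    for (axis in 1:3) for (o in c(-1L, 1L)) {
      sh <- shiftAxis(rm0, o, axis)
      inVol <- shiftAxis(array(1, dims), o, axis) > 0
      edge <- edge | (inVol & sh != rm0)
    }
  }
  w <- spec@edgePartialVolume
  bgSignal <- compartmentSignal(gtab, spec@compartments[[labs[1]]],
                                S0 = spec@S0)
  bgTensor <- mixtureTensor(spec@compartments[[labs[1]]])
  fillTruth <- function(idx, D) {
    ed <- eigen(D, symmetric = TRUE)
    lam <- pmax(ed$values, 0)
    truthFA[idx] <<- faFromEigenvalues(matrix(lam, 1))[1]
    if ((lam[1] - lam[2]) / max(lam[1], 1e-30) > 1e-6)
      truthDir[idx, ] <<- matrix(canonicalizeDirections(t(ed$vectors[, 1,
                                 drop = FALSE])), length(idx), 3, byrow = TRUE)
  }
  for (lab in labs) {
    inRegion <- spec@regionMap == lab
    cps <- spec@compartments[[lab]]
    s <- compartmentSignal(gtab, cps, S0 = spec@S0)
    D <- mixtureTensor(cps)
    pv <- lab != labs[1] & edge & inRegion
    pure <- which(inRegion & !pv)
    sig[pure, ] <- matrix(s, length(pure), nvol, byrow = TRUE)
    fillTruth(pure, D)
    idxPv <- which(pv)
    if (length(idxPv)) {
      sPv <- (1 - w) * s + w * bgSignal
      sig[idxPv, ] <- matrix(sPv, length(idxPv), nvol, byrow = TRUE)
      fillTruth(idxPv, (1 - w) * D + w * bgTensor)
    }
  }
  sig <- addRicianNoise(sig, spec@noiseSigma, seed = spec@seed + 1L)

  signal <- array(sig, dim = c(dims, nvol))
  affine <- diag(c(acq@voxelSize, 1))
  dwi <- new("DWIDataset", signal = signal, voxelSize = acq@voxelSize,
             affine = affine, gtab = gtab)
  regionNames <- names(spec@compartments)
  if (is.null(regionNames)) regionNames <- paste0("region", labs)
  masks <- lapply(labs, function(l) spec@regionMap == l)
  names(masks) <- regionNames[labs]
  allMask <- array(TRUE, dims)
  truth <- list(
    directions = array(truthDir, dim = c(dims, 3)),
    fa = scalarMap("trueFA", array(truthFA, dims), allMask),
    regionMap = spec@regionMap,
    masks = masks)
  list(dwi = dwi, gtab = gtab, truth = truth)
}
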