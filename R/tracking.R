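#' Anisotropy stopping thresholds by shell scheme
#'
#' The protocol's threshold table for anisotropy-aided deterministic
#' tractography: single-shell reconstructions use FA 0.25, GFA 0.02,
#' NQA 0.25; multi-shell reconstructions (k >= 2) use FA 0.20, GFA 0.03,
#' NQA 0.30. Single-shell FA runs higher than multi-shell FA while GFA and
#' NQA run lower, hence the opposite adjustments.
#'
#' @param map one of "FA", "GFA", "NQA".
#' @param k cumulative shell count, 1..5.
#' @return the stopping threshold.
#' @export
stoppingThreshold <- function(map, k) {
  if (!k %in% 1:5) stop("scheme k must be in 1..5")
  tab <- list(FA = c(single = 0.25, multi = 0.20),
              GFA = c(single = 0.02, multi = 0.03),
              NQA = c(single = 0.25, multi = 0.30))
  if (!map %in% names(tab)) stop("unknown stopping map '", map, "'")
  unname(tab[[map]][if (k == 1) "single" else "multi"])
}

#' Tracking parameters
#'
#' @param stopThreshold anisotropy value below which tracking stops
#'   (0 < t < 1).
#' @param maxTurnDeg maximum turning angle between consecutive steps
#'   (default 60).
#' @param stepMm integration step; default half the smallest voxel
#'   dimension (resolved at tracking time when NULL).
#' @param targetCount streamlines to collect (default 300).
#' @param seed RNG seed for seeding positions.
#' @param maxSteps per-direction step cap.
#' @param seedBudgetFactor seeds attempted per requested streamline before
#'   giving up.
#' @return list of validated parameters.
#' @export
trackingParams <- function(stopThreshold, maxTurnDeg = 60, stepMm = NULL,
                           targetCount = 300, seed = 1, maxSteps = 2000,
                           seedBudgetFactor = 20) {
  if (stopThreshold <= 0 || stopThreshold >= 1)
    stop("stopThreshold must lie in (0, 1)")
  if (maxTurnDeg <= 0 || maxTurnDeg > 90)
    stop("maxTurnDeg must lie in (0, 90]")
  if (!is.null(stepMm) && stepMm <= 0) stop("stepMm must be positive")
  list(stopThreshold = stopThreshold, maxTurnDeg = maxTurnDeg,
       stepMm = stepMm, targetCount = as.integer(targetCount),
       seed = as.integer(seed), maxSteps = as.integer(maxSteps),
       seedBudgetFactor = seedBudgetFactor)
}

# trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates; NaN outside the grid or where the array is NaN
trilinear <- function(arr, p) {
  d <- dim(arr)
  if (any(p < 0) || any(p > d - 1)) return(NaN)
  f <- pmin(floor(p), d - 2)
  f <- pmax(f, 0)
  w <- p - f
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    if (wt > 0)
      val <- val + wt * arr[f[1] + dx + 1, f[2] + dy + 1, f[3] + dz + 1]
  }
  val
}

# candidate directions at an (already validated) voxel index triple
voxelDirections <- function(field, ijk) {
  if (is(field, "DirectionField")) {
    if (!field@mask[ijk[1], ijk[2], ijk[3]]) return(NULL)
    matrix(field@dirs[ijk[1], ijk[2], ijk[3], ], 1, 3)
  } else {
    np <- field@nPeaks[ijk[1], ijk[2], ijk[3]]
    if (is.na(np) || np < 1 || field@degenerate[ijk[1], ijk[2], ijk[3]])
      return(NULL)
    m <- matrix(NaN, np, 3)
    for (p in seq_len(np)) m[p, ] <- field@peakDirs[ijk[1], ijk[2], ijk[3], p, ]
    m
  }
}

# integrate one direction from a seed (continuous voxel coords, 0-based)
traceHalf <- function(field, stopArr, seedVox, heading, params, voxelSize) {
  stepVox <- params$stepMm / voxelSize
  cosTurn <- cos(params$maxTurnDeg * pi / 180)
  pts <- matrix(NA_real_, params$maxSteps + 1, 3)
  pts[1, ] <- seedVox
  pos <- seedVox
  h <- heading
  reason <- "maxSteps"
  n <- 1L
  for (s in seq_len(params$maxSteps)) {
    ijk <- round(pos) + 1
    d <- dim(stopArr)
    if (any(ijk < 1) || any(ijk > d)) { reason <- "outOfVolume"; break }
    cand <- voxelDirections(field, ijk)
    if (is.null(cand)) { reason <- "noDirection"; break }
    al <- as.vector(cand %*% h)
    best <- which.max(abs(al))
    dirn <- cand[best, ] * sign(al[best])
    if (sum(dirn * h) < cosTurn) { reason <- "turn"; break }
    newPos <- pos + dirn * stepVox
    v <- trilinear(stopArr, newPos)
    if (is.na(v)) { reason <- "outOfVolume"; break }
    if (v < params$stopThreshold) { reason <- "lowAnisotropy"; break }
    n <- n + 1L
    pts[n, ] <- newPos
    pos <- newPos
    h <- dirn
  }
  list(points = pts[seq_len(n), , drop = FALSE], reason = reason)
}

#' Deterministic streamline tractography
#'
#' FACT-style tracking: from each seed, the streamline is integrated in
#' both directions with Euler steps; the direction at a point is the
#' nearest voxel's peak best aligned (by absolute dot product) with the
#' incoming heading, sign-flipped to preserve heading. A streamline
#' terminates when the trilinearly interpolated stopping map falls below
#' the threshold, the turn exceeds the maximum angle, a voxel carries no
#' direction, or the streamline leaves the volume. Seeds are drawn
#' uniformly at random within seed-mask voxels (seeded RNG) until
#' \code{targetCount} streamlines of at least 2 points are collected or
#' the seed budget is exhausted.
#'
#' @param field a \linkS4class{DirectionField} or \linkS4class{PeakField}.
#' @param stopMap a \linkS4class{ScalarMap} (e.g. FA, GFA or NQA).
#' @param seedMask logical 3D array of seed voxels.
#' @param params a \code{\link{trackingParams}} list.
#' @param voxelSizeMm voxel dimensions in mm (used to convert steps and
#'   report physical coordinates).
#' @return a \linkS4class{Tractogram}; points are in mm (voxel center i
#'   maps to (i - 1) * voxelSize).
#' @export
trackStreamlines <- function(field, stopMap, seedMask, params,
                             voxelSizeMm = c(1, 1, 1)) {
  stopArr <- stopMap@values
  stopArr[!stopMap@mask] <- NaN
  inRange <- stopArr >= params$stopThreshold
  if (!any(inRange, na.rm = TRUE))
    stop("no voxel reaches the stopping threshold ", params$stopThreshold)
  seedable <- which(seedMask & !is.na(stopArr) & inRange)
  if (length(seedable) == 0)
    stop("no seed voxel at or above the stopping threshold")
  if (is.null(params$stepMm)) params$stepMm <- min(voxelSizeMm) / 2
  d <- dim(stopArr)
  set.seed(params$seed)
  budget <- ceiling(params$seedBudgetFactor * params$targetCount)
  lines <- vector("list", params$targetCount)
  term <- vector("list", params$targetCount)
  got <- 0L
  short <- 0L
  for (trial in seq_len(budget)) {
    if (got >= params$targetCount) break
    vx <- seedable[sample.int(length(seedable), 1)]
    ijk <- arrayInd(vx, d)
    seedVox <- as.numeric(ijk - 1) + stats::runif(3, -0.5, 0.5)
    v0 <- trilinear(stopArr, seedVox)
    if (is.na(v0) || v0 < params$stopThreshold) next
    cand <- voxelDirections(field, pmin(pmax(round(seedVox) + 1, 1), d))
    if (is.null(cand)) next
    h0 <- cand[1, ]
    fwd <- traceHalf(field, stopArr, seedVox, h0, params, voxelSizeMm)
    bwd <- traceHalf(field, stopArr, seedVox, -h0, params, voxelSizeMm)
    pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))[-1]), , drop = FALSE],
                 fwd$points)
    if (nrow(pts) < 2) { short <- short + 1L; next }
    got <- got + 1L
    lines[[got]] <- sweep(pts, 2, voxelSizeMm, "*")
    term[[got]] <- data.frame(startReason = bwd$reason,
                              endReason = fwd$reason,
                              lengthMm = (nrow(pts) - 1) * params$stepMm)
  }
  lines <- lines[seq_len(got)]
  termination <- do.call(rbind, term[seq_len(got)])
  if (is.null(termination))
    termination <- data.frame(startReason = character(0),
                              endReason = character(0),
                              lengthMm = numeric(0))
  termination$shortDiscarded <- short
  new("Tractogram", streamlines = lines, stepMm = params$stepMm,
      termination = termination, params = params)
}

#' Tractogram summary
#'
#' @param tract a \linkS4class{Tractogram}.
#' @return data.frame with streamline count, mean length (mm), and
#'   termination-reason counts.
#' @export
trackSummary <- function(tract) {
  n <- length(tract@streamlines)
  reasons <- c(tract@termination$startReason, tract@termination$endReason)
  tab <- table(factor(reasons, levels = c("lowAnisotropy", "turn",
                                          "outOfVolume", "noDirection",
                                          "maxSteps")))
  data.frame(count = n,
             meanLengthMm = if (n) mean(tract@termination$lengthMm) else NA,
             t(as.matrix(tab)))
}

#' Write streamlines in TrackVis .trk format
#'
#' Minimal TrackVis writer (format version 2, little-endian, no scalars or
#' properties); point coordinates are written in mm.
#'
#' @param tract a \linkS4class{Tractogram}.
#' @param path output file.
#' @param dim grid dimensions.
#' @param voxelSizeMm voxel size, mm.
#' @return the path, invisibly.
#' @export
writeTrk <- function(tract, path, dim = c(1L, 1L, 1L),
                     voxelSizeMm = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(as.raw(0), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxelSizeMm), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")     # origin
  writeBin(0L, con, size = 2, endian = "little")             # n_scalars
  writeBin(raw(200), con)                                    # scalar names
  writeBin(0L, con, size = 2, endian = "little")             # n_properties
  writeBin(raw(200), con)                                    # property names
  m <- diag(c(voxelSizeMm, 1))
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                    # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(as.raw(0), con)
  writeBin(raw(4), con)                                      # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # invert/swap
  writeBin(length(tract@streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")             # version
  writeBin(1000L, con, size = 4, endian = "little")          # hdr_size
  for (sl in tract@streamlines) {
    writeBin(nrow(sl), con, size = 4, endian = "little")
    writeBin(as.numeric(t(sl)), con, size = 4, endian = "little")
  }
  invisible(path)
}
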