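#' Per-voxel dominant fiber direction
#'
#' Extracts one unit direction per voxel: the principal eigenvector for a
#' tensor field, or the highest-amplitude ODF peak for a peak field.
#' Degenerate voxels (near-isotropic tensors, flat ODFs) are excluded from
#' the output mask and counted rather than assigned a direction, so they
#' cannot deflate downstream angular statistics. Directions are
#' canonicalized (first nonzero component positive).
#'
#' @param recon a \linkS4class{TensorField} or \linkS4class{PeakField}.
#' @param mask logical 3D array of voxels to evaluate.
#' @param scheme shell-scheme code k to record.
#' @param isoTol for tensors: voxels with (l1 - l2) / l1 below this are
#'   excluded as direction-degenerate.
#' @return a \linkS4class{DirectionField}.
#' @export
setGeneric("dominantDirection",
  function(recon, mask, scheme = NA_integer_, isoTol = 1e-4)
    standardGeneric("dominantDirection"))

#' @rdname dominantDirection
#' @export
setMethod("dominantDirection", "TensorField",
  function(recon, mask, scheme = NA_integer_, isoTol = 1e-4) {
    if (!any(mask)) stop("empty mask")
    dims <- dim(recon@mask)
    use <- mask & recon@mask
    vox <- which(use)
    nv <- prod(dims)
    l1 <- recon@evals[vox]
    l2 <- recon@evals[vox + nv]
    ok <- (l1 - l2) > isoTol * pmax(l1, .Machine$double.eps)
    # first eigenvector occupies component blocks (cc-1)*nv within m = 1
    d <- matrix(c(recon@evecs[vox], recon@evecs[vox + nv * 1],
                  recon@evecs[vox + nv * 2]), ncol = 3)
    d <- canonicalizeDirections(d)
    dirs <- array(NaN, c(dims, 3))
    outMask <- array(FALSE, dims)
    outMask[vox[ok]] <- TRUE
    for (cc in 1:3) dirs[vox[ok] + (cc - 1) * nv] <- d[ok, cc]
    new("DirectionField", dirs = dirs, mask = outMask, source = "DTI",
        scheme = as.integer(scheme), nExcluded = as.integer(sum(!ok)))
  })

#' @rdname dominantDirection
#' @export
setMethod("dominantDirection", "PeakField",
  function(recon, mask, scheme = NA_integer_, isoTol = 1e-4) {
    if (!any(mask)) stop("empty mask")
    dims <- dim(recon@mask)
    use <- mask & recon@mask
    vox <- which(use)
    nv <- prod(dims)
    ok <- !recon@degenerate[vox] & recon@nPeaks[vox] >= 1L
    maxP <- dim(recon@peakDirs)[4]
    d <- matrix(NaN, length(vox), 3)
    for (cc in 1:3)
      d[, cc] <- recon@peakDirs[vox + (cc - 1) * maxP * nv]
    d[ok, ] <- canonicalizeDirections(d[ok, , drop = FALSE])
    dirs <- array(NaN, c(dims, 3))
    outMask <- array(FALSE, dims)
    outMask[vox[ok]] <- TRUE
    for (cc in 1:3) dirs[vox[ok] + (cc - 1) * nv] <- d[ok, cc]
    new("DirectionField", dirs = dirs, mask = outMask, source = "QBI",
        scheme = as.integer(scheme), nExcluded = as.integer(sum(!ok)))
  })

#' Angular deviation between two direction fields
#'
#' Per voxel, theta = arccos(|u_target . u_reference|) in degrees — the
#' inner angle between the dominant fiber orientations, invariant to the
#' sign of either direction and to swapping the fields. Dot products are
#' clipped to [-1, 1] before arccos. The ROI mean and max are taken over
#' voxels carried by both fields and the supplied mask.
#'
#' @param target,reference \linkS4class{DirectionField}s on the same grid.
#' @param mask logical 3D ROI.
#' @return a \linkS4class{DeviationResult}.
#' @export
angularDeviation <- function(target, reference, mask = NULL) {
  dims <- dim(target@mask)
  if (!identical(dims, dim(reference@mask)))
    stop("direction fields are on different grids")
  if (is.null(mask)) mask <- array(TRUE, dims)
  use <- mask & target@mask & reference@mask
  vox <- which(use)
  if (length(vox) == 0) stop("no voxels with directions in both fields")
  nv <- prod(dims)
  dp <- numeric(length(vox))
  for (cc in 1:3)
    dp <- dp + target@dirs[vox + (cc - 1) * nv] *
               reference@dirs[vox + (cc - 1) * nv]
  dp <- pmin(1, pmax(-1, abs(dp)))
  th <- acos(dp) * 180 / pi
  theta <- array(NaN, dims)
  theta[vox] <- th
  new("DeviationResult", theta = theta, roiMean = mean(th),
      roiMax = max(th), scheme = target@scheme,
      nVoxels = length(vox))
}

#' Linear trend of a quantity across cumulative shell schemes
#'
#' Ordinary least squares of a response (e.g. ROI-mean angular deviation or
#' ROI-mean anisotropy) on the shell-scheme code 1..5, optionally adding an
#' age covariate; the two-sided p-value for the scheme slope comes from the
#' t distribution.
#'
#' @param scheme numeric scheme codes.
#' @param value response values.
#' @param age optional covariate.
#' @return list: \code{slope}, \code{t}, \code{p} for the scheme predictor,
#'   plus \code{fit} (the \code{lm} object).
#' @export
shellTrend <- function(scheme, value, age = NULL) {
  if (length(scheme) != length(value)) stop("length mismatch")
  if (length(scheme) < 3) stop("at least 3 points are required")
  df <- data.frame(value = value, scheme = scheme)
  form <- value ~ scheme
  if (!is.null(age)) {
    df$age <- age
    form <- value ~ scheme + age
  }
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient trend design")
  sm <- suppressWarnings(summary(fit))   # perfect fits handled below
  slope <- sm$coefficients["scheme", "Estimate"]
  tv <- sm$coefficients["scheme", "t value"]
  pv <- sm$coefficients["scheme", "Pr(>|t|)"]
  # perfect fits leave only rounding error in the residuals; resolve the
  # 0/0 by convention instead of reporting noise-driven t statistics
  scale0 <- max(abs(value), .Machine$double.eps)
  if (!is.finite(tv) || sm$sigma < 1e-10 * scale0) {
    degenerateSlope <- abs(slope) < 1e-10 * scale0
    slope <- if (degenerateSlope) 0 else slope
    tv <- if (degenerateSlope) 0 else sign(slope) * Inf
    pv <- if (degenerateSlope) 1 else 0
  }
  list(slope = slope, t = tv, p = pv, fit = fit)
}
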