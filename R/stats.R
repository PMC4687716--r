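#' Shell-wise signal-to-noise estimation
#'
#' Noise is estimated as the mean (over the mask) of each voxel's standard
#' deviation across the b0 volumes; the SNR of a shell is the mean weighted
#' signal in the mask for that shell divided by this noise, and the SNR of
#' a cumulative k-shell scheme is the mean of its member shells' SNRs.
#'
#' @param dataset a \linkS4class{DWIDataset} with at least 2 b0 volumes.
#' @param mask logical 3D array (e.g. a white-matter bundle mask).
#' @param maskName label stored in the report.
#' @return list: \code{noise}, \code{shellSNR} (named by b-value),
#'   \code{schemeSNR} (named by k), \code{maskName}.
#' @export
estimateSNR <- function(dataset, mask, maskName = "mask") {
  gt <- dataset@gtab
  b0idx <- which(gt@shellId == 0L)
  if (length(b0idx) < 2)
    stop("SNR estimation needs at least 2 b0 volumes")
  vox <- which(mask)
  n <- length(gt)
  S <- matrix(aperm(dataset@signal, c(4, 1, 2, 3)), n)[, vox, drop = FALSE]
  noise <- mean(apply(S[b0idx, , drop = FALSE], 2, stats::sd))
  if (noise == 0) {
    warning("zero noise estimate (identical b0 volumes); SNR is infinite")
    noise <- 0
  }
  ns <- length(gt@shellBvalues)
  shellSNR <- vapply(seq_len(ns), function(s) {
    m <- mean(S[gt@shellId == s, , drop = FALSE])
    if (noise == 0) Inf else m / noise
  }, numeric(1))
  names(shellSNR) <- gt@shellBvalues
  schemeSNR <- vapply(seq_len(ns), function(k) mean(shellSNR[seq_len(k)]),
                      numeric(1))
  names(schemeSNR) <- seq_len(ns)
  list(noise = noise, shellSNR = shellSNR, schemeSNR = schemeSNR,
       maskName = maskName)
}

# shift a 3D array by o along one axis, zero-filling
shiftAxis <- function(a, o, axis) {
  if (o == 0) return(a)
  d <- dim(a)
  out <- array(0, d)
  idx <- lapply(d, seq_len)
  src <- idx; dst <- idx
  n <- d[axis]
  if (abs(o) >= n) return(out)
  if (o > 0) { dst[[axis]] <- (o + 1):n; src[[axis]] <- 1:(n - o) }
  else { dst[[axis]] <- 1:(n + o); src[[axis]] <- (1 - o):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Gaussian smoothing of a scalar map
#'
#' Separable Gaussian convolution with sigma = fwhm / 2.3548 per axis,
#' NaN-aware: values outside the mask contribute nothing and the kernel is
#' renormalized by the smoothed mask weight, so edges are unbiased.
#' \code{fwhm} is expressed in voxels.
#'
#' @param map a \linkS4class{ScalarMap}.
#' @param fwhm full width at half maximum of the kernel, voxels (>= 0;
#'   0 is the identity).
#' @return a smoothed \linkS4class{ScalarMap}.
#' @export
gaussianSmooth <- function(map, fwhm = 3) {
  if (fwhm < 0) stop("fwhm must be nonnegative")
  if (fwhm == 0) return(map)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  valid <- map@mask & !is.na(map@values) & !is.nan(map@values)
  num <- map@values
  num[!valid] <- 0
  den <- array(as.numeric(valid), dim(valid))
  for (axis in 1:3) {
    numNew <- array(0, dim(num)); denNew <- array(0, dim(den))
    for (j in seq_along(k)) {
      o <- j - r - 1L
      numNew <- numNew + k[j] * shiftAxis(num, o, axis)
      denNew <- denNew + k[j] * shiftAxis(den, o, axis)
    }
    num <- numNew; den <- denNew
  }
  out <- num / den
  out[den == 0] <- NaN
  scalarMap(map@name, out, map@mask)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' Classic step-up rule: with sorted p-values p_(1) <= ... <= p_(m), the
#' critical p is the largest p_(i) <= (i/m) q; all p-values at or below it
#' are rejected. Controls the expected false-discovery proportion at q.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param q target FDR level (default 0.05).
#' @return list: \code{criticalP} (0 when nothing is rejected) and
#'   \code{reject} (logical, same order as the input).
#' @export
fdrBH <- function(pvalues, q = 0.05) {
  m <- length(pvalues)
  if (m == 0) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  ps <- sort(pvalues)
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0)
    return(list(criticalP = 0, reject = rep(FALSE, m)))
  crit <- ps[max(ok)]
  list(criticalP = crit, reject = pvalues <= crit)
}

#' Voxel-wise regression result
#'
#' @slot slope,t,p 3D arrays for the shell-code predictor.
#' @slot criticalP the BH-FDR critical p-value.
#' @slot sigMask logical 3D array of significant voxels.
#' @slot q FDR level.
#' @slot mask analysis mask (voxels entering the BH correction).
#' @export
setClass("VoxelRegressionResult",
  representation(slope = "array", t = "array", p = "array",
                 criticalP = "numeric", sigMask = "array", q = "numeric",
                 mask = "array"))

setMethod("show", "VoxelRegressionResult", function(object) {
  cat(sprintf("VoxelRegressionResult: %d voxels tested, %d significant (FDR q = %g, critical p = %.4g)\n",
              sum(object@mask), sum(object@sigMask), object@q,
              object@criticalP))
})

#' Voxel-wise shell-trend regression with FDR correction
#'
#' Per voxel, OLS of an anisotropy value on the cumulative shell code
#' (1..5), with an optional age covariate when maps from several subjects
#' are pooled. Two-sided p-values for the shell slope are corrected over
#' the in-mask voxels by Benjamini-Hochberg at level q. Voxels with any
#' missing value are excluded from testing and from the correction.
#'
#' @param maps list of \linkS4class{ScalarMap}s, one per subject x scheme.
#' @param schemes numeric shell codes parallel to \code{maps}.
#' @param ages optional subject ages parallel to \code{maps}.
#' @param mask optional analysis mask (default: intersection of map masks).
#' @param q FDR level.
#' @return a \linkS4class{VoxelRegressionResult}.
#' @export
voxelwiseShellRegression <- function(maps, schemes, ages = NULL,
                                     mask = NULL, q = 0.05) {
  nobs <- length(maps)
  if (nobs != length(schemes)) stop("maps and schemes length mismatch")
  if (length(unique(schemes)) < 2) stop("at least 2 distinct schemes needed")
  dims <- dim(maps[[1]]@values)
  if (is.null(mask)) {
    mask <- array(TRUE, dims)
    for (m in maps) mask <- mask & m@mask
  }
  X <- cbind(1, schemes)
  if (!is.null(ages) && length(unique(ages)) > 1) X <- cbind(X, ages)
  p0 <- ncol(X)
  if (nobs <= p0) stop("not enough observations for the design")
  vox <- which(mask)
  Y <- matrix(NA_real_, nobs, length(vox))
  for (i in seq_len(nobs)) Y[i, ] <- maps[[i]]@values[vox]
  good <- colSums(is.na(Y) | is.nan(Y)) == 0
  XtXinv <- solve(crossprod(X))
  A <- XtXinv %*% t(X)
  beta <- A %*% Y[, good, drop = FALSE]
  res <- Y[, good, drop = FALSE] - X %*% beta
  df <- nobs - p0
  s2 <- colSums(res^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])
  tv <- beta[2, ] / se
  pv <- 2 * stats::pt(-abs(tv), df)

  bh <- fdrBH(pv, q)
  mk <- function(vals) {
    a <- array(NaN, dims); a[vox[good]] <- vals; a
  }
  sig <- array(FALSE, dims)
  sig[vox[good]] <- bh$reject
  testMask <- array(FALSE, dims)
  testMask[vox[good]] <- TRUE
  new("VoxelRegressionResult", slope = mk(beta[2, ]), t = mk(tv),
      p = mk(pv), criticalP = bh$criticalP, sigMask = sig, q = q,
      mask = testMask)
}

#' ROI-mean anisotropy and its shell trend
#'
#' Computes the ROI mean of each map and regresses the means on the shell
#' code (optionally adjusting for age) with the same OLS engine as
#' \code{\link{shellTrend}}.
#'
#' @param maps list of \linkS4class{ScalarMap}s, one per subject x scheme.
#' @param schemes shell codes parallel to \code{maps}.
#' @param ages optional ages parallel to \code{maps}.
#' @param roiMask logical 3D ROI.
#' @return list: \code{table} (data.frame scheme, age, mean) and
#'   \code{trend} (\code{\link{shellTrend}} output).
#' @export
roiMeanTrend <- function(maps, schemes, ages = NULL, roiMask) {
  if (!any(roiMask)) stop("empty ROI")
  means <- vapply(maps, function(m) {
    v <- m@values[roiMask & m@mask]
    if (length(v) == 0) stop("ROI lies outside the map mask")
    mean(v, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(scheme = schemes, mean = means)
  if (!is.null(ages)) tab$age <- ages
  trend <- shellTrend(schemes, means,
                      age = if (!is.null(ages) &&
                                length(unique(ages)) > 1) ages else NULL)
  list(table = tab, trend = trend)
}
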