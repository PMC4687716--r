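#' Real symmetric spherical harmonic basis matrix
#'
#' Evaluates the real, even-order, orthonormal spherical harmonic basis at
#' unit directions. Basis ordering: for each even degree l = 0, 2, ..,
#' order, the orders m = -l..l, with m < 0 mapped to sin(|m| phi) terms,
#' m = 0 to the zonal term and m > 0 to cos(m phi) terms. An order-8 basis
#' has (8+1)(8+2)/2 = 45 functions.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param order maximum even degree.
#' @return n x R basis matrix with attributes \code{degree} (the l of each
#'   column) and \code{m}.
#' @export
shMatrix <- function(directions, order = 8) {
  if (order %% 2 != 0) stop("order must be even")
  ct <- pmin(1, pmax(-1, directions[, 3]))
  phi <- atan2(directions[, 2], directions[, 1])
  degrees <- seq(0, order, by = 2)
  R <- (order + 1) * (order + 2) / 2
  B <- matrix(0, nrow(directions), R)
  degCol <- integer(R); mCol <- integer(R)
  j <- 0L
  for (l in degrees) {
    P <- pracma::legendre(l, ct)             # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, 1)
    for (m in -l:l) {
      j <- j + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Pl <- P[am + 1, ]
      B[, j] <- if (m < 0) sqrt(2) * nrm * Pl * sin(am * phi)
                else if (m == 0) nrm * Pl
                else sqrt(2) * nrm * Pl * cos(m * phi)
      degCol[j] <- l; mCol[j] <- m
    }
  }
  attr(B, "degree") <- degCol
  attr(B, "m") <- mCol
  B
}

# largest even order whose basis size fits ndir observations
reduceOrder <- function(order, ndir) {
  while (order > 0 && (order + 1) * (order + 2) / 2 > ndir)
    order <- order - 2
  order
}

#' Fit per-shell spherical harmonic coefficients
#'
#' Least-squares SH fit of each shell's normalized signal E = S / S0 (S0 is
#' the voxel mean over b0 volumes) with a Laplace-Beltrami roughness
#' penalty: c = (B'B + lambda L)^{-1} B' E, where L is diagonal with
#' entries l^2 (l+1)^2. If a shell has fewer directions than basis
#' functions the order is reduced (and reported) to the largest even order
#' that fits.
#'
#' @param dataset a \linkS4class{DWIDataset}.
#' @param order maximum even SH degree (default 8, 45 coefficients).
#' @param lambda regularization weight (default 0.006).
#' @param mask optional logical 3D array.
#' @return an \linkS4class{SHField}.
#' @export
fitSH <- function(dataset, order = 8, lambda = 0.006, mask = NULL) {
  gt <- dataset@gtab
  dims <- dim(dataset@signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  vox <- which(mask)
  n <- length(gt)
  S <- matrix(aperm(dataset@signal, c(4, 1, 2, 3)), n)[, vox, drop = FALSE]
  b0 <- colMeans(S[gt@shellId == 0L, , drop = FALSE])
  b0 <- pmax(b0, .Machine$double.eps)
  shells <- seq_along(gt@shellBvalues)
  coefs <- vector("list", length(shells))
  for (s in shells) {
    rows <- which(gt@shellId == s)
    dirs <- gt@directions[rows, , drop = FALSE]
    ord <- reduceOrder(order, nrow(dirs))
    if (ord < order)
      message(sprintf("shell %d: order reduced %d -> %d (%d directions)",
                      s, order, ord, nrow(dirs)))
    Rn <- (ord + 1) * (ord + 2) / 2
    if (nrow(dirs) < Rn)
      stop("shell has fewer directions than SH coefficients")
    B <- shMatrix(dirs, ord)
    ldeg <- attr(B, "degree")
    L <- diag(ldeg^2 * (ldeg + 1)^2, Rn)
    E <- sweep(S[rows, , drop = FALSE], 2, b0, "/")
    C <- solve(crossprod(B) + lambda * L, crossprod(B, E))  # R x nvox
    arr <- array(NaN, c(dims, Rn))
    nv <- prod(dims)
    for (j in seq_len(Rn)) arr[vox + (j - 1) * nv] <- C[j, ]
    attr(arr, "order") <- ord
    coefs[[s]] <- arr
  }
  new("SHField", coefs = coefs, shellBvalues = gt@shellBvalues,
      order = as.integer(order), lambda = lambda, mask = mask)
}

# Legendre polynomial P_l at 0 (zero for odd l)
legendreP0 <- function(l) {
  if (l %% 2 == 1) return(0)
  h <- l / 2
  (-1)^h * exp(lgamma(l + 1) - l * log(2) - 2 * lgamma(h + 1))
}

#' Analytic Funk-Radon transform to ODFs
#'
#' Converts per-shell SH signal coefficients to a sampled orientation
#' distribution function: each degree-l coefficient is scaled by
#' 2 pi P_l(0) (the analytic great-circle integral of a spherical
#' harmonic), then evaluated on the sphere grid. Negative samples are
#' floored at zero and counted. When several shells are present, per-shell
#' ODFs are combined by a weighted average (the monoexponential q-ball
#' theory holds per shell; the Funk-Radon scaling is shell-specific).
#' With \code{shellWeighting = "signal"} (the default) each shell's weight
#' is proportional to its mean normalized signal (its mean l = 0 SH
#' coefficient), so heavily attenuated, low-SNR shells contribute in
#' proportion to the signal they actually carry — close to an
#' inverse-variance combination. \code{"equal"} averages shells with
#' identical weights.
#'
#' @param sh an \linkS4class{SHField}.
#' @param sphere a \linkS4class{SphereGrid}.
#' @param shellWeighting "signal" or "equal".
#' @return an \linkS4class{ODFField}.
#' @export
frtODF <- function(sh, sphere, shellWeighting = c("signal", "equal")) {
  shellWeighting <- match.arg(shellWeighting)
  dims <- dim(sh@mask)
  vox <- which(sh@mask)
  nv <- prod(dims)
  m <- nrow(sphere@vertices)
  acc <- matrix(0, length(vox), m)
  wsum <- 0
  for (s in seq_along(sh@coefs)) {
    arr <- sh@coefs[[s]]
    ord <- attr(arr, "order")
    Rn <- dim(arr)[4]
    C <- matrix(0, length(vox), Rn)
    for (j in seq_len(Rn)) C[, j] <- arr[vox + (j - 1) * nv]
    Bs <- shMatrix(sphere@vertices, ord)
    ldeg <- attr(Bs, "degree")
    scale <- 2 * pi * vapply(ldeg, legendreP0, numeric(1))
    w <- if (shellWeighting == "signal")
      max(mean(C[, 1]), .Machine$double.eps) else 1
    acc <- acc + w * (C %*% (t(Bs) * scale))
    wsum <- wsum + w
  }
  acc <- acc / wsum
  nNeg <- sum(acc < 0)
  acc[acc < 0] <- 0
  odf <- array(NaN, c(dims, m))
  for (j in seq_len(m)) odf[vox + (j - 1) * nv] <- acc[, j]
  new("ODFField", odf = odf, sphere = sphere, mask = sh@mask,
      nNegative = as.integer(nNeg))
}

# in-mask ODF matrix (nvox x m) helper
odfMatrix <- function(odf) {
  dims <- dim(odf@mask)
  vox <- which(odf@mask)
  nv <- prod(dims)
  m <- dim(odf@odf)[4]
  M <- matrix(0, length(vox), m)
  for (j in seq_len(m)) M[, j] <- odf@odf[vox + (j - 1) * nv]
  M
}

#' Generalized fractional anisotropy
#'
#' GFA = sqrt( n * sum_i (psi(u_i) - <psi>)^2 / ((n-1) * sum_i psi(u_i)^2) ),
#' the normalized standard deviation of the sampled ODF; 0 for an all-zero
#' ODF. Scale-invariant and bounded in [0, 1].
#'
#' @param odf an \linkS4class{ODFField}.
#' @return a \linkS4class{ScalarMap} named "GFA".
#' @export
gfa <- function(odf) {
  M <- odfMatrix(odf)
  n <- ncol(M)
  if (n < 2) stop("GFA needs at least 2 ODF samples")
  mu <- rowMeans(M)
  num <- n * rowSums((M - mu)^2)
  den <- (n - 1) * rowSums(M^2)
  g <- sqrt(num / den)
  g[den == 0] <- 0
  dims <- dim(odf@mask)
  vals <- array(NaN, dims)
  vals[which(odf@mask)] <- pmin(g, 1)
  scalarMap("GFA", vals, odf@mask)
}

# Sub-grid refinement of a peak direction: fit a quadratic surface to the
# ODF over the peak vertex and its neighbors in gnomonic (tangent-plane)
# coordinates and move to its stationary point, clamped to one grid step.
refinePeakDirection <- function(vals, sph, idx) {
  v0 <- sph@vertices[idx, ]
  nbIdx <- unique(sph@neighbors[idx, ])
  nbIdx <- nbIdx[nbIdx != idx]
  ref <- if (abs(v0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- ref - sum(ref * v0) * v0
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(v0[2] * t1[3] - v0[3] * t1[2], v0[3] * t1[1] - v0[1] * t1[3],
          v0[1] * t1[2] - v0[2] * t1[1])
  u <- sph@vertices[nbIdx, , drop = FALSE]
  u <- u * sign(as.vector(u %*% v0))        # antipodal fold toward v0
  w <- as.vector(u %*% v0)
  x <- as.vector(u %*% t1) / w
  y <- as.vector(u %*% t2) / w
  X <- cbind(1, c(0, x), c(0, y), c(0, x^2), c(0, x * y), c(0, y^2))
  z <- c(vals[idx], vals[nbIdx])
  cf <- tryCatch(qr.solve(X, z), error = function(e) NULL)
  if (is.null(cf) || anyNA(cf)) return(v0)
  H <- matrix(c(2 * cf[4], cf[5], cf[5], 2 * cf[6]), 2, 2)
  detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
  if (!(detH > 0 && H[1, 1] < 0)) return(v0)  # not a local maximum
  s <- -solve(H, cf[2:3])
  lim <- tan(sph@maxEdgeDeg * pi / 180)
  if (sqrt(sum(s^2)) > lim) return(v0)
  d <- v0 + s[1] * t1 + s[2] * t2
  d / sqrt(sum(d^2))
}

#' Extract ODF peaks
#'
#' Local maxima over the sphere grid's neighbor graph, selected greedily by
#' amplitude while honoring a minimum angular separation; ties are broken
#' by lexicographic direction order so the result is deterministic.
#' Retained peak directions are refined below the grid resolution by a
#' quadratic fit over the vertex's neighbor patch. Flat ODFs (no contrast)
#' are flagged degenerate and carry a single deterministic peak.
#'
#' @param odf an \linkS4class{ODFField}.
#' @param minSeparationDeg minimum pairwise peak separation (default 25).
#' @param maxPeaks maximum retained peaks per voxel (default 3).
#' @param flatTol relative ODF range below which a voxel counts as flat.
#' @return a \linkS4class{PeakField}.
#' @export
findPeaks <- function(odf, minSeparationDeg = 25, maxPeaks = 3,
                      flatTol = 1e-6) {
  M <- odfMatrix(odf)
  sph <- odf@sphere
  nb <- sph@neighbors
  nvx <- nrow(M)
  # neighbor maximum per vertex, vectorized over voxels
  neighMax <- M[, nb[, 1], drop = FALSE]
  for (j in 2:ncol(nb))
    neighMax <- pmax(neighMax, M[, nb[, j], drop = FALSE])
  isMax <- M >= neighMax & M > 0
  rng <- apply(M, 1, max) - apply(M, 1, min)
  flat <- rng <= flatTol * pmax(apply(M, 1, max), .Machine$double.eps)

  v <- sph@vertices
  lex <- order(v[, 1], v[, 2], v[, 3])
  lexRank <- integer(nrow(v)); lexRank[lex] <- seq_len(nrow(v))
  cosSep <- cos(minSeparationDeg * pi / 180)

  dims <- dim(odf@mask)
  vox <- which(odf@mask)
  peakDirs <- array(NaN, c(dims, maxPeaks, 3))
  peakAmp <- array(NaN, c(dims, maxPeaks))
  nPeaks <- array(0L, dims)
  iso <- array(NaN, dims)
  degen <- array(FALSE, dims)
  nv <- prod(dims)
  for (i in seq_len(nvx)) {
    vals <- M[i, ]
    iso[vox[i]] <- min(vals)
    if (flat[i]) {
      degen[vox[i]] <- TRUE
      cand <- lex[1]
    } else {
      cand <- which(isMax[i, ])
      if (length(cand) == 0) cand <- which.max(vals)
      cand <- cand[order(-vals[cand], lexRank[cand])]
    }
    kept <- integer(0)
    for (c0 in cand) {
      if (length(kept) == maxPeaks) break
      if (length(kept) == 0 ||
          all(abs(v[kept, , drop = FALSE] %*% v[c0, ]) < cosSep))
        kept <- c(kept, c0)
    }
    nPeaks[vox[i]] <- length(kept)
    for (p in seq_along(kept)) {
      peakAmp[vox[i] + (p - 1) * nv] <- vals[kept[p]]
      pd <- if (flat[i]) v[kept[p], ] else
        refinePeakDirection(vals, sph, kept[p])
      for (cc in 1:3)
        peakDirs[vox[i] + ((cc - 1) * maxPeaks + (p - 1)) * nv] <- pd[cc]
    }
  }
  new("PeakField", peakDirs = peakDirs, peakAmp = peakAmp, nPeaks = nPeaks,
      iso = iso, degenerate = degen, mask = odf@mask, sphere = sph)
}

#' Quantitative anisotropy and the normalized QA map
#'
#' QA(u) = Z0 (psi(u) - I_psi), where I_psi is the voxel's isotropic ODF
#' level (its minimum over the sphere samples) and Z0 = 1 / max over the
#' volume of I_psi. The NQA map divides the largest-peak QA by its
#' volume-wide maximum, so max(NQA) = 1 exactly.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @return list: \code{nqa} (\linkS4class{ScalarMap}), \code{qa} (4D array
#'   of per-peak QA), \code{z0}, \code{isoMax}.
#' @export
qaNQA <- function(peaks) {
  vox <- which(peaks@mask)
  if (length(vox) == 0) stop("empty mask: QA is undefined")
  dimsM <- dim(peaks@mask)
  nvTot <- prod(dimsM)
  P <- dim(peaks@peakAmp)[4]
  ampM <- matrix(NaN, length(vox), P)
  for (p in seq_len(P)) ampM[, p] <- peaks@peakAmp[vox + (p - 1) * nvTot]
  isoVals <- peaks@iso[vox]
  if (all(c(isoVals, ampM[, 1]) == 0, na.rm = TRUE))
    stop("all-zero ODF volume: QA is undefined")
  isoMax <- max(isoVals)
  z0 <- if (isoMax > 0) 1 / isoMax else 1
  qa <- z0 * sweep(ampM, 1, isoVals, "-")
  qa[!is.na(qa) & qa < 0] <- 0
  qa1 <- qa[, 1]
  qaMax <- max(qa1, na.rm = TRUE)
  if (qaMax <= 0) stop("volume has no ODF peak contrast: NQA is undefined")
  dims <- dim(peaks@mask)
  nqaVals <- array(NaN, dims)
  nqaVals[vox] <- qa1 / qaMax
  qaArr <- array(NaN, c(dims, ncol(qa)))
  nv <- prod(dims)
  for (p in seq_len(ncol(qa))) qaArr[vox + (p - 1) * nv] <- qa[, p]
  list(nqa = scalarMap("NQA", nqaVals, peaks@mask), qa = qaArr, z0 = z0,
       isoMax = isoMax)
}
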