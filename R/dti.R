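#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(3/2) * sqrt(sum_i (lambda_i - MD)^2) / sqrt(sum_i lambda_i^2),
#' with FA defined as 0 when all eigenvalues are 0.
#'
#' @param lam matrix, one row of 3 eigenvalues per voxel.
#' @return numeric vector of FA values in [0, 1].
#' @export
faFromEigenvalues <- function(lam) {
  md <- rowMeans(lam)
  num <- (lam[, 1] - md)^2 + (lam[, 2] - md)^2 + (lam[, 3] - md)^2
  den <- rowSums(lam^2)
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  pmin(fa, 1)
}

# tensor design matrix: log S = X beta with
# beta = (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensorDesign <- function(gtab) {
  g <- gtab@directions
  b <- gtab@bvalues
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by weighted least squares
#'
#' Fits log S = log S0 - b g' D g per voxel: an ordinary least-squares pass
#' followed by one reweighting pass with weights equal to the squared
#' predicted signal (the standard WLS estimator for log-linearized tensor
#' fits). All included volumes are fit jointly, whatever shells they come
#' from. Nonpositive signal samples are floored at a small positive value
#' and counted; negative eigenvalues are clamped at zero and counted.
#'
#' @param dataset a \linkS4class{DWIDataset} with at least 6 unique weighted
#'   directions and one b0 volume.
#' @param mask optional logical 3D array restricting the fit.
#' @return a \linkS4class{TensorField}.
#' @export
fitTensor <- function(dataset, mask = NULL) {
  gt <- dataset@gtab
  n <- length(gt)
  if (n < 7) stop("tensor fit needs at least 7 usable volumes")
  w <- gt@shellId > 0L
  uniqDirs <- unique(round(canonicalizeDirections(
    gt@directions[w, , drop = FALSE]), 6))
  if (nrow(uniqDirs) < 6 || !any(!w))
    stop("tensor fit needs >= 6 unique weighted directions and >= 1 b0")
  dims <- dim(dataset@signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  X <- tensorDesign(gt)
  vox <- which(mask)
  S <- matrix(aperm(dataset@signal, c(4, 1, 2, 3)), n)[, vox, drop = FALSE]

  floorVal <- pmax(apply(S, 2, max), .Machine$double.eps) * 1e-8
  bad <- S <= 0
  nFloored <- sum(bad)
  if (nFloored > 0) S <- pmax(S, rep(floorVal, each = n))
  Y <- log(S)

  betaOLS <- solve(crossprod(X), crossprod(X, Y))
  pred2 <- exp(2 * (X %*% betaOLS))
  beta <- matrix(0, 7, length(vox))
  for (j in seq_along(vox)) {
    Xw <- X * pred2[, j]
    beta[, j] <- solve(crossprod(Xw, X), crossprod(Xw, Y[, j]))
  }

  evals <- array(NaN, c(dims, 3))
  evecs <- array(NaN, c(dims, 3, 3))
  logS0 <- array(NaN, dims)
  nClamped <- 0L
  ev3 <- matrix(0, length(vox), 3)
  ec3 <- array(0, c(length(vox), 3, 3))
  for (j in seq_along(vox)) {
    b <- beta[, j]
    D <- matrix(c(b[2], b[5], b[6], b[5], b[3], b[7], b[6], b[7], b[4]), 3, 3)
    ed <- eigen(D, symmetric = TRUE)
    lam <- ed$values
    nClamped <- nClamped + sum(lam < 0)
    ev3[j, ] <- pmax(lam, 0)
    ec3[j, , ] <- t(ed$vectors)     # row m = m-th eigenvector
  }
  nv <- prod(dims)
  for (m in 1:3) {
    evals[vox + (m - 1) * nv] <- ev3[, m]
    for (cc in 1:3)
      evecs[vox + ((m - 1) * 3 + (cc - 1)) * nv] <- ec3[, m, cc]
  }
  logS0[vox] <- beta[1, ]
  new("TensorField", evals = evals, evecs = evecs, logS0 = logS0,
      mask = mask, nClamped = as.integer(nClamped),
      nFloored = as.integer(nFloored))
}

#' Tensor-derived scalar maps
#'
#' FA (fractional anisotropy), MD = (l1+l2+l3)/3 (mean diffusivity),
#' RD = (l2+l3)/2 (radial diffusivity) and AX = l1 (axial diffusivity)
#' from a fitted tensor field.
#'
#' @param tf a \linkS4class{TensorField}.
#' @return named list of \linkS4class{ScalarMap}s: FA, MD, RD, AX.
#' @export
tensorScalars <- function(tf) {
  dims <- dim(tf@mask)
  vox <- which(tf@mask)
  lam <- cbind(tf@evals[, , , 1][vox], tf@evals[, , , 2][vox],
               tf@evals[, , , 3][vox])
  mk <- function(name, vals) {
    a <- array(NaN, dims); a[vox] <- vals
    scalarMap(name, a, tf@mask)
  }
  list(FA = mk("FA", faFromEigenvalues(lam)),
       MD = mk("MD", rowMeans(lam)),
       RD = mk("RD", (lam[, 2] + lam[, 3]) / 2),
       AX = mk("AX", lam[, 1]))
}
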