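#' Subdivided-icosahedron sampling grid on the sphere
#'
#' Builds an antipodally symmetric tessellation of the unit sphere by
#' repeated edge-midpoint subdivision of the icosahedron, then keeps one
#' canonical representative per antipodal pair (first nonzero coordinate
#' positive). Neighbor relations follow the triangulation edges, with each
#' neighbor mapped to its canonical representative, so local-maximum tests
#' on the hemisphere honor the implicit antipodal symmetry of ODFs.
#'
#' @param subdivisions number of binary subdivision passes; 3 gives 642 full
#'   sphere vertices, i.e. 321 hemisphere directions (the default grid).
#' @return a \linkS4class{SphereGrid}.
#' @export
sphereGrid <- function(subdivisions = 3) {
  ico <- icosphere(subdivisions)
  v <- ico$vertices
  canon <- canonicalHemisphere(v)
  keep <- which(canon$isCanonical)
  # map every full-sphere vertex to the index (within `keep`) of its
  # canonical representative
  rep2keep <- integer(nrow(v))
  rep2keep[keep] <- seq_along(keep)
  full2hemi <- rep2keep[canon$pairIndex]

  edges <- ico$edges
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(v))
  k <- max(deg)
  nb <- matrix(NA_integer_, nrow(v), k)
  cnt <- integer(nrow(v))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    cnt[a] <- cnt[a] + 1L; nb[a, cnt[a]] <- b
    cnt[b] <- cnt[b] + 1L; nb[b, cnt[b]] <- a
  }
  hemiNb <- matrix(NA_integer_, length(keep), k)
  for (i in seq_along(keep)) {
    row <- nb[keep[i], ]
    row <- full2hemi[row[!is.na(row)]]
    row <- unique(row[row != i])
    hemiNb[i, seq_along(row)] <- row
  }
  # pad with self index so matrix ops are total
  for (j in seq_len(ncol(hemiNb))) {
    miss <- is.na(hemiNb[, j])
    hemiNb[miss, j] <- which(miss)
  }
  verts <- v[keep, , drop = FALSE]
  # angular resolution: largest neighbor step (antipodally folded)
  maxEdge <- 0
  for (j in seq_len(ncol(hemiNb))) {
    d <- abs(rowSums(verts * verts[hemiNb[, j], , drop = FALSE]))
    ang <- acos(pmin(1, d)) * 180 / pi
    sel <- hemiNb[, j] != seq_len(nrow(verts))
    if (any(sel)) maxEdge <- max(maxEdge, ang[sel])
  }
  new("SphereGrid", vertices = verts, neighbors = hemiNb, maxEdgeDeg = maxEdge)
}

# Icosahedron subdivision; returns unit vertices and the unique edge list.
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # derive the 20 faces from mutual adjacency (icosahedron edges are the
  # shortest inter-vertex distances)
  dmat <- as.matrix(stats::dist(v))
  edgeLen <- min(dmat[dmat > 1e-9])
  adj <- dmat < edgeLen + 1e-9 & dmat > 1e-9
  f <- NULL
  for (a in 1:10) for (b in (a + 1):11) for (c0 in (b + 1):12)
    if (adj[a, b] && adj[b, c0] && adj[a, c0]) f <- rbind(f, c(a, b, c0))
  storage.mode(f) <- "integer"
  for (s in seq_len(subdivisions)) {
    midCache <- new.env(hash = TRUE)
    newFaces <- matrix(0L, 4 * nrow(f), 3)
    getMid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midCache[[key]]
      if (!is.null(idx)) return(idx)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      midCache[[key]] <- idx
      idx
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c0 <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, c0); ca <- getMid(c0, a)
      newFaces[4 * i - 3, ] <- c(a, ab, ca)
      newFaces[4 * i - 2, ] <- c(b, bc, ab)
      newFaces[4 * i - 1, ] <- c(c0, ca, bc)
      newFaces[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newFaces
  }
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  list(vertices = v, faces = f, edges = e)
}

# Canonical hemisphere selection: a vector is canonical when its first
# nonzero coordinate (x, then y, then z order) is positive. pairIndex maps
# each vertex to the index of the canonical member of its antipodal pair.
canonicalHemisphere <- function(v, tol = 1e-9) {
  isCanon <- apply(v, 1, function(u) {
    for (c0 in u) if (abs(c0) > tol) return(c0 > 0)
    TRUE
  })
  pairIndex <- integer(nrow(v))
  canonIdx <- which(isCanon)
  cv <- v[canonIdx, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    if (isCanon[i]) { pairIndex[i] <- i; next }
    d <- cv %*% (-v[i, ])
    j <- which.max(d)
    if (d[j] < 1 - 1e-6) stop("sphere grid is not antipodally symmetric")
    pairIndex[i] <- canonIdx[j]
  }
  list(isCanonical = isCanon, pairIndex = pairIndex)
}

# Canonicalize direction vectors (rows): flip sign so the first nonzero
# component is positive.
canonicalizeDirections <- function(d, tol = 1e-12) {
  s <- sign(d[, 1])
  use2 <- abs(d[, 1]) <= tol
  s[use2] <- sign(d[use2, 2])
  use3 <- use2 & abs(d[, 2]) <= tol
  s[use3] <- sign(d[use3, 3])
  s[s == 0] <- 1
  d * s
}
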