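#' @import methods
NULL

#' Gradient table for a multi-shell acquisition
#'
#' Per-volume diffusion weightings and unit gradient directions, with an
#' integer shell label per volume (0 denotes the unweighted b0 volumes).
#' The shell labels are consistent with clustering of the b-values and are
#' numbered in ascending b order.
#'
#' @slot bvalues numeric vector of b-values in s/mm^2, one per volume.
#' @slot directions numeric matrix, n x 3, unit gradient directions for
#'   weighted volumes (rows for b0 volumes are zero).
#' @slot shellId integer vector, shell label per volume (0 = b0).
#' @slot shellBvalues numeric vector of distinct nonzero shell centers,
#'   ascending; \code{shellBvalues[i]} is the center of shell \code{i}.
#' @slot metadata list of optional acquisition metadata (e.g. the gradient
#'   pulse timings \code{smallDelta}, \code{bigDelta} in ms, TE).
#' @export
setClass("GradientTable",
  representation(bvalues = "numeric", directions = "matrix",
                 shellId = "integer", shellBvalues = "numeric",
                 metadata = "list"))

setValidity("GradientTable", function(object) {
  n <- length(object@bvalues)
  if (nrow(object@directions) != n || ncol(object@directions) != 3)
    return("directions must be an n x 3 matrix matching bvalues")
  if (length(object@shellId) != n)
    return("shellId must have one entry per volume")
  if (!any(object@shellId == 0L))
    return("at least one b0 volume is required")
  w <- object@shellId > 0L
  if (any(w)) {
    nrm <- sqrt(rowSums(object@directions[w, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("weighted gradient directions must be unit vectors")
  }
  if (is.unsorted(object@shellBvalues, strictly = TRUE))
    return("shellBvalues must be strictly increasing")
  TRUE
})

#' A 4D diffusion-weighted dataset
#'
#' The container consumed by every reconstruction: a 4D signal array
#' (x, y, z, volume), grid geometry, and the matching gradient table.
#'
#' @slot signal 4D numeric array of nonnegative signal values.
#' @slot voxelSize numeric length-3 voxel dimensions in mm.
#' @slot affine 4x4 voxel-to-physical (mm) transform.
#' @slot gtab a \linkS4class{GradientTable} whose length equals dim 4.
#' @export
setClass("DWIDataset",
  representation(signal = "array", voxelSize = "numeric",
                 affine = "matrix", gtab = "GradientTable"))

setValidity("DWIDataset", function(object) {
  d <- dim(object@signal)
  if (length(d) != 4) return("signal must be a 4D array")
  if (d[4] != length(object@gtab@bvalues))
    return("4th dimension must equal the gradient-table length")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (mm)")
  if (!all(dim(object@affine) == c(4, 4)) ||
      abs(det(object@affine)) < .Machine$double.eps)
    return("affine must be an invertible 4x4 matrix")
  TRUE
})

#' Discrete sampling grid on the unit sphere
#'
#' An antipodally symmetric subdivided-icosahedron tessellation represented
#' on one hemisphere (first nonzero coordinate positive), with a neighbor
#' graph used for ODF local-maximum tests. \code{maxEdgeDeg} is the largest
#' angular step between neighboring vertices, i.e. the grid's angular
#' resolution.
#'
#' @slot vertices m x 3 unit vectors (canonical hemisphere representatives).
#' @slot neighbors m x k integer matrix of neighbor indices (padded with the
#'   vertex's own index where degree < k).
#' @slot maxEdgeDeg largest neighbor-to-neighbor angle, degrees.
#' @export
setClass("SphereGrid",
  representation(vertices = "matrix", neighbors = "matrix",
                 maxEdgeDeg = "numeric"))

setValidity("SphereGrid", function(object) {
  if (ncol(object@vertices) != 3) return("vertices must be m x 3")
  if (nrow(object@vertices) < 100)
    return("at least 100 hemisphere directions are required")
  nrm <- sqrt(rowSums(object@vertices^2))
  if (any(abs(nrm - 1) > 1e-8)) return("vertices must be unit vectors")
  if (nrow(object@neighbors) != nrow(object@vertices))
    return("neighbor rows must match vertices")
  TRUE
})

#' Per-voxel diffusion tensor eigen-system
#'
#' @slot evals 4D array (x, y, z, 3) of eigenvalues, sorted descending,
#'   clamped at zero (mm^2/s).
#' @slot evecs 5D array (x, y, z, 3, 3); \code{evecs[i,j,k, ,m]} is the m-th
#'   eigenvector.
#' @slot logS0 3D array of fitted log S0.
#' @slot mask logical 3D array of fitted voxels.
#' @slot nClamped number of negative eigenvalues clamped to zero.
#' @slot nFloored number of nonpositive signal samples floored before log.
#' @export
setClass("TensorField",
  representation(evals = "array", evecs = "array", logS0 = "array",
                 mask = "array", nClamped = "integer", nFloored = "integer"))

#' A named 3D scalar map
#'
#' @slot name one of FA, MD, RD, AX, GFA, NQA (or any label).
#' @slot values 3D numeric array; NaN outside the mask.
#' @slot mask logical 3D array.
#' @export
setClass("ScalarMap",
  representation(name = "character", values = "array", mask = "array"))

setValidity("ScalarMap", function(object) {
  if (length(dim(object@values)) != 3) return("values must be 3D")
  if (!identical(dim(object@values), dim(object@mask)))
    return("mask must match values dimensions")
  TRUE
})

#' Per-voxel, per-shell spherical harmonic coefficients
#'
#' Real symmetric (even-order) SH coefficients of the normalized diffusion
#' signal, one coefficient block per q-space shell.
#'
#' @slot coefs list, one 4D array (x, y, z, nCoef) per shell.
#' @slot shellBvalues b-value of each shell block.
#' @slot order maximum (even) SH order used per shell.
#' @slot lambda Laplace-Beltrami regularization weight.
#' @slot mask logical 3D array.
#' @export
setClass("SHField",
  representation(coefs = "list", shellBvalues = "numeric", order = "integer",
                 lambda = "numeric", mask = "array"))

#' Sampled orientation distribution functions
#'
#' @slot odf 4D array (x, y, z, m) of ODF amplitudes on the hemisphere grid
#'   (antipodal symmetry is implicit), floored at zero.
#' @slot sphere the \linkS4class{SphereGrid} the amplitudes live on.
#' @slot mask logical 3D array.
#' @slot nNegative number of negative samples floored at zero.
#' @export
setClass("ODFField",
  representation(odf = "array", sphere = "SphereGrid", mask = "array",
                 nNegative = "integer"))

#' ODF local maxima with amplitudes and isotropic level
#'
#' @slot peakDirs 5D array (x, y, z, maxPeaks, 3) of unit peak directions
#'   (NaN where fewer peaks).
#' @slot peakAmp 4D array (x, y, z, maxPeaks) of ODF amplitudes at the peaks,
#'   sorted descending.
#' @slot nPeaks integer 3D array of retained peak counts.
#' @slot iso 3D array, per-voxel isotropic ODF level (minimum over the grid).
#' @slot degenerate logical 3D array flagging flat-ODF voxels.
#' @slot mask logical 3D array.
#' @slot sphere the grid peaks were extracted on.
#' @export
setClass("PeakField",
  representation(peakDirs = "array", peakAmp = "array", nPeaks = "array",
                 iso = "array", degenerate = "array", mask = "array",
                 sphere = "SphereGrid"))

#' Per-voxel dominant fiber direction
#'
#' @slot dirs 4D array (x, y, z, 3) of unit directions, canonicalized so the
#'   first nonzero component is positive; NaN at excluded voxels.
#' @slot mask logical 3D array of voxels carrying a direction.
#' @slot source "DTI" or "QBI".
#' @slot scheme cumulative shell count k the reconstruction used.
#' @slot nExcluded degenerate voxels dropped from the input mask.
#' @export
setClass("DirectionField",
  representation(dirs = "array", mask = "array", source = "character",
                 scheme = "integer", nExcluded = "integer"))

#' Angular deviation between two direction fields
#'
#' @slot theta 3D array of inner angles in degrees, in [0, 90]; NaN outside
#'   the evaluated mask.
#' @slot roiMean mean angle over the evaluated voxels.
#' @slot roiMax maximum angle over the evaluated voxels.
#' @slot scheme shell-scheme code of the target field.
#' @slot nVoxels voxels entering the mean.
#' @export
setClass("DeviationResult",
  representation(theta = "array", roiMean = "numeric", roiMax = "numeric",
                 scheme = "integer", nVoxels = "integer"))

#' A set of streamlines
#'
#' @slot streamlines list of p x 3 matrices of points in physical mm
#'   coordinates.
#' @slot stepMm integration step length.
#' @slot termination data.frame with one row per streamline: termination
#'   reason at each end and length in mm.
#' @slot params the tracking parameter list used.
#' @export
setClass("Tractogram",
  representation(streamlines = "list", stepMm = "numeric",
                 termination = "data.frame", params = "list"))

#' @describeIn GradientTable number of volumes
#' @param x object
#' @export
setMethod("length", "GradientTable", function(x) length(x@bvalues))

setMethod("show", "GradientTable", function(object) {
  ns <- length(object@shellBvalues)
  cat(sprintf("GradientTable: %d volumes (%d b0, %d shells: %s s/mm^2)\n",
              length(object@bvalues), sum(object@shellId == 0L), ns,
              paste(object@shellBvalues, collapse = ", ")))
})

setMethod("show", "DWIDataset", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DWIDataset: %d x %d x %d grid, %d volumes, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  show(object@gtab)
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("ScalarMap '%s': %s grid, %d in-mask voxels, range [%.4g, %.4g]\n",
              object@name, paste(dim(object@values), collapse = " x "),
              sum(object@mask), min(v), max(v)))
})

setMethod("show", "SphereGrid", function(object) {
  cat(sprintf("SphereGrid: %d hemisphere directions, max edge %.2f deg\n",
              nrow(object@vertices), object@maxEdgeDeg))
})

setMethod("show", "TensorField", function(object) {
  cat(sprintf("TensorField: %s grid, %d fitted voxels (%d eigenvalues clamped)\n",
              paste(dim(object@mask), collapse = " x "), sum(object@mask),
              object@nClamped))
})

setMethod("show", "Tractogram", function(object) {
  len <- vapply(object@streamlines, nrow, integer(1))
  cat(sprintf("Tractogram: %d streamlines, step %.3f mm, mean %.1f points\n",
              length(object@streamlines), object@stepMm, mean(len)))
})

setMethod("show", "DirectionField", function(object) {
  cat(sprintf("DirectionField (%s, %d-shell): %d voxels, %d excluded\n",
              object@source, object@scheme, sum(object@mask), object@nExcluded))
})

setMethod("show", "DeviationResult", function(object) {
  cat(sprintf("DeviationResult (%d-shell vs reference): mean %.2f deg, max %.2f deg over %d voxels\n",
              object@scheme, object@roiMean, object@roiMax, object@nVoxels))
})

# ---- accessors ----

#' Accessors for the core containers
#'
#' @param object a \linkS4class{GradientTable}, \linkS4class{DWIDataset},
#'   \linkS4class{ScalarMap} or other hydikit object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bvalues", function(object) standardGeneric("bvalues"))
#' @rdname accessors
#' @export
setMethod("bvalues", "GradientTable", function(object) object@bvalues)
#' @rdname accessors
#' @export
setMethod("bvalues", "DWIDataset", function(object) object@gtab@bvalues)

#' @rdname accessors
#' @export
setGeneric("gradDirections", function(object) standardGeneric("gradDirections"))
#' @rdname accessors
#' @export
setMethod("gradDirections", "GradientTable", function(object) object@directions)
#' @rdname accessors
#' @export
setMethod("gradDirections", "DWIDataset", function(object) object@gtab@directions)

#' @rdname accessors
#' @export
setGeneric("shellIds", function(object) standardGeneric("shellIds"))
#' @rdname accessors
#' @export
setMethod("shellIds", "GradientTable", function(object) object@shellId)
#' @rdname accessors
#' @export
setMethod("shellIds", "DWIDataset", function(object) object@gtab@shellId)

#' @rdname accessors
#' @export
setGeneric("gradientTable", function(object) standardGeneric("gradientTable"))
#' @rdname accessors
#' @export
setMethod("gradientTable", "DWIDataset", function(object) object@gtab)

#' @rdname accessors
#' @export
setGeneric("signalArray", function(object) standardGeneric("signalArray"))
#' @rdname accessors
#' @export
setMethod("signalArray", "DWIDataset", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "DWIDataset", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "ScalarMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mapMask", function(object) standardGeneric("mapMask"))
#' @rdname accessors
#' @export
setMethod("mapMask", "ScalarMap", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("streamlines", function(object) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setMethod("streamlines", "Tractogram", function(object) object@streamlines)

#' Construct a ScalarMap
#'
#' @param name map label (FA, MD, RD, AX, GFA, NQA, ...).
#' @param values 3D numeric array.
#' @param mask logical 3D array; values outside are set to NaN.
#' @return a \linkS4class{ScalarMap}.
#' @export
scalarMap <- function(name, values, mask) {
  values[!mask] <- NaN
  new("ScalarMap", name = name, values = values, mask = mask)
}
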