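#' Cluster b-values into shells
#'
#' Values at or below \code{b0Tol} are labeled shell 0. Remaining values are
#' clustered: if \code{centers} is not given, distinct weighted b-values are
#' grouped by single-linkage with gap \code{shellTol} and each cluster's mean
#' becomes its center. Every value is then assigned to its nearest center;
#' a value farther than \code{shellTol} from every center is an error.
#' Labels ascend with b.
#'
#' @param bvalues numeric vector of b-values (s/mm^2).
#' @param b0Tol values <= this are treated as b0 (default 50 s/mm^2).
#' @param shellTol clustering tolerance (default 100 s/mm^2).
#' @param centers optional declared shell centers.
#' @return list with \code{shellId} (integer labels, 0 = b0) and
#'   \code{shellBvalues} (ascending cluster centers).
#' @export
detectShells <- function(bvalues, b0Tol = 50, shellTol = 100, centers = NULL) {
  if (shellTol <= 0) stop("shellTol must be positive")
  shellId <- integer(length(bvalues))
  weighted <- bvalues > b0Tol
  if (!any(weighted))
    return(list(shellId = shellId, shellBvalues = numeric(0)))
  if (is.null(centers)) {
    u <- sort(unique(bvalues[weighted]))
    grp <- cumsum(c(1, diff(u) > shellTol))
    centers <- as.numeric(tapply(u, grp, mean))
  }
  centers <- sort(centers)
  bw <- bvalues[weighted]
  nearest <- max.col(-abs(outer(bw, centers, "-")), ties.method = "first")
  off <- abs(bw - centers[nearest])
  if (any(off > shellTol))
    stop(sprintf("b-value %g is farther than %g from every shell center",
                 bw[which.max(off)], shellTol))
  shellId[weighted] <- nearest
  list(shellId = shellId, shellBvalues = centers)
}

#' Construct a GradientTable from raw b-values and directions
#'
#' Shells are detected with \code{\link{detectShells}}; weighted directions
#' that are not unit length are renormalized with a warning.
#'
#' @param bvalues numeric vector, one per volume.
#' @param directions n x 3 matrix of gradient directions.
#' @param b0Tol,shellTol see \code{\link{detectShells}}.
#' @param metadata optional list (delta, Delta, TE).
#' @return a \linkS4class{GradientTable}.
#' @export
makeGradientTable <- function(bvalues, directions, b0Tol = 50,
                              shellTol = 100, metadata = list()) {
  if (nrow(directions) != length(bvalues))
    stop("gradient table length mismatch: ", length(bvalues), " b-values vs ",
         nrow(directions), " directions")
  sh <- detectShells(bvalues, b0Tol = b0Tol, shellTol = shellTol)
  w <- sh$shellId > 0L
  if (any(w)) {
    nrm <- sqrt(rowSums(directions[w, , drop = FALSE]^2))
    if (any(nrm <= 0)) stop("weighted volume with zero gradient direction")
    if (any(abs(nrm - 1) > 1e-4)) {
      warning("renormalizing non-unit gradient directions")
    }
    directions[w, ] <- directions[w, , drop = FALSE] / nrm
  }
  new("GradientTable", bvalues = as.numeric(bvalues), directions = directions,
      shellId = as.integer(sh$shellId), shellBvalues = sh$shellBvalues,
      metadata = metadata)
}

#' Read / write a DWI dataset
#'
#' FSL-dialect gradient files: \code{bvals} is one whitespace-separated row
#' of b-values and \code{bvecs} three rows (x, y, z components), one column
#' per volume. The 4D signal is stored as NIfTI-1. Directions are expressed
#' in the frame of the affine's rotation; voxel indices are 0-based in
#' physical-coordinate computations.
#'
#' @param niftiPath path to the 4D NIfTI file.
#' @param bvalsPath,bvecsPath paths to the gradient text files.
#' @param b0Tol,shellTol passed to \code{\link{detectShells}}.
#' @return a \linkS4class{DWIDataset}.
#' @export
readDWIDataset <- function(niftiPath, bvalsPath, bvecsPath,
                           b0Tol = 50, shellTol = 100) {
  img <- RNifti::readNifti(niftiPath)
  signal <- array(as.numeric(img), dim = dim(img))
  if (length(dim(signal)) == 3) dim(signal) <- c(dim(signal), 1)
  bvals <- scan(bvalsPath, quiet = TRUE)
  bvecs <- unname(as.matrix(utils::read.table(bvecsPath)))
  if (nrow(bvecs) != 3)
    stop("bvecs must have exactly 3 rows (x, y, z components)")
  if (ncol(bvecs) != length(bvals) || length(bvals) != dim(signal)[4])
    stop("gradient table length mismatch: ", dim(signal)[4], " volumes, ",
         length(bvals), " b-values, ", ncol(bvecs), " direction columns")
  gtab <- makeGradientTable(bvals, t(bvecs), b0Tol = b0Tol,
                            shellTol = shellTol)
  aff <- structure(RNifti::xform(img), class = "matrix")
  new("DWIDataset", signal = signal,
      voxelSize = as.numeric(RNifti::pixdim(img))[1:3],
      affine = matrix(as.numeric(aff), 4, 4), gtab = gtab)
}

#' @rdname readDWIDataset
#' @param dataset a \linkS4class{DWIDataset}.
#' @return \code{writeDWIDataset} invisibly returns the paths written.
#' @export
writeDWIDataset <- function(dataset, niftiPath, bvalsPath, bvecsPath) {
  img <- RNifti::asNifti(dataset@signal)
  RNifti::pixdim(img) <- c(dataset@voxelSize, 1)  # 4th dim is volume index
  RNifti::qform(img) <- structure(dataset@affine, code = 2L)
  RNifti::writeNifti(img, niftiPath, datatype = "double")
  writeLines(paste(formatC(dataset@gtab@bvalues, format = "fg"),
                   collapse = " "), bvalsPath)
  bv <- t(dataset@gtab@directions)
  writeLines(apply(bv, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " ")), bvecsPath)
  invisible(c(niftiPath, bvalsPath, bvecsPath))
}

#' Write / read a 3D scalar map as NIfTI-1
#'
#' @param map a \linkS4class{ScalarMap}.
#' @param path output file.
#' @param affine optional 4x4 voxel-to-mm transform.
#' @return the path, invisibly.
#' @export
writeScalarMap <- function(map, path, affine = diag(4)) {
  img <- RNifti::asNifti(map@values)
  RNifti::pixdim(img) <- diag(affine)[1:3]
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Cumulative shell-subset scheme
#'
#' The k-shell scheme keeps the k smallest distinct nonzero b-values:
#' 1-shell is the lowest shell alone, 2-shell adds the next, and so on.
#'
#' @slot k integer 1..number of shells.
#' @slot includedBvalues the k smallest shell b-values, ascending.
#' @export
setClass("ShellScheme",
  representation(k = "integer", includedBvalues = "numeric"))

#' @rdname ShellScheme-class
#' @param k cumulative shell count.
#' @param gtab a \linkS4class{GradientTable} (or numeric vector of shell
#'   b-values).
#' @return a \linkS4class{ShellScheme}.
#' @export
shellScheme <- function(k, gtab) {
  sb <- if (is(gtab, "GradientTable")) gtab@shellBvalues else sort(gtab)
  k <- as.integer(k)
  if (k < 1L || k > length(sb))
    stop("scheme k = ", k, " is out of range (1..", length(sb), ")")
  new("ShellScheme", k = k, includedBvalues = sb[seq_len(k)])
}

setMethod("show", "ShellScheme", function(object) {
  cat(sprintf("%d-shell scheme: b = %s s/mm^2\n", object@k,
              paste(object@includedBvalues, collapse = ", ")))
})

#' Select a cumulative shell subset of a dataset
#'
#' Retains all b0 volumes plus every volume whose shell rank is at most k,
#' preserving volume order, so the k-shell volume set nests inside the
#' (k+1)-shell set.
#'
#' @param dataset a \linkS4class{DWIDataset}.
#' @param scheme a \linkS4class{ShellScheme} or an integer k.
#' @return a \linkS4class{DWIDataset} restricted to the scheme.
#' @export
selectSubset <- function(dataset, scheme) {
  if (!is(scheme, "ShellScheme"))
    scheme <- shellScheme(scheme, dataset@gtab)
  k <- scheme@k
  gt <- dataset@gtab
  if (k > length(gt@shellBvalues))
    stop("scheme k = ", k, " exceeds the ", length(gt@shellBvalues),
         " shells present")
  keep <- which(gt@shellId <= k)
  newGt <- new("GradientTable", bvalues = gt@bvalues[keep],
               directions = gt@directions[keep, , drop = FALSE],
               shellId = gt@shellId[keep],
               shellBvalues = gt@shellBvalues[seq_len(k)],
               metadata = gt@metadata)
  new("DWIDataset",
      signal = dataset@signal[, , , keep, drop = FALSE],
      voxelSize = dataset@voxelSize, affine = dataset@affine, gtab = newGt)
}
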