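#' End-to-end experiment configuration
#'
#' Describes a full synthetic study: three pseudo-subjects "aged" 10, 15
#' and 24 months are simulated with the 5-shell acquisition, reconstructed
#' under every cumulative shell scheme with both DTI and QBI, and the
#' shell trends, angular deviations and tractography are computed.
#'
#' @param acquisition an \linkS4class{AcquisitionSpec}.
#' @param ages subject age codes (each in 10, 15, 24).
#' @param schemes cumulative shell counts to reconstruct (default all).
#' @param shOrder,shLambda SH order and regularization for QBI.
#' @param sphereSubdivisions icosphere subdivision level.
#' @param S0,noiseSigmaFrac signal level and Rician sigma as a fraction of
#'   S0.
#' @param declinePerStep anisotropy-ratio shrinkage per age step.
#' @param trackingMaps stopping maps to run tractography with.
#' @param targetFiberCount streamlines per tractography run.
#' @param smoothFwhm Gaussian FWHM (voxels) before the voxel-wise
#'   regression.
#' @param fdrQ FDR level for the voxel-wise analysis.
#' @param masterSeed master seed; all stage seeds derive from it by fixed
#'   offsets.
#' @return a named list (class "hydiExperimentConfig").
#' @export
experimentConfig <- function(acquisition = acquisitionSpec(),
                             ages = c(10, 15, 24),
                             schemes = NULL,
                             shOrder = 8, shLambda = 0.006,
                             sphereSubdivisions = 3,
                             S0 = 100, noiseSigmaFrac = 1 / 55,
                             declinePerStep = 0.1,
                             trackingMaps = c("FA", "NQA"),
                             targetFiberCount = 300,
                             smoothFwhm = 3, fdrQ = 0.05,
                             masterSeed = 1) {
  nShells <- length(acquisition@shellBvalues)
  if (is.null(schemes)) schemes <- seq_len(nShells)
  if (any(schemes < 1 | schemes > nShells))
    stop("requested schemes exceed the available shells")
  structure(list(acquisition = acquisition, ages = ages,
                 schemes = sort(unique(as.integer(schemes))),
                 shOrder = shOrder, shLambda = shLambda,
                 sphereSubdivisions = sphereSubdivisions, S0 = S0,
                 noiseSigmaFrac = noiseSigmaFrac,
                 declinePerStep = declinePerStep,
                 trackingMaps = trackingMaps,
                 targetFiberCount = as.integer(targetFiberCount),
                 smoothFwhm = smoothFwhm, fdrQ = fdrQ,
                 masterSeed = as.integer(masterSeed)),
            class = "hydiExperimentConfig")
}

# round a numeric tree for byte-stable JSON
roundTree <- function(x, digits = 8) {
  if (is.list(x)) return(lapply(x, roundTree, digits = digits))
  if (is.numeric(x)) return(round(x, digits))
  x
}

#' Run the full synthetic multi-shell experiment
#'
#' Generates the aged phantoms, reconstructs every requested cumulative
#' shell scheme with DTI and QBI, computes ROI-mean shell trends of FA,
#' MD, RD, AX (bundle), GFA and NQA, gray-matter trends, the angular
#' deviation of each scheme against the full 5-shell reconstruction for
#' both models, per-shell SNR, anisotropy-aided tractography with the
#' protocol threshold table, and a voxel-wise FA shell regression with
#' FDR correction. Deterministic for a fixed master seed.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param outDir optional output directory; when given, maps (NIfTI),
#'   tables (CSV), tracts (.trk), \code{report.json} and a separate
#'   \code{timings.csv} are written under it.
#' @param verbose print stage progress.
#' @return the report (a nested list), invisibly when \code{outDir} is
#'   given.
#' @export
runExperiment <- function(config, outDir = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
    if (verbose) message(sprintf("[%s] %.1fs", stage, timings[[stage]]))
  }
  acq <- config$acquisition
  nShells <- length(acq@shellBvalues)
  refK <- max(config$schemes)
  sphere <- sphereGrid(config$sphereSubdivisions)

  subjects <- lapply(seq_along(config$ages), function(i) {
    spec <- phantomSpec(acquisition = acq,
                        compartments = tissueCompartments(
                          config$ages[i], config$declinePerStep),
                        S0 = config$S0,
                        noiseSigma = config$S0 * config$noiseSigmaFrac,
                        ageMonths = config$ages[i],
                        seed = config$masterSeed + 1000L * i)
    buildPhantom(spec)
  })
  masks <- subjects[[1]]$truth$masks
  tick("phantoms")

  recon <- list()
  for (i in seq_along(subjects)) {
    dwi <- subjects[[i]]$dwi
    for (k in config$schemes) {
      sub <- selectSubset(dwi, k)
      tf <- fitTensor(sub)
      scal <- tensorScalars(tf)
      sh <- fitSH(sub, order = config$shOrder, lambda = config$shLambda)
      odf <- frtODF(sh, sphere)
      scal$GFA <- gfa(odf)
      pk <- findPeaks(odf)
      qn <- qaNQA(pk)
      scal$NQA <- qn$nqa
      recon[[paste(i, k)]] <- list(tensor = tf, peaks = pk, maps = scal)
    }
  }
  tick("reconstruction")

  metrics <- c("FA", "MD", "RD", "AX", "GFA", "NQA")
  obsScheme <- rep(config$schemes, times = length(subjects))
  obsAge <- rep(config$ages, each = length(config$schemes))
  obsKey <- paste(rep(seq_along(subjects), each = length(config$schemes)),
                  rep(config$schemes, times = length(subjects)))
  roiTrends <- NULL
  if (length(config$schemes) >= 2) {
    roiTrends <- list()
    for (roi in c("bundle", "gray")) {
      roiMask <- masks[[roi]]
      for (met in metrics) {
        maps <- lapply(obsKey, function(kk) recon[[kk]]$maps[[met]])
        tr <- roiMeanTrend(maps, obsScheme, ages = obsAge, roiMask = roiMask)
        roiTrends[[roi]][[met]] <- list(
          means = tr$table$mean, scheme = tr$table$scheme,
          age = tr$table$age, slope = tr$trend$slope, t = tr$trend$t,
          p = tr$trend$p)
      }
    }
  }
  tick("roiTrends")

  deviation <- NULL
  if (length(config$schemes) >= 2) {
    deviation <- list()
    for (model in c("DTI", "QBI")) {
      rows <- NULL
      for (i in seq_along(subjects)) {
        refRec <- recon[[paste(i, refK)]]
        refField <- if (model == "DTI")
          dominantDirection(refRec$tensor, masks$bundle, scheme = refK)
        else dominantDirection(refRec$peaks, masks$bundle, scheme = refK)
        for (k in config$schemes) {
          rec <- recon[[paste(i, k)]]
          fld <- if (model == "DTI")
            dominantDirection(rec$tensor, masks$bundle, scheme = k)
          else dominantDirection(rec$peaks, masks$bundle, scheme = k)
          dv <- angularDeviation(fld, refField, masks$bundle)
          rows <- rbind(rows, data.frame(subject = i,
            age = config$ages[i], scheme = k, meanTheta = dv@roiMean,
            maxTheta = dv@roiMax, nVoxels = dv@nVoxels))
        }
      }
      tr <- shellTrend(rows$scheme, rows$meanTheta, age = rows$age)
      byScheme <- tapply(rows$meanTheta, rows$scheme, mean)
      deviation[[model]] <- list(table = rows,
        meanThetaByScheme = as.numeric(byScheme),
        scheme = as.integer(names(byScheme)),
        slope = tr$slope, t = tr$t, p = tr$p)
    }
  } else if (verbose) {
    message("single scheme requested: angular-deviation stage skipped")
  }
  tick("deviation")

  snr <- lapply(seq_along(subjects), function(i)
    estimateSNR(subjects[[i]]$dwi, masks$bundle, maskName = "bundle"))
  tick("snr")

  tracts <- list()
  for (mp in config$trackingMaps) {
    rec <- recon[[paste(1, refK)]]
    stopMap <- rec$maps[[mp]]
    params <- trackingParams(
      stopThreshold = stoppingThreshold(mp, refK),
      targetCount = config$targetFiberCount,
      seed = config$masterSeed + 77L)
    field <- if (mp == "FA")
      dominantDirection(rec$tensor, array(TRUE, dim(masks$bundle)),
                        scheme = refK)
    else rec$peaks
    tg <- trackStreamlines(field, stopMap, masks$bundle, params,
                           voxelSizeMm = acq@voxelSize)
    sm <- trackSummary(tg)
    tracts[[mp]] <- list(count = sm$count, meanLengthMm = sm$meanLengthMm,
                         tractogram = tg)
  }
  tick("tracking")

  vw <- NULL
  if (length(config$schemes) >= 2) {
    faMaps <- lapply(obsKey, function(kk)
      gaussianSmooth(recon[[kk]]$maps$FA, config$smoothFwhm))
    vwr <- voxelwiseShellRegression(faMaps, obsScheme, ages = obsAge,
                                    q = config$fdrQ)
    vw <- list(criticalP = vwr@criticalP,
               nSignificant = sum(vwr@sigMask),
               nTested = sum(vwr@mask),
               medianSlope = stats::median(vwr@slope[vwr@mask]))
  }
  tick("voxelwise")

  mono <- function(x, dec) all(if (dec) diff(x) <= 0 else diff(x) >= 0)
  replication <- list(
    snrDecreasesAcrossShells =
      all(vapply(snr, function(s) mono(s$shellSNR, TRUE), logical(1))))
  if (!is.null(roiTrends)) replication <- c(replication, list(
    faDecreases = roiTrends$bundle$FA$slope < 0,
    mdDecreases = roiTrends$bundle$MD$slope < 0,
    rdDecreases = roiTrends$bundle$RD$slope < 0,
    axDecreases = roiTrends$bundle$AX$slope < 0,
    gfaIncreases = roiTrends$bundle$GFA$slope > 0,
    nqaIncreases = roiTrends$bundle$NQA$slope > 0,
    grayFaDecreases = roiTrends$gray$FA$slope < 0,
    grayGfaIncreases = roiTrends$gray$GFA$slope > 0))
  if (!is.null(deviation)) {
    replication$dtiThetaNonincreasing <-
      mono(deviation$DTI$meanThetaByScheme, TRUE)
    replication$qbiThetaNonincreasing <-
      mono(deviation$QBI$meanThetaByScheme, TRUE)
    replication$dtiThetaSlopeNegative <-
      deviation$DTI$slope < 0 && deviation$DTI$p < 0.05
    replication$qbiThetaSlopeNegative <-
      deviation$QBI$slope < 0 && deviation$QBI$p < 0.05
  }
  report <- list(
    version = as.character(utils::packageVersion("hydikit")),
    masterSeed = config$masterSeed,
    ages = config$ages, schemes = config$schemes,
    shellBvalues = acq@shellBvalues,
    grid = acq@gridShape,
    roiTrends = if (is.null(roiTrends)) list(skipped = TRUE) else roiTrends,
    deviation = if (is.null(deviation)) list(skipped = TRUE) else
      lapply(deviation, function(d) d[setdiff(names(d), "table")]),
    snr = lapply(snr, function(s)
      list(noise = s$noise, shellSNR = as.numeric(s$shellSNR),
           schemeSNR = as.numeric(s$schemeSNR))),
    tracking = lapply(tracts, function(t0)
      list(count = t0$count, meanLengthMm = t0$meanLengthMm)),
    voxelwise = if (is.null(vw)) list(skipped = TRUE) else vw,
    replication = replication)

  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "maps"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outDir, "tracts"), showWarnings = FALSE)
    dir.create(file.path(outDir, "stats"), showWarnings = FALSE)
    affine <- diag(c(acq@voxelSize, 1))
    for (kk in names(recon)) {
      ik <- strsplit(kk, " ")[[1]]
      for (met in metrics)
        writeScalarMap(recon[[kk]]$maps[[met]],
          file.path(outDir, "maps", sprintf("sub%s_%sshell_%s.nii.gz",
                                            ik[1], ik[2], met)), affine)
    }
    for (mp in names(tracts))
      writeTrk(tracts[[mp]]$tractogram,
               file.path(outDir, "tracts", paste0(mp, ".trk")),
               dim = acq@gridShape, voxelSizeMm = acq@voxelSize)
    if (!is.null(deviation))
      utils::write.csv(do.call(rbind, lapply(names(deviation), function(m)
        cbind(model = m, deviation[[m]]$table))),
        file.path(outDir, "stats", "deviation.csv"), row.names = FALSE)
    snrTab <- do.call(rbind, lapply(seq_along(snr), function(i)
      data.frame(subject = i, bvalue = names(snr[[i]]$shellSNR),
                 snr = as.numeric(snr[[i]]$shellSNR))))
    utils::write.csv(snrTab, file.path(outDir, "stats", "snr.csv"),
                     row.names = FALSE)
    jsonlite::write_json(roundTree(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(stage = names(timings),
                                seconds = round(as.numeric(unlist(timings)), 2)),
                     file.path(outDir, "timings.csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}
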