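#' Build a pipeline configuration
#'
#' A plain list validated by \code{\link{runPipeline}}; it round-trips
#' through JSON unchanged. `phantom` holds named overrides for
#' \code{\link{PhantomSpec}} arguments shared by all simulated conditions.
#'
#' @param outDir output directory for the report bundle.
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param nConditions number of simulated ventilatory conditions.
#' @param mergeWeightHigh blend weight on the high-energy volume.
#' @param cutoffs aeration gas-fraction cutoffs.
#' @param band frame-classification band (fraction of the gas-volume range).
#' @param nRegions gravitational regions for displacement summaries.
#' @param basisFile optional path to a material-basis JSON used for
#'   rendering instead of \code{\link{defaultMaterialBasis}}.
#' @param phantom named list of PhantomSpec overrides.
#' @param writeVolumes write example NIfTI volumes for the first condition.
#' @return A named list.
#' @export
pipelineConfig <- function(outDir = "lungdect-run", seed = 1L,
                           nConditions = 4L, mergeWeightHigh = 0.7,
                           cutoffs = c(0.10, 0.50, 0.90), band = 0.30,
                           nRegions = 12L, basisFile = NULL,
                           phantom = list(), writeVolumes = TRUE) {
    list(outDir = outDir, seed = as.integer(seed),
         nConditions = as.integer(nConditions),
         mergeWeightHigh = mergeWeightHigh, cutoffs = cutoffs, band = band,
         nRegions = as.integer(nRegions), basisFile = basisFile,
         phantom = phantom, writeVolumes = writeVolumes)
}

# ventilatory condition grid: PEEP x VT, half the animals injured
.conditionGrid <- function(n) {
    peep <- rep(c(5, 8, 10, 12), length.out = n)
    vt <- rep(c(7, 11, 15), length.out = n)
    data.frame(condition = seq_len(n), peep = peep, vt = vt,
               injured = seq_len(n) <= n / 2)
}

# condition-dependent phantom: higher PEEP recruits the dependent lung
# (less atelectasis), larger VT deepens the tidal excursion, and caudal
# slice displacement peaks around PEEP 10
.conditionSpec <- function(cond, seed, overrides) {
    args <- list(
        seed = seed,
        atelectasisExtent = max(0, (if (cond$injured) 0.22 else 0.10) -
                                   0.008 * cond$peep),
        tidalAmplitude = min(1, 0.12 + 0.012 * cond$vt),
        peakCaudalMM = 4 + 8 * exp(-(cond$peep - 10)^2 / 50))
    do.call(PhantomSpec, utils::modifyList(args, overrides))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
             call. = FALSE))
}

.writeCsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE)
    path
}

#' Run the simulate-then-analyze pipeline
#'
#' Chains the analysis stages on simulated conditions: phantom generation,
#' dual-energy rendering, ROI coefficient calibration, three-material
#' decomposition, merge-volume synthesis, aeration segmentation, tidal
#' frame classification, per-frame dynamic-slice summaries, density and
#' fraction histograms, dCT versus whole-lung agreement statistics
#' (correlation, Bland-Altman, phase-resolved bias, adjacent-slice position
#' regression), and displacement-field regional summaries. Writes a CSV/NIfTI
#' report bundle plus a JSON manifest listing every artifact; re-running
#' with the same configuration reproduces the bundle byte for byte.
#'
#' @param config a list from \code{\link{pipelineConfig}} or a path to a
#'   JSON file with the same fields.
#' @return Invisibly, a list with the manifest (as a list) and the main
#'   result tables.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config))
        config <- utils::modifyList(pipelineConfig(),
                                    jsonlite::read_json(config,
                                                        simplifyVector = TRUE))
    stopifnot(is.list(config))
    config <- utils::modifyList(pipelineConfig(), config)
    if (config$mergeWeightHigh < 0 || config$mergeWeightHigh > 1)
        stop("mergeWeightHigh must lie in [0, 1]")
    if (config$band < 0 || config$band >= 0.5)
        stop("band must lie in [0, 0.5)")

    trueBasis <- if (!is.null(config$basisFile)) {
        .stage("basis", readMaterialBasis(config$basisFile))
    } else {
        defaultMaterialBasis()
    }

    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    grid <- .conditionGrid(config$nConditions)
    phantomOverrides <- config$phantom
    if (length(phantomOverrides))
        phantomOverrides <- phantomOverrides[!vapply(phantomOverrides,
                                                     is.null, logical(1))]

    varRows <- list(); frameRows <- list(); histRows <- list()
    distRows <- list(); regRows <- list(); fracRows <- list()
    sliceRows <- list()
    whole <- dct <- dctExp <- dctInsp <- NULL
    files <- character()

    for (i in seq_len(nrow(grid))) {
        cond <- grid[i, ]
        spec <- .conditionSpec(cond, seed = config$seed * 1000L + i,
                               overrides = phantomOverrides)
        truth <- .stage("simulate", generatePhantom(spec))
        pair <- .stage("render", renderDect(truth, trueBasis))
        basis <- .stage("calibrate",
                        calibrateBasis(pair, truth@aortaMask,
                                       truth@muscleMask))
        merge <- .stage("merge", mergeVolumes(pair, config$mergeWeightHigh))
        fractions <- .stage("decompose",
                            decomposeDect(pair, basis, truth@lungMask))
        labels <- .stage("segment",
                         classifyAeration(fractions,
                                          cutoffs = config$cutoffs))
        wholeVec <- .stage("summarize",
                           summarizeVariables(merge, fractions, labels))

        # dynamic series: render, decompose and summarize every frame
        tidal <- .stage("frames", simulateTidalSeries(spec,
                        condition = as.list(cond)))
        phases <- .stage("frames", classifyFrames(tidal$series,
                                                  band = config$band))
        frameVecs <- .stage("frames",
                            .summarizeFrames(tidal$series, truth, basis,
                                             spec, config))
        keep <- phases$phase != "excluded"
        dctVec <- colMeans(frameVecs[keep, , drop = FALSE])
        expVec <- colMeans(frameVecs[phases$phase == "expiratory", ,
                                     drop = FALSE])
        inspVec <- colMeans(frameVecs[phases$phase == "inspiratory", ,
                                      drop = FALSE])

        # distributions: whole-lung vs dynamic-slice density histograms
        slabMerge <- .sliceVolume(merge, truth, spec)
        hWhole <- densityHistogram(merge, truth@lungMask)
        hSlab <- densityHistogram(slabMerge$volume, slabMerge$mask)
        distRows[[i]] <- data.frame(condition = i,
                                    r = distributionCorrelation(hSlab,
                                                                hWhole))
        histRows[[i]] <- rbind(
            cbind(condition = i, context = "whole", histogramTable(hWhole)),
            cbind(condition = i, context = "dct", histogramTable(hSlab)))

        # adjacent-slice composition (relative to the most caudal slice)
        sliceRows[[i]] <- .adjacentSliceTable(merge, fractions, truth,
                                              config, i)

        # displacement summaries
        cc <- ccDisplacementSlice(truth@field, truth@sliceMask)
        reg <- regionalMeans(cc, truth@sliceMask,
                             nRegions = config$nRegions)
        mf <- movementFractions(cc, truth@sliceMask)
        regRows[[i]] <- data.frame(condition = i, peep = cond$peep,
                                   injured = cond$injured,
                                   region = seq_along(reg), mean_mm = reg)
        fracRows[[i]] <- cbind(data.frame(condition = i, peep = cond$peep,
                                          injured = cond$injured),
                               as.data.frame(as.list(mf)))

        varRows[[i]] <- cbind(
            data.frame(condition = i, peep = cond$peep, vt = cond$vt,
                       injured = cond$injured,
                       context = c("whole", "dct", "dct_expiratory",
                                   "dct_inspiratory")),
            as.data.frame(rbind(wholeVec, dctVec, expVec, inspVec),
                          row.names = FALSE))
        frameRows[[i]] <- cbind(condition = i, phases)
        whole <- rbind(whole, wholeVec)
        dct <- rbind(dct, dctVec)
        dctExp <- rbind(dctExp, expVec)
        dctInsp <- rbind(dctInsp, inspVec)

        if (isTRUE(config$writeVolumes) && i == 1L) {
            files <- c(files,
                writeCtVolume(merge, file.path(config$outDir,
                                               "merge_c1.nii.gz")),
                writeCtVolume(fractions@gas, file.path(config$outDir,
                              "gas_fraction_c1.nii.gz"),
                              spacing = spec@spacing),
                writeCtVolume(labels, file.path(config$outDir,
                                                "aeration_c1.nii.gz")),
                writeDisplacementField(truth@field,
                    file.path(config$outDir, "displacement_c1.nii.gz")),
                writeMaterialBasis(basis, file.path(config$outDir,
                                                    "basis_c1.json")))
        }
    }

    # agreement across conditions, per variable
    agree <- do.call(rbind, lapply(.VARIABLES, function(v) {
        ba <- blandAltman(dct[, v], whole[, v])
        cbind(data.frame(variable = v,
                         r_squared = correlateMeans(dct[, v], whole[, v])),
              ba)
    }))
    bias <- phaseBias(dctExp - whole, dctInsp - whole)
    slicePos <- do.call(rbind, sliceRows)
    sliceFit <- slicePositionRegression(
        slicePos[, .VARIABLES, drop = FALSE], slicePos$offset_mm)
    regLong <- do.call(rbind, regRows)
    dispSummary <- summarizeByCondition(regLong, "mean_mm",
                                        c("peep", "injured", "region"))

    tables <- list(
        variables = do.call(rbind, varRows),
        frames = do.call(rbind, frameRows),
        histograms = do.call(rbind, histRows),
        distribution_correlation = do.call(rbind, distRows),
        agreement = agree,
        phase_bias = bias,
        slice_position = sliceFit,
        displacement_regional = regLong,
        displacement_fractions = do.call(rbind, fracRows),
        displacement_summary = dispSummary)
    for (nm in names(tables))
        files <- c(files, .writeCsv(tables[[nm]],
                                    file.path(config$outDir,
                                              paste0(nm, ".csv"))))

    manifest <- list(config = config,
                     package_version =
                         as.character(utils::packageVersion("lungdect")),
                     files = sort(basename(files)))
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    invisible(c(list(manifest = manifest, manifest_path = manifestPath),
                tables))
}

# per-frame dynamic-slice variable vectors: render each frame's slab with
# noise, decompose with the calibrated basis, segment, summarize
.summarizeFrames <- function(series, truth, basis, spec, config) {
    mid <- as.integer(ceiling(spec@dim[3] / 2))
    slabBlood <- truth@fractions@blood[, , mid, drop = FALSE]
    slabMask <- series@mask
    out <- matrix(NA_real_, nrow = length(series@frames),
                  ncol = length(.VARIABLES),
                  dimnames = list(NULL, .VARIABLES))
    for (t in seq_along(series@frames)) {
        g <- series@frames[[t]]
        vols <- .renderFractionArrays(g, 1 - g - slabBlood, slabBlood,
                                      basis, spec@noiseSD,
                                      seed = spec@seed + 5000L + t)
        pair <- DectPair(CtVolume(vols$low, spec@spacing),
                         CtVolume(vols$high, spec@spacing))
        fr <- decomposeDect(pair, basis, slabMask)
        lab <- classifyAeration(fr, cutoffs = config$cutoffs)
        mrg <- mergeVolumes(pair, config$mergeWeightHigh)
        out[t, ] <- summarizeVariables(mrg, fr, lab)
    }
    out
}

# the dCT slab of a whole-lung volume
.sliceVolume <- function(volume, truth, spec) {
    mid <- as.integer(ceiling(spec@dim[3] / 2))
    list(volume = CtVolume(volume@voxels[, , mid, drop = FALSE],
                           spec@spacing),
         mask = truth@sliceMask[, , mid, drop = FALSE])
}

# variable vectors of the three adjacent 5-mm slices, relative to the most
# caudal slice (caudal = larger axis-3 index); offsets in mm cranial
.adjacentSliceTable <- function(merge, fractions, truth, config, condition) {
    mid <- as.integer(ceiling(dim(merge@voxels)[3] / 2))
    ks <- c(mid + 1L, mid, mid - 1L)
    ks <- ks[ks >= 1L & ks <= dim(merge@voxels)[3]]
    offsets <- (ks[1L] - ks) * voxelSpacing(merge)[3]
    k3 <- .axisIndex(dim(merge@voxels), 3L)
    vecs <- t(vapply(ks, function(k) {
        m <- truth@lungMask & k3 == k
        lab <- classifyAeration(fractions@gas, m,
                                cutoffs = config$cutoffs,
                                spacing = voxelSpacing(merge))
        summarizeVariables(merge, fractions, lab, mask = m)
    }, numeric(length(.VARIABLES))))
    colnames(vecs) <- .VARIABLES
    rel <- sweep(vecs, 2L, vecs[1L, ])
    cbind(data.frame(condition = condition, slice_k = ks,
                     offset_mm = offsets),
          as.data.frame(rel, row.names = FALSE))
}
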