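#' Accessors for lungdect containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `voxelData()` returns the raw array of a volume, `voxelSpacing()` the
#' spacing in mm, `voxelVolumeML()` the volume of one voxel in mL,
#' `lowEnergy()`/`highEnergy()` the two volumes of a
#' \linkS4class{DectPair}, `materialCoefficients()` the 3x2 HU matrix of a
#' \linkS4class{MaterialBasis}, `gasFraction()`, `tissueFraction()` and
#' `bloodFraction()` the material maps of a \linkS4class{FractionMaps},
#' `analysisMask()` the analysis mask, `aerationLabels()` the label array of
#' an \linkS4class{AerationMap}, and `binWeights()`/`binEdges()` the content
#' of a \linkS4class{HistogramBins}.
#'
#' @param x the object.
#' @return The corresponding slot content (see details above).
#' @name lungdect-accessors
#' @aliases voxelData voxelSpacing voxelVolumeML lowEnergy highEnergy
#'   materialCoefficients gasFraction tissueFraction bloodFraction
#'   analysisMask aerationLabels binWeights binEdges
NULL

#' @rdname lungdect-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname lungdect-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname lungdect-accessors
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))
#' @rdname lungdect-accessors
#' @export
setGeneric("lowEnergy", function(x) standardGeneric("lowEnergy"))
#' @rdname lungdect-accessors
#' @export
setGeneric("highEnergy", function(x) standardGeneric("highEnergy"))
#' @rdname lungdect-accessors
#' @export
setGeneric("materialCoefficients",
           function(x) standardGeneric("materialCoefficients"))
#' @rdname lungdect-accessors
#' @export
setGeneric("gasFraction", function(x) standardGeneric("gasFraction"))
#' @rdname lungdect-accessors
#' @export
setGeneric("tissueFraction", function(x) standardGeneric("tissueFraction"))
#' @rdname lungdect-accessors
#' @export
setGeneric("bloodFraction", function(x) standardGeneric("bloodFraction"))
#' @rdname lungdect-accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))
#' @rdname lungdect-accessors
#' @export
setGeneric("aerationLabels", function(x) standardGeneric("aerationLabels"))
#' @rdname lungdect-accessors
#' @export
setGeneric("binWeights", function(x) standardGeneric("binWeights"))
#' @rdname lungdect-accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname lungdect-accessors
setMethod("voxelData", "CtVolume", function(x) x@voxels)
#' @rdname lungdect-accessors
setMethod("voxelSpacing", "CtVolume", function(x) x@spacing)
#' @rdname lungdect-accessors
setMethod("voxelSpacing", "DectPair", function(x) x@low@spacing)
#' @rdname lungdect-accessors
setMethod("voxelSpacing", "FractionMaps", function(x) x@spacing)
#' @rdname lungdect-accessors
setMethod("voxelSpacing", "AerationMap", function(x) x@spacing)
#' @rdname lungdect-accessors
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)
#' @rdname lungdect-accessors
setMethod("voxelVolumeML", "CtVolume", function(x) prod(x@spacing) / 1000)
#' @rdname lungdect-accessors
setMethod("voxelVolumeML", "FractionMaps", function(x) prod(x@spacing) / 1000)
#' @rdname lungdect-accessors
setMethod("voxelVolumeML", "AerationMap", function(x) prod(x@spacing) / 1000)
#' @rdname lungdect-accessors
setMethod("lowEnergy", "DectPair", function(x) x@low)
#' @rdname lungdect-accessors
setMethod("highEnergy", "DectPair", function(x) x@high)
#' @rdname lungdect-accessors
setMethod("materialCoefficients", "MaterialBasis", function(x) x@coefficients)
#' @rdname lungdect-accessors
setMethod("gasFraction", "FractionMaps", function(x) x@gas)
#' @rdname lungdect-accessors
setMethod("tissueFraction", "FractionMaps", function(x) x@tissue)
#' @rdname lungdect-accessors
setMethod("bloodFraction", "FractionMaps", function(x) x@blood)
#' @rdname lungdect-accessors
setMethod("analysisMask", "FractionMaps", function(x) x@mask)
#' @rdname lungdect-accessors
setMethod("gasFraction", "GroundTruth", function(x) x@fractions@gas)
#' @rdname lungdect-accessors
setMethod("aerationLabels", "AerationMap", function(x) x@labels)
#' @rdname lungdect-accessors
setMethod("binWeights", "HistogramBins", function(x) x@weights)
#' @rdname lungdect-accessors
setMethod("binEdges", "HistogramBins", function(x) x@edges)

setMethod("show", "CtVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("CtVolume: %d x %d x %d voxels, spacing %s mm\n",
                d[1], d[2], d[3],
                paste(format(object@spacing), collapse = " x ")))
    cat(sprintf("  HU range [%.1f, %.1f]\n",
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "DectPair", function(object) {
    d <- dim(object@low@voxels)
    cat(sprintf("DectPair (%s/%s energy): %d x %d x %d voxels\n",
                object@energies[1], object@energies[2], d[1], d[2], d[3]))
})

setMethod("show", "MaterialBasis", function(object) {
    cat("MaterialBasis (HU per 100% material):\n")
    print(round(object@coefficients, 2))
    cat(sprintf("  system condition number %.3g\n",
                .basisConditionNumber(object@coefficients)))
})

setMethod("show", "FractionMaps", function(object) {
    d <- dim(object@gas)
    n <- sum(object@mask)
    cat(sprintf("FractionMaps: %d x %d x %d voxels, %d in analysis mask\n",
                d[1], d[2], d[3], n))
    if (n) cat(sprintf("  mean gas %.3f | tissue %.3f | blood %.3f\n",
                       mean(object@gas[object@mask]),
                       mean(object@tissue[object@mask]),
                       mean(object@blood[object@mask])))
})

setMethod("show", "AerationMap", function(object) {
    tab <- tabulate(object@labels + 1L, nbins = 5L)
    cat(sprintf(
        "AerationMap (cutoffs %s): atelectasis %d | poor %d | normal %d | overdistended %d\n",
        paste(object@cutoffs, collapse = "/"),
        tab[2], tab[3], tab[4], tab[5]))
})

setMethod("show", "FrameSeries", function(object) {
    cat(sprintf("FrameSeries: %d frames over %.0f s, %d masked voxels/frame\n",
                length(object@frames), diff(range(object@timestamps)),
                sum(object@mask)))
})

setMethod("show", "DisplacementField", function(object) {
    cc <- object@field[, , , 3]
    cat(sprintf(
        "DisplacementField: %s voxels; caudal component range [%.2f, %.2f] mm\n",
        paste(dim(object@field)[1:3], collapse = " x "), min(cc), max(cc)))
})

setMethod("show", "HistogramBins", function(object) {
    cat(sprintf(
        "HistogramBins (%s): %d bins on [%g, %g], %d masked voxels (%d out of range)\n",
        object@kind, length(object@weights), min(object@edges),
        max(object@edges), object@nMasked, object@outOfRange))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: %s voxels at %s mm; gas %.2f -> %.2f (ant -> post); seed %d\n",
        paste(object@dim, collapse = " x "),
        paste(object@spacing, collapse = " x "),
        object@gasAnterior, object@gasPosterior, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(
        "GroundTruth: %d lung voxels (%d in dCT slice); peak caudal displacement %.2f mm\n",
        sum(object@lungMask), sum(object@sliceMask),
        max(object@field@field[, , , 3])))
})
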