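#' @import methods
NULL

.MATERIALS <- c("gas", "soft_tissue", "iodinated_blood")
.ENERGIES <- c("low", "high")
.AERATION_LEVELS <- c(outside = 0L, atelectasis = 1L, poorly_aerated = 2L,
                      normally_aerated = 3L, overdistended = 4L)

#' CtVolume: a 3-D CT density volume
#'
#' A scalar volume of CT densities in Hounsfield units (HU) together with its
#' voxel spacing. Axis convention throughout the package: axis 1 runs
#' left-right, axis 2 anterior to posterior (posterior = dependent in a supine
#' subject, increasing index), axis 3 cranio-caudal (caudal = increasing
#' index).
#'
#' @slot voxels 3-D numeric array of HU values.
#' @slot spacing numeric(3), voxel spacing in mm per axis.
#' @export
setClass("CtVolume", representation(voxels = "array", spacing = "numeric"))

setValidity("CtVolume", function(object) {
    if (length(dim(object@voxels)) != 3L)
        return("voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("spacing must be 3 positive finite values (mm)")
    if (any(!is.finite(object@voxels)))
        return("voxel values must be finite")
    TRUE
})

#' Construct a CtVolume
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric(3) voxel spacing in mm (default 0.5 x 0.5 x 5,
#'   a 5-mm slice thickness).
#' @return A \linkS4class{CtVolume}.
#' @export
CtVolume <- function(voxels, spacing = c(0.5, 0.5, 5)) {
    new("CtVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' DectPair: co-registered dual-energy CT volumes
#'
#' The same anatomy imaged at two X-ray tube energies on one voxel grid.
#'
#' @slot low low-energy \linkS4class{CtVolume}.
#' @slot high high-energy \linkS4class{CtVolume}.
#' @slot energies character(2) labels for the two acquisitions.
#' @export
setClass("DectPair", representation(low = "CtVolume", high = "CtVolume",
                                    energies = "character"))

setValidity("DectPair", function(object) {
    if (!identical(dim(object@low@voxels), dim(object@high@voxels)))
        return("low and high energy volumes must share one grid")
    if (!isTRUE(all.equal(object@low@spacing, object@high@spacing)))
        return("low and high energy volumes must share voxel spacing")
    if (length(object@energies) != 2L)
        return("energies must have length 2")
    TRUE
})

#' Construct a DectPair
#'
#' @param low,high \linkS4class{CtVolume} objects on the same grid, or 3-D
#'   arrays (converted with the spacing of `low` when given as a CtVolume,
#'   else `spacing`).
#' @param spacing voxel spacing in mm, used when arrays are supplied.
#' @param energies labels for the two energy levels.
#' @return A \linkS4class{DectPair}.
#' @export
DectPair <- function(low, high, spacing = c(0.5, 0.5, 5),
                     energies = c("low", "high")) {
    if (!is(low, "CtVolume")) low <- CtVolume(low, spacing)
    if (!is(high, "CtVolume")) high <- CtVolume(high, low@spacing)
    new("DectPair", low = low, high = high, energies = energies)
}

#' MaterialBasis: DECT coefficients for three basis materials
#'
#' CT densities equivalent to 100\% of each material at each energy level.
#' The three materials are gas, soft tissue and iodinated blood; gas is
#' -1000 HU at both energies unless overridden. The associated 3x3 linear
#' system (two energy equations plus the unity constraint) must be
#' well-conditioned for the decomposition to be identifiable.
#'
#' @slot coefficients 3x2 numeric matrix, rows gas / soft_tissue /
#'   iodinated_blood, columns low / high energy, in HU.
#' @slot provenance character(3): how each material row was obtained
#'   ("fixed" or "roi_mean").
#' @export
setClass("MaterialBasis",
         representation(coefficients = "matrix", provenance = "character"))

# system matrix: rows = (low energy, high energy, unity), cols = materials
.basisSystemMatrix <- function(coefficients) {
    rbind(t(coefficients), rep(1, 3))
}

.basisConditionNumber <- function(coefficients) {
    kappa(.basisSystemMatrix(coefficients), exact = TRUE)
}

# name the closest pair of material signatures, for degeneracy diagnostics
.closestMaterialPair <- function(coefficients) {
    a <- .basisSystemMatrix(coefficients)
    d <- as.matrix(stats::dist(t(a)))
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    paste(rownames(coefficients)[sort(idx)], collapse = " / ")
}

setValidity("MaterialBasis", function(object) {
    co <- object@coefficients
    if (!identical(dim(co), c(3L, 2L)))
        return("coefficients must be a 3x2 matrix (materials x energies)")
    if (!identical(rownames(co), .MATERIALS))
        return(sprintf("coefficient rows must be %s",
                       paste(.MATERIALS, collapse = ", ")))
    if (any(!is.finite(co)))
        return("coefficients must be finite")
    cn <- .basisConditionNumber(co)
    if (!is.finite(cn) || cn >= 1e6)
        return(sprintf(
            "degenerate material basis (condition number %.3g >= 1e6); nearly indistinguishable materials: %s",
            cn, .closestMaterialPair(co)))
    TRUE
})

#' Construct a MaterialBasis
#'
#' @param softTissue,iodinatedBlood numeric(2): HU of the pure material at
#'   (low, high) energy.
#' @param gas numeric(2); defaults to -1000 HU at both energies.
#' @param provenance character(3) provenance tag per material.
#' @return A \linkS4class{MaterialBasis}.
#' @export
MaterialBasis <- function(softTissue, iodinatedBlood, gas = c(-1000, -1000),
                          provenance = c("fixed", "fixed", "fixed")) {
    co <- rbind(gas = as.numeric(gas),
                soft_tissue = as.numeric(softTissue),
                iodinated_blood = as.numeric(iodinatedBlood))
    rownames(co) <- .MATERIALS
    colnames(co) <- .ENERGIES
    new("MaterialBasis", coefficients = co, provenance = provenance)
}

#' A default material basis for simulation
#'
#' Gas at -1000 HU both energies, soft tissue (60, 40) HU and iodinated
#' blood (400, 250) HU at (low, high) energy: iodine attenuates much more at
#' low energy, which is what makes the three-material system identifiable.
#'
#' @return A \linkS4class{MaterialBasis}.
#' @export
defaultMaterialBasis <- function() {
    MaterialBasis(softTissue = c(60, 40), iodinatedBlood = c(400, 250))
}

#' FractionMaps: per-voxel material volume fractions
#'
#' Gas, soft tissue and iodinated blood volume fractions on a voxel grid.
#' Inside the analysis mask the three fractions are non-negative and sum to
#' one (after simplex projection); the pre-projection residual records, per
#' voxel, the Euclidean distance between the raw linear-system solution and
#' the projected point so users can audit the projection.
#'
#' @slot gas,tissue,blood 3-D numeric arrays of volume fractions.
#' @slot mask logical 3-D array: the analysis (lung) mask.
#' @slot residual 3-D numeric array: pre-projection residual (0 where the raw
#'   solution was already on the simplex; NA outside the mask).
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot projected logical: whether fractions were projected onto the simplex.
#' @export
setClass("FractionMaps",
         representation(gas = "array", tissue = "array", blood = "array",
                        mask = "array", residual = "array",
                        spacing = "numeric", projected = "logical"))

setValidity("FractionMaps", function(object) {
    dims <- dim(object@gas)
    if (!identical(dims, dim(object@tissue)) ||
        !identical(dims, dim(object@blood)) ||
        !identical(dims, dim(object@mask)))
        return("gas, tissue, blood and mask must share one grid")
    if (!is.logical(object@mask))
        return("mask must be logical")
    m <- object@mask & !is.na(object@gas)
    if (any(object@mask & is.na(object@gas)))
        return("fractions must be defined inside the mask")
    s <- object@gas[m] + object@tissue[m] + object@blood[m]
    if (length(s) && max(abs(s - 1)) > 1e-6)
        return("masked fractions must sum to 1 within 1e-6")
    if (isTRUE(object@projected) && length(s)) {
        lo <- min(object@gas[m], object@tissue[m], object@blood[m])
        hi <- max(object@gas[m], object@tissue[m], object@blood[m])
        if (lo < -1e-9 || hi > 1 + 1e-9)
            return("projected fractions must lie in [0, 1]")
    }
    TRUE
})

#' AerationMap: aeration compartment labels
#'
#' Integer labels per voxel: 0 outside the analysis mask, 1 atelectasis,
#' 2 poorly aerated, 3 normally aerated, 4 overdistended, derived from the
#' gas volume fraction at the stored cutoffs.
#'
#' @slot labels 3-D integer array of labels 0-4.
#' @slot cutoffs numeric(3) strictly increasing gas-fraction cutoffs in
#'   (0, 1); default c(0.10, 0.50, 0.90).
#' @slot spacing numeric(3) voxel spacing (mm).
#' @export
setClass("AerationMap",
         representation(labels = "array", cutoffs = "numeric",
                        spacing = "numeric"))

setValidity("AerationMap", function(object) {
    if (!all(object@labels %in% 0:4))
        return("labels must be integers 0..4")
    cf <- object@cutoffs
    if (length(cf) != 3L || any(diff(cf) <= 0) || cf[1] <= 0 || cf[3] >= 1)
        return("cutoffs must be strictly increasing within (0, 1)")
    TRUE
})

#' FrameSeries: a dynamic single-slice CT series
#'
#' Ordered thin-slab gas-fraction frames acquired at (nominally) 1 Hz while
#' the lung moves during tidal ventilation, sharing one grid and mask.
#'
#' @slot frames list of 3-D numeric arrays: per-frame gas volume fraction maps.
#' @slot timestamps numeric, acquisition time of each frame (s).
#' @slot mask logical 3-D array: slab analysis mask shared by all frames.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @slot condition list of ventilatory condition metadata (peep cmH2O,
#'   tidal_volume mL/kg, injured flag, free-form).
#' @export
setClass("FrameSeries",
         representation(frames = "list", timestamps = "numeric",
                        mask = "array", spacing = "numeric",
                        condition = "list"))

setValidity("FrameSeries", function(object) {
    n <- length(object@frames)
    if (n < 2L)
        return("a frame series needs at least 2 frames")
    if (length(object@timestamps) != n)
        return("one timestamp per frame required")
    dims <- dim(object@mask)
    ok <- vapply(object@frames, function(f) identical(dim(f), dims), logical(1))
    if (!all(ok))
        return("all frames must share the mask's grid")
    TRUE
})

#' Construct a FrameSeries
#'
#' @param frames list of 3-D gas-fraction arrays.
#' @param mask logical array on the frame grid.
#' @param timestamps frame times in s (default 0, 1, 2, ... for 1 Hz).
#' @param spacing voxel spacing (mm).
#' @param condition list of condition metadata.
#' @return A \linkS4class{FrameSeries}.
#' @export
FrameSeries <- function(frames, mask, timestamps = seq_along(frames) - 1,
                        spacing = c(0.5, 0.5, 5), condition = list()) {
    new("FrameSeries", frames = frames, timestamps = as.numeric(timestamps),
        mask = mask, spacing = as.numeric(spacing), condition = condition)
}

#' DisplacementField: dense expiration-to-inspiration displacement vectors
#'
#' Per-voxel 3-vectors in mm describing how each point moves between the
#' expiratory and inspiratory images. Component order follows the volume
#' axes; component 3 is cranio-caudal, with positive values = caudal
#' (toward the diaphragm).
#'
#' @slot field 4-D numeric array (x, y, z, component), mm.
#' @slot spacing numeric(3) voxel spacing (mm).
#' @export
setClass("DisplacementField",
         representation(field = "array", spacing = "numeric"))

setValidity("DisplacementField", function(object) {
    d <- dim(object@field)
    if (length(d) != 4L || d[4] != 3L)
        return("field must be a 4-D array with 3 components on axis 4")
    if (any(!is.finite(object@field)))
        return("displacement vectors must be finite")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        return("spacing must be 3 positive values (mm)")
    TRUE
})

#' Construct a DisplacementField
#'
#' @param field 4-D numeric array (x, y, z, 3), mm.
#' @param spacing voxel spacing in mm.
#' @return A \linkS4class{DisplacementField}.
#' @export
DisplacementField <- function(field, spacing = c(0.5, 0.5, 5)) {
    new("DisplacementField", field = field, spacing = as.numeric(spacing))
}

#' HistogramBins: a normalized fixed-bin histogram
#'
#' Left-closed, right-open bins (the last bin closed on the right). In-range
#' weights are normalized to sum to 1; voxels outside the bin range are
#' excluded from normalization and counted separately.
#'
#' @slot edges numeric bin edges (length nbins + 1).
#' @slot weights numeric normalized counts per bin.
#' @slot outOfRange integer count of masked voxels outside the range.
#' @slot nMasked integer total masked voxels considered.
#' @slot kind "hu" or "fraction".
#' @export
setClass("HistogramBins",
         representation(edges = "numeric", weights = "numeric",
                        outOfRange = "integer", nMasked = "integer",
                        kind = "character"))

setValidity("HistogramBins", function(object) {
    if (length(object@weights) != length(object@edges) - 1L)
        return("weights must have one entry per bin")
    if (any(object@weights < 0))
        return("weights must be non-negative")
    s <- sum(object@weights)
    if (object@nMasked > object@outOfRange && abs(s - 1) > 1e-9)
        return("in-range weights must sum to 1 within 1e-9")
    TRUE
})

#' PhantomSpec: parameters of the synthetic thorax phantom
#'
#' Defines a miniature supine thorax with an anterior-to-posterior
#' (gravitational) aeration gradient, cranio-caudal vessels carrying
#' iodinated blood, dependent atelectasis, a tidal gas waveform and a smooth
#' cranio-caudal displacement field concentrated in the mid-gravitational
#' lung. One seed fixes all stochastic output.
#'
#' @slot dim integer(3) grid size in voxels.
#' @slot spacing numeric(3) voxel spacing mm (default 0.5 x 0.5 x 5).
#' @slot gasAnterior,gasPosterior target gas fractions at the anterior and
#'   posterior lung border (gradient endpoints).
#' @slot gasJitterSD SD of truncated-Gaussian voxelwise jitter on the gas
#'   fraction (truncated at 3 SD so gradient ordering is preserved).
#' @slot vesselCount,vesselRadius,vesselBloodFraction number of cranio-caudal
#'   vessel cylinders, their radius in voxels, and the iodinated-blood volume
#'   fraction inside them.
#' @slot atelectasisExtent fraction of the lung's gravitational extent (from
#'   the dependent border) rendered atelectatic; 0 disables.
#' @slot atelectasisGasFraction gas fraction inside the atelectatic mass.
#' @slot noiseSD numeric(2) HU noise SD at (low, high) energy for rendering.
#' @slot tidalAmplitude fractional recruitment amplitude: at end-inspiration
#'   each modulated voxel's gas fraction is f + amplitude * (1 - f).
#' @slot framesPerCycle,cycles tidal sampling (1 Hz frames per breath, and
#'   number of breaths).
#' @slot peakCaudalMM peak caudal displacement (mm).
#' @slot controlSpacingMM control-point grid spacing for the displacement
#'   field (mm, default 3).
#' @slot displacementProfile "midlung" (raised bump peaking mid-gravitationally)
#'   or "uniform".
#' @slot seed integer random seed.
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", spacing = "numeric",
                        gasAnterior = "numeric", gasPosterior = "numeric",
                        gasJitterSD = "numeric",
                        vesselCount = "integer", vesselRadius = "numeric",
                        vesselBloodFraction = "numeric",
                        atelectasisExtent = "numeric",
                        atelectasisGasFraction = "numeric",
                        noiseSD = "numeric",
                        tidalAmplitude = "numeric",
                        framesPerCycle = "integer", cycles = "integer",
                        peakCaudalMM = "numeric",
                        controlSpacingMM = "numeric",
                        displacementProfile = "character",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
    frac <- c(object@gasAnterior, object@gasPosterior,
              object@vesselBloodFraction, object@atelectasisExtent,
              object@atelectasisGasFraction, object@tidalAmplitude)
    if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
        return("all fractions must lie in [0, 1]")
    if (length(object@dim) != 3L || any(object@dim <= 0))
        return("dim must be 3 positive integers")
    if (any(object@spacing <= 0))
        return("spacing must be positive")
    if (any(object@noiseSD < 0) || length(object@noiseSD) != 2L)
        return("noiseSD must be 2 non-negative values")
    if (object@vesselCount < 0 || object@vesselRadius < 0)
        return("vessel parameters must be non-negative")
    if (object@framesPerCycle < 1L || object@cycles < 1L)
        return("framesPerCycle and cycles must be >= 1")
    if (object@peakCaudalMM < 0 || object@controlSpacingMM <= 0)
        return("displacement parameters must be non-negative (spacing > 0)")
    if (!object@displacementProfile %in% c("midlung", "uniform"))
        return("displacementProfile must be 'midlung' or 'uniform'")
    TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults define the reference study conditions used throughout the test
#' suite and the demonstration pipeline; see the methods vignette for the
#' rationale behind each value.
#'
#' @param dim grid size in voxels.
#' @param spacing voxel spacing mm.
#' @param gasAnterior,gasPosterior gravitational gradient endpoints.
#' @param gasJitterSD voxelwise gas-fraction jitter SD.
#' @param vesselCount,vesselRadius,vesselBloodFraction vessel parameters.
#' @param atelectasisExtent,atelectasisGasFraction dependent-atelectasis
#'   parameters.
#' @param noiseSD HU noise SD per energy.
#' @param tidalAmplitude,framesPerCycle,cycles tidal parameters.
#' @param peakCaudalMM,controlSpacingMM,displacementProfile displacement
#'   parameters.
#' @param seed random seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(dim = c(48L, 64L, 16L), spacing = c(0.5, 0.5, 5),
                        gasAnterior = 0.85, gasPosterior = 0.25,
                        gasJitterSD = 0.01,
                        vesselCount = 6L, vesselRadius = 1.5,
                        vesselBloodFraction = 0.8,
                        atelectasisExtent = 0.15,
                        atelectasisGasFraction = 0.03,
                        noiseSD = c(5, 5),
                        tidalAmplitude = 0.3,
                        framesPerCycle = 16L, cycles = 2L,
                        peakCaudalMM = 10, controlSpacingMM = 3,
                        displacementProfile = "midlung",
                        seed = 1L) {
    new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
        gasAnterior = gasAnterior, gasPosterior = gasPosterior,
        gasJitterSD = gasJitterSD,
        vesselCount = as.integer(vesselCount), vesselRadius = vesselRadius,
        vesselBloodFraction = vesselBloodFraction,
        atelectasisExtent = atelectasisExtent,
        atelectasisGasFraction = atelectasisGasFraction,
        noiseSD = as.numeric(noiseSD),
        tidalAmplitude = tidalAmplitude,
        framesPerCycle = as.integer(framesPerCycle),
        cycles = as.integer(cycles),
        peakCaudalMM = peakCaudalMM, controlSpacingMM = controlSpacingMM,
        displacementProfile = displacementProfile,
        seed = as.integer(seed))
}

#' GroundTruth: a generated phantom with known composition
#'
#' Everything downstream stages estimate, known exactly: true fraction maps,
#' masks (lung, aorta, parasternal muscle), true aeration labels, the true
#' displacement field with per-region mean caudal displacement of the
#' selected slice, and the true tidal phase labels.
#'
#' @slot fractions true \linkS4class{FractionMaps} (mask = lung).
#' @slot lungMask,aortaMask,muscleMask logical arrays; aorta and muscle are
#'   disjoint from the lung.
#' @slot aeration true \linkS4class{AerationMap}.
#' @slot field true \linkS4class{DisplacementField}.
#' @slot sliceMask logical array: the selected 5-mm dCT slice within the lung.
#' @slot regionalDisplacement numeric: true per-region mean caudal
#'   displacement (mm), anterior to posterior.
#' @slot tidalTruth data.frame: frame, time_s, gas_volume_ml, phase for the
#'   noiseless tidal waveform.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("GroundTruth",
         representation(fractions = "FractionMaps", lungMask = "array",
                        aortaMask = "array", muscleMask = "array",
                        aeration = "AerationMap",
                        field = "DisplacementField", sliceMask = "array",
                        regionalDisplacement = "numeric",
                        tidalTruth = "data.frame", spec = "PhantomSpec"))

setValidity("GroundTruth", function(object) {
    if (any(object@aortaMask & object@lungMask) ||
        any(object@muscleMask & object@lungMask))
        return("aorta and muscle ROIs must lie outside the lung mask")
    TRUE
})
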