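#' Calibrate DECT material coefficients from anatomical ROIs
#'
#' DECT coefficients are the CT densities equivalent to 100\% of each basis
#' material at each energy level. Iodinated blood is calibrated as the mean
#' density of a descending-thoracic-aorta ROI at each energy, soft tissue as
#' the mean density of a parasternal-muscle ROI, and gas is fixed at
#' -1000 HU at both energy levels.
#'
#' @param pair a \linkS4class{DectPair}.
#' @param aorta,muscle logical arrays on the pair's grid: calibration ROIs
#'   (both must be non-empty).
#' @return A \linkS4class{MaterialBasis} with provenance
#'   `c("fixed", "roi_mean", "roi_mean")`.
#' @examples
#' spec <- PhantomSpec(dim = c(24, 32, 6), seed = 3)
#' truth <- generatePhantom(spec)
#' pair <- renderDect(truth, defaultMaterialBasis(), noiseSD = c(0, 0))
#' calibrateBasis(pair, truth@aortaMask, truth@muscleMask)
#' @export
calibrateBasis <- function(pair, aorta, muscle) {
    stopifnot(is(pair, "DectPair"))
    .checkMaskOnGrid(aorta, dim(pair@low@voxels), "aorta")
    .checkMaskOnGrid(muscle, dim(pair@low@voxels), "muscle")
    if (!any(aorta)) stop("aorta ROI is empty")
    if (!any(muscle)) stop("muscle ROI is empty")
    roiMean <- function(mask) c(mean(pair@low@voxels[mask]),
                                mean(pair@high@voxels[mask]))
    MaterialBasis(softTissue = roiMean(muscle),
                  iodinatedBlood = roiMean(aorta),
                  provenance = c("fixed", "roi_mean", "roi_mean"))
}

.checkMaskOnGrid <- function(mask, dims, what) {
    if (!is.logical(mask) || !identical(dim(mask), as.integer(dims)))
        stop(sprintf("%s mask must be a logical array on the volume grid",
                     what))
    invisible(TRUE)
}

#' Three-material differentiation of a dual-energy CT pair
#'
#' Solves, per masked voxel, the 3x3 linear system
#' \deqn{HU_{low} = \sum_m f_m C_{m,low},\quad
#'       HU_{high} = \sum_m f_m C_{m,high},\quad \sum_m f_m = 1}
#' for the volume fractions of gas, soft tissue and iodinated blood. Because
#' the system matrix is voxel-independent, one shared inverse is applied to
#' all voxels. Raw solutions falling outside the unit simplex (possible under
#' noise) are clipped at zero and renormalized to sum to one; the Euclidean
#' distance between the raw and projected fraction vector is stored per voxel
#' as a diagnostic residual.
#'
#' @param pair a \linkS4class{DectPair}.
#' @param basis a \linkS4class{MaterialBasis} (condition number < 1e6).
#' @param mask logical array selecting analysis voxels, or NULL for all.
#' @param project clip-and-renormalize onto the simplex (default TRUE).
#'   With `project = FALSE` the raw, possibly out-of-range solutions are
#'   returned (useful to audit noise behaviour: the raw estimator is linear
#'   in the HU noise and therefore unbiased).
#' @return A \linkS4class{FractionMaps}; voxels outside the mask are NA.
#' @examples
#' b <- defaultMaterialBasis()
#' pair <- DectPair(array(-1000, c(2, 2, 1)), array(-1000, c(2, 2, 1)))
#' gasFraction(decomposeDect(pair, b))[1, 1, 1]  # pure gas voxel -> 1
#' @export
decomposeDect <- function(pair, basis, mask = NULL, project = TRUE) {
    stopifnot(is(pair, "DectPair"), is(basis, "MaterialBasis"))
    dims <- dim(pair@low@voxels)
    if (is.null(mask)) mask <- array(TRUE, dims)
    .checkMaskOnGrid(mask, dims, "analysis")
    if (!any(mask)) stop("analysis mask is empty")

    lo <- pair@low@voxels[mask]
    hi <- pair@high@voxels[mask]
    bad <- sum(!is.finite(lo) | !is.finite(hi))
    if (bad > 0)
        stop(sprintf("%d masked voxels have non-finite HU values", bad))

    a <- .basisSystemMatrix(basis@coefficients)
    raw <- solve(a, rbind(lo, hi, 1))       # 3 x n, rows = materials

    if (project) {
        clipped <- pmax(raw, 0)
        f <- sweep(clipped, 2, colSums(clipped), "/")
        residual <- sqrt(colSums((raw - f)^2))
    } else {
        f <- raw
        residual <- rep(0, ncol(raw))
    }

    asMap <- function(v) {
        arr <- array(NA_real_, dims)
        arr[mask] <- v
        arr
    }
    new("FractionMaps",
        gas = asMap(f[1L, ]), tissue = asMap(f[2L, ]), blood = asMap(f[3L, ]),
        mask = mask, residual = asMap(residual),
        spacing = pair@low@spacing, projected = project)
}

#' Merge the two DECT energy volumes
#'
#' Voxelwise linear blend `weightHigh * HU_high + (1 - weightHigh) * HU_low`,
#' producing the mixed image conventionally used for display and
#' segmentation. The default puts 70\% weight on the high-energy image.
#'
#' @param pair a \linkS4class{DectPair}.
#' @param weightHigh blend weight on the high-energy volume, in [0, 1].
#' @return A \linkS4class{CtVolume}.
#' @examples
#' p <- DectPair(array(-800, c(1, 1, 1)), array(-600, c(1, 1, 1)))
#' voxelData(mergeVolumes(p))  # 0.7 * -600 + 0.3 * -800 = -660
#' @export
mergeVolumes <- function(pair, weightHigh = 0.7) {
    stopifnot(is(pair, "DectPair"))
    if (!is.finite(weightHigh) || weightHigh < 0 || weightHigh > 1)
        stop("weightHigh must lie in [0, 1]")
    CtVolume(weightHigh * pair@high@voxels +
             (1 - weightHigh) * pair@low@voxels,
             spacing = pair@low@spacing)
}

#' Non-contrast-equivalent HU of a gas volume fraction
#'
#' The CT density of a gas / soft-tissue mixture on a non-contrast scan,
#' taking soft tissue at 0 HU (water-equivalent) and gas at -1000 HU:
#' `HU = -1000 * gasFraction`. This maps the aeration cutoffs at gas volume
#' fractions 0.10, 0.50 and 0.90 to the familiar -100, -500 and -900 HU
#' thresholds of non-contrast quantitative CT.
#'
#' @param gasFraction numeric vector of gas volume fractions in [0, 1].
#' @return HU values, same length.
#' @examples
#' noncontrastEquivalentHU(c(0.10, 0.50, 0.90))  # -100 -500 -900
#' @export
noncontrastEquivalentHU <- function(gasFraction) {
    if (any(!is.finite(gasFraction)) || any(gasFraction < 0) ||
        any(gasFraction > 1))
        stop("gasFraction must lie in [0, 1]")
    -1000 * gasFraction
}
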