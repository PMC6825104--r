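#' Gas volume of a single dynamic-CT frame
#'
#' Mean gas volume within a frame: the masked slab volume multiplied by the
#' mean gas volume fraction over the mask, i.e. the sum of per-voxel gas
#' fraction times voxel volume.
#'
#' @param fGas 3-D array of gas volume fractions for one frame.
#' @param mask logical array: slab analysis mask (non-empty).
#' @param spacing voxel spacing in mm.
#' @return Gas volume in mL.
#' @examples
#' frameGasVolume(array(0.5, c(10, 10, 1)), array(TRUE, c(10, 10, 1)),
#'                spacing = c(1, 1, 5))  # 50 voxels-mm3 worth of gas
#' @export
frameGasVolume <- function(fGas, mask = NULL, spacing = c(0.5, 0.5, 5)) {
    stopifnot(is.array(fGas))
    if (is.null(mask)) mask <- array(TRUE, dim(fGas))
    .checkMaskOnGrid(mask, dim(fGas), "slab")
    if (!any(mask)) stop("slab mask is empty")
    sum(fGas[mask]) * prod(spacing) / 1000
}

#' Classify dynamic-CT frames as expiratory, inspiratory or excluded
#'
#' For one ventilatory condition, the frames containing the maximum and
#' minimum gas volumes are identified; frames whose gas volume lies within
#' `band` (default 30\%) of the min-to-max range from the minimum are deemed
#' expiratory, within `band` of the range from the maximum inspiratory, and
#' the remaining mid-cycle frames are excluded. Measuring the band against
#' the range (rather than the raw gas-volume value) makes the rule invariant
#' to the offset and scale of the gas volumes.
#'
#' @param series a \linkS4class{FrameSeries}, or a numeric vector of
#'   per-frame gas volumes (mL).
#' @param band fraction of the gas-volume range, in [0, 0.5); with
#'   band < 0.5 the expiratory and inspiratory sets are disjoint.
#' @return data.frame with one row per frame: `frame`, `time_s`,
#'   `gas_volume_ml`, `phase` ("expiratory", "inspiratory" or "excluded").
#' @examples
#' classifyFrames(c(100, 115, 150, 185, 200))$phase
#' @export
classifyFrames <- function(series, band = 0.30) {
    if (is(series, "FrameSeries")) {
        g <- vapply(series@frames, frameGasVolume, numeric(1),
                    mask = series@mask, spacing = series@spacing)
        tm <- series@timestamps
    } else {
        g <- as.numeric(series)
        tm <- seq_along(g) - 1
    }
    if (length(g) < 2L) stop("at least 2 frames are required")
    if (any(!is.finite(g))) stop("gas volumes must be finite")
    if (!is.finite(band) || band < 0 || band >= 0.5)
        stop("band must lie in [0, 0.5): larger bands make the expiratory and inspiratory sets overlap")
    r <- max(g) - min(g)
    if (r == 0)
        stop("degenerate series: no tidal variation in gas volume")

    phase <- rep("excluded", length(g))
    phase[g <= min(g) + band * r] <- "expiratory"
    phase[g >= max(g) - band * r] <- "inspiratory"
    data.frame(frame = seq_along(g), time_s = tm, gas_volume_ml = g,
               phase = phase, stringsAsFactors = FALSE)
}
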