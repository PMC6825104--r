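#' Classify lung voxels into aeration compartments
#'
#' Labels each masked voxel by its gas volume fraction f:
#' atelectasis for f in [0, 0.10), poor aeration for [0.10, 0.50), normal
#' aeration for [0.50, 0.90], overdistension for (0.90, 1]. The printed
#' compartment ranges overlap at their boundaries; this half-open convention
#' (boundary values 0.10 -> poor, 0.50 and 0.90 -> normal) is fixed so the
#' labelling is deterministic. Classification is performed on the gas volume
#' fraction rather than contrast-enhanced HU, which would overestimate the
#' atelectatic fraction in the presence of iodine.
#'
#' @param fGas 3-D array of gas volume fractions (in [0, 1] inside the mask),
#'   or a \linkS4class{FractionMaps} (its mask is then the default mask).
#' @param mask logical array: analysis mask.
#' @param cutoffs strictly increasing gas-fraction cutoffs in (0, 1).
#' @param spacing voxel spacing mm (taken from `fGas` when it is a
#'   FractionMaps).
#' @return An \linkS4class{AerationMap} (label 0 outside the mask).
#' @examples
#' f <- array(c(0.05, 0.3, 0.6, 0.95), c(4, 1, 1))
#' aerationLabels(classifyAeration(f, array(TRUE, c(4, 1, 1))))
#' @export
classifyAeration <- function(fGas, mask = NULL, cutoffs = c(0.10, 0.50, 0.90),
                             spacing = c(0.5, 0.5, 5)) {
    if (is(fGas, "FractionMaps")) {
        if (is.null(mask)) mask <- fGas@mask
        spacing <- fGas@spacing
        fGas <- fGas@gas
    }
    stopifnot(is.array(fGas))
    if (is.null(mask)) mask <- array(TRUE, dim(fGas))
    .checkMaskOnGrid(mask, dim(fGas), "analysis")
    if (length(cutoffs) != 3L || any(diff(cutoffs) <= 0))
        stop("cutoffs must be strictly increasing")
    v <- fGas[mask]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
        stop("gas fractions inside the mask must lie in [0, 1]")

    lab <- integer(length(v))
    lab[v < cutoffs[1]] <- 1L
    lab[v >= cutoffs[1] & v < cutoffs[2]] <- 2L
    lab[v >= cutoffs[2] & v <= cutoffs[3]] <- 3L
    lab[v > cutoffs[3]] <- 4L

    labels <- array(0L, dim(fGas))
    labels[mask] <- lab
    new("AerationMap", labels = labels, cutoffs = as.numeric(cutoffs),
        spacing = as.numeric(spacing))
}

#' Compartment volume fractions of an aeration map
#'
#' Volume fraction (\%) of the masked lung occupied by each aeration
#' compartment, plus the total masked volume in mL. Fractions are voxel
#' counts over the masked count times 100 and sum to 100 by construction.
#'
#' @param aeration an \linkS4class{AerationMap}.
#' @return list with `fractions` (named numeric(4), percent: atelectasis,
#'   poorly_aerated, normally_aerated, overdistended), `counts`
#'   (named integer(4)) and `total_volume_ml`.
#' @examples
#' f <- array(rep(c(0.05, 0.3, 0.6, 0.95), c(2, 3, 4, 1)), c(10, 1, 1))
#' compartmentFractions(classifyAeration(f))$fractions
#' @export
compartmentFractions <- function(aeration) {
    stopifnot(is(aeration, "AerationMap"))
    lab <- aeration@labels[aeration@labels > 0L]
    n <- length(lab)
    if (n == 0L) stop("aeration map has no masked voxels")
    counts <- tabulate(lab, nbins = 4L)
    names(counts) <- names(.AERATION_LEVELS)[-1L]
    list(fractions = counts / n * 100,
         counts = counts,
         total_volume_ml = n * voxelVolumeML(aeration))
}
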