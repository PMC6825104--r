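# band index along the gravitational (anterior->posterior) axis: equal-height
# division of the mask's physical bounding extent [jmin - 0.5, jmax + 0.5]
# (voxel centres at integer indices, each voxel one unit tall). Voxel j falls
# in the smallest band k with (j - jmin + 0.5) / (jmax - jmin + 1) <= k / n;
# evaluated in integer arithmetic so boundary voxels are assigned exactly.
.gravitationalBand <- function(j, jmin, jmax, nRegions) {
    num <- (2L * (j - jmin) + 1L) * as.integer(nRegions)
    den <- 2L * (jmax - jmin + 1L)
    pmin(as.integer(nRegions), pmax(1L, (num + den - 1L) %/% den))
}

#' Extract the cranio-caudal displacement of a slice
#'
#' Pulls the cranio-caudal component (axis-3 component; positive = caudal)
#' of a dense displacement field for the voxels of a selected slab.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param sliceMask logical array on the field grid selecting the slab
#'   (non-empty).
#' @return 3-D numeric array of caudal displacement (mm), NA outside the
#'   mask.
#' @export
ccDisplacementSlice <- function(field, sliceMask) {
    stopifnot(is(field, "DisplacementField"))
    .checkMaskOnGrid(sliceMask, dim(field@field)[1:3], "slice")
    if (!any(sliceMask)) stop("slice mask is empty")
    cc <- field@field[, , , 3L]
    cc[!sliceMask] <- NA_real_
    cc
}

#' Regional mean displacement over gravitational bands
#'
#' Divides the lung mask's anterior-to-posterior bounding extent into
#' `nRegions` bands of equal height along the gravitational axis and
#' averages the caudal displacement within each band. Bands empty of lung
#' voxels (possible near the mask's apex) are reported as NA.
#'
#' @param cc 3-D array of caudal displacement (mm), e.g. from
#'   \code{\link{ccDisplacementSlice}}.
#' @param mask logical array: slice lung mask (defaults to non-NA voxels of
#'   `cc`).
#' @param nRegions number of bands (default 12).
#' @return Numeric(nRegions): mean caudal displacement per band, ordered
#'   anterior to posterior.
#' @export
regionalMeans <- function(cc, mask = NULL, nRegions = 12L) {
    stopifnot(is.array(cc))
    if (nRegions < 1L) stop("nRegions must be >= 1")
    if (is.null(mask)) mask <- !is.na(cc)
    .checkMaskOnGrid(mask, dim(cc), "slice lung")
    if (!any(mask)) stop("slice lung mask is empty")
    idx <- which(mask, arr.ind = TRUE)
    j <- idx[, 2L]
    band <- .gravitationalBand(j, min(j), max(j), nRegions)
    v <- cc[mask]
    means <- rep(NA_real_, nRegions)
    agg <- tapply(v, band, mean)
    means[as.integer(names(agg))] <- agg
    means
}

#' Fractions of the slice moving by caudal-displacement bins
#'
#' Fractions of masked voxels whose caudal displacement falls below one
#' slice thickness (< 5 mm, including any cranial movement), between one and
#' two slices (5-10 mm), and between two and three slices (10-15 mm). Voxels
#' moving more than 15 mm caudally are reported separately; the four
#' fractions always sum to 1.
#'
#' @param cc 3-D array (or numeric vector) of caudal displacement (mm).
#' @param mask logical array (defaults to non-NA entries).
#' @param thresholds increasing bin thresholds in mm (default c(5, 10, 15)).
#' @return Named numeric(4): lt_5mm, mm_5_10, mm_10_15, gt_15mm (names track
#'   the thresholds supplied).
#' @examples
#' movementFractions(c(3, 7, 12, 4))  # 0.50 0.25 0.25 0.00
#' @export
movementFractions <- function(cc, mask = NULL, thresholds = c(5, 10, 15)) {
    if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
        stop("thresholds must be 3 increasing values")
    v <- if (is.array(cc)) {
        if (is.null(mask)) mask <- !is.na(cc)
        .checkMaskOnGrid(mask, dim(cc), "slice")
        cc[mask]
    } else {
        as.numeric(cc)
    }
    if (!length(v)) stop("no masked voxels")
    out <- c(mean(v < thresholds[1]),
             mean(v >= thresholds[1] & v < thresholds[2]),
             mean(v >= thresholds[2] & v <= thresholds[3]),
             mean(v > thresholds[3]))
    names(out) <- c(sprintf("lt_%gmm", thresholds[1]),
                    sprintf("mm_%g_%g", thresholds[1], thresholds[2]),
                    sprintf("mm_%g_%g", thresholds[2], thresholds[3]),
                    sprintf("gt_%gmm", thresholds[3]))
    out
}

#' Median and IQR of displacement summaries by condition group
#'
#' Groups per-condition regional displacement summaries (long format) and
#' reports the median and interquartile range per group. Quantiles use
#' linear interpolation between order statistics (R's default type 7).
#'
#' @param data data.frame in long format with one value column and any
#'   number of grouping columns (e.g. peep, injured, region).
#' @param value name of the value column.
#' @param by character vector of grouping column names.
#' @return data.frame: grouping columns, n, median, iqr.
#' @examples
#' d <- data.frame(peep = c(5, 5, 10, 10), v = c(1, 2, 3, 4))
#' summarizeByCondition(d, "v", "peep")
#' @export
summarizeByCondition <- function(data, value, by) {
    stopifnot(is.data.frame(data), value %in% names(data),
              all(by %in% names(data)))
    v <- data[[value]]
    key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
    groups <- split(seq_len(nrow(data)), key)
    rows <- lapply(groups, function(ix) {
        g <- data[ix[1L], by, drop = FALSE]
        cbind(g,
              data.frame(n = length(ix),
                         median = stats::median(v[ix]),
                         iqr = stats::IQR(v[ix], type = 7)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
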