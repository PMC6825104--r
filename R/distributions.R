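# shared fixed-bin histogram core: left-closed right-open bins, last bin
# closed; out-of-range values excluded from normalization, counted apart
.fixedBinHistogram <- function(values, edges, kind) {
    lo <- edges[1L]
    hi <- edges[length(edges)]
    w <- edges[2L] - edges[1L]
    inRange <- values >= lo & values <= hi
    counts <- numeric(length(edges) - 1L)
    if (any(inRange)) {
        idx <- pmin(floor((values[inRange] - lo) / w) + 1L,
                    length(edges) - 1L)
        tab <- tabulate(idx, nbins = length(counts))
        counts <- tab / sum(tab)
    }
    new("HistogramBins", edges = edges, weights = counts,
        outOfRange = sum(!inRange), nMasked = length(values), kind = kind)
}

#' Normalized CT density histogram
#'
#' Counts masked voxels within 10 HU-wide bins from -1000 to +500 HU
#' (150 bins) and normalizes the counts to sum to 1 so that volumes with
#' differing voxel counts can be compared. Bins are left-closed, right-open,
#' with the last bin closed at +500 HU. Voxels outside [-1000, +500] HU
#' (e.g. dense contrast) are excluded from normalization and counted
#' separately rather than clamped into the edge bins.
#'
#' @param volume a \linkS4class{CtVolume} or 3-D HU array.
#' @param mask logical array (non-empty).
#' @param binWidth bin width in HU (default 10).
#' @param range histogram range in HU (default c(-1000, 500)).
#' @return A \linkS4class{HistogramBins} with kind "hu".
#' @export
densityHistogram <- function(volume, mask = NULL, binWidth = 10,
                             range = c(-1000, 500)) {
    v <- if (is(volume, "CtVolume")) volume@voxels else volume
    stopifnot(is.array(v))
    if (is.null(mask)) mask <- array(TRUE, dim(v))
    .checkMaskOnGrid(mask, dim(v), "histogram")
    if (!any(mask)) stop("histogram mask is empty")
    edges <- seq(range[1], range[2], by = binWidth)
    .fixedBinHistogram(v[mask], edges, kind = "hu")
}

#' Normalized material-fraction histogram
#'
#' Counts masked voxels of a volume-fraction map within 1\%-wide bins from
#' 0\% to 100\% (100 bins), normalized to sum to 1. Same edge conventions as
#' \code{\link{densityHistogram}}; a fraction of exactly 100\% falls in the
#' last bin.
#'
#' @param f 3-D array of volume fractions in [0, 1].
#' @param mask logical array (non-empty).
#' @return A \linkS4class{HistogramBins} with kind "fraction" and edges in
#'   percent.
#' @export
fractionHistogram <- function(f, mask = NULL) {
    stopifnot(is.array(f))
    if (is.null(mask)) mask <- array(TRUE, dim(f))
    .checkMaskOnGrid(mask, dim(f), "histogram")
    if (!any(mask)) stop("histogram mask is empty")
    .fixedBinHistogram(f[mask] * 100, seq(0, 100, by = 1), kind = "fraction")
}

#' Pearson correlation between two paired histograms
#'
#' Pearson's product-moment correlation of the normalized count vectors of
#' two histograms built on identical bin edges, computed over all bins
#' (including bins empty in both histograms, as a fixed-bin design implies).
#'
#' @param a,b \linkS4class{HistogramBins} with identical edges.
#' @return Pearson r in [-1, 1].
#' @export
distributionCorrelation <- function(a, b) {
    stopifnot(is(a, "HistogramBins"), is(b, "HistogramBins"))
    if (length(a@edges) != length(b@edges) ||
        max(abs(a@edges - b@edges)) > 1e-9)
        stop("histograms must share identical bin edges")
    if (stats::sd(a@weights) == 0 || stats::sd(b@weights) == 0)
        stop("correlation undefined: a histogram has zero variance across bins")
    stats::cor(a@weights, b@weights)
}

#' Mean of histograms across volumes
#'
#' Averages the normalized weights of several histograms on identical edges
#' (each input is already normalized, so the mean again sums to 1 when no
#' input had out-of-range-only content). Useful to average distributions
#' across animals/conditions after per-volume normalization.
#'
#' @param histograms list of \linkS4class{HistogramBins} on identical edges.
#' @return A \linkS4class{HistogramBins}.
#' @export
meanHistogram <- function(histograms) {
    stopifnot(length(histograms) >= 1L)
    e <- histograms[[1L]]@edges
    for (h in histograms)
        if (max(abs(h@edges - e)) > 1e-9)
            stop("histograms must share identical bin edges")
    w <- Reduce(`+`, lapply(histograms, binWeights)) / length(histograms)
    new("HistogramBins", edges = e, weights = w,
        outOfRange = sum(vapply(histograms, function(h) h@outOfRange,
                                integer(1))),
        nMasked = sum(vapply(histograms, function(h) h@nMasked, integer(1))),
        kind = histograms[[1L]]@kind)
}
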