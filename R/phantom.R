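# --- internal geometry helpers -----------------------------------------------

# index arrays along each axis for a grid of dims d
.axisIndex <- function(d, axis) {
    slice.index(array(0L, d), axis)
}

# elliptical-cylinder lung mask extruded along the cranio-caudal axis
.lungMask <- function(d) {
    cx <- (d[1] + 1) / 2
    cy <- (d[2] + 1) / 2
    rx <- 0.40 * d[1]
    ry <- 0.42 * d[2]
    x <- .axisIndex(d, 1L)
    y <- .axisIndex(d, 2L)
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

# truncated gaussian jitter: bounded at +/- 3 SD so the gravitational gradient
# ordering cannot be destroyed by a rare tail draw
.truncJitter <- function(n, sd) {
    if (sd <= 0) return(numeric(n))
    pmax(pmin(stats::rnorm(n, 0, sd), 3 * sd), -3 * sd)
}

# brute-force application of the expiratory/inspiratory range rule; kept
# internal to the generator so ground-truth labels do not depend on
# classifyFrames()
.phaseTruth <- function(g, band = 0.30) {
    r <- max(g) - min(g)
    if (r == 0) return(rep(NA_character_, length(g)))
    phase <- rep("excluded", length(g))
    phase[g <= min(g) + band * r] <- "expiratory"
    phase[g >= max(g) - band * r] <- "inspiratory"
    phase
}

# raised-cosine tidal weight in [0, 1]: 0 at end-expiration, 1 at the peak
.tidalWeights <- function(framesPerCycle, cycles) {
    t <- seq_len(framesPerCycle * cycles)
    (1 - cos(2 * pi * (t - 1) / framesPerCycle)) / 2
}

# end-inspiratory gas fraction: fractional recruitment of the non-gas space
.inspiratoryGas <- function(fGas, amplitude, modulated) {
    fi <- fGas
    fi[modulated] <- fGas[modulated] + amplitude * (1 - fGas[modulated])
    fi
}

#' Generate a ground-truth thorax phantom
#'
#' Builds a miniature supine thorax with known per-voxel composition: an
#' elliptical lung with a monotone anterior-to-posterior (gravitational)
#' decrease in gas fraction, cranio-caudal vessel cylinders carrying
#' iodinated blood, a dependent atelectatic mass, aorta and parasternal
#' muscle calibration ROIs outside the lung, true aeration labels, a smooth
#' expiration-to-inspiration displacement field concentrated in the
#' mid-gravitational lung, and the true tidal phase labels of the noiseless
#' gas-volume waveform. All stochastic output is fixed by the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' truth <- generatePhantom(PhantomSpec(dim = c(24, 32, 6), seed = 7))
#' truth
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    set.seed(spec@seed)
    d <- spec@dim
    lung <- .lungMask(d)
    if (!any(lung)) stop("grid too small: empty lung mask")

    y <- .axisIndex(d, 2L)
    jmin <- min(y[lung])
    jmax <- max(y[lung])
    yn <- if (jmax > jmin) (y - jmin) / (jmax - jmin) else array(0.5, d)

    # gravitational gas gradient with bounded voxelwise jitter
    fGas <- array(0, d)
    base <- spec@gasAnterior + (spec@gasPosterior - spec@gasAnterior) * yn
    fGas[lung] <- pmin(pmax(base[lung] +
                            .truncJitter(sum(lung), spec@gasJitterSD), 0), 1)

    # dependent atelectasis: the most posterior fraction of the lung extent
    if (spec@atelectasisExtent > 0) {
        atel <- lung & yn >= 1 - spec@atelectasisExtent
        fGas[atel] <- spec@atelectasisGasFraction
    }

    # vessels: cylinders along the cranio-caudal axis, inside the lung
    fBlood <- array(0, d)
    if (spec@vesselCount > 0L) {
        cx <- (d[1] + 1) / 2
        cy <- (d[2] + 1) / 2
        theta <- stats::runif(spec@vesselCount, 0, 2 * pi)
        rho <- sqrt(stats::runif(spec@vesselCount, 0.05, 0.85))
        vx <- cx + rho * cos(theta) * 0.40 * d[1]
        vy <- cy + rho * sin(theta) * 0.42 * d[2]
        x <- .axisIndex(d, 1L)
        for (v in seq_len(spec@vesselCount)) {
            hit <- lung & ((x - vx[v])^2 + (y - vy[v])^2 <=
                           spec@vesselRadius^2)
            fBlood[hit] <- spec@vesselBloodFraction
            fGas[hit] <- 0
        }
    }

    # calibration ROIs strictly outside the lung
    aorta <- .roiBand(d, lung, side = "posterior", jmin, jmax)
    muscle <- .roiBand(d, lung, side = "anterior", jmin, jmax)

    # non-lung body is soft tissue; aorta is pure iodinated blood
    fBlood[aorta] <- 1
    fGas[aorta] <- 0
    fTissue <- 1 - fGas - fBlood

    fractions <- new("FractionMaps", gas = fGas, tissue = fTissue,
                     blood = fBlood, mask = lung,
                     residual = array(0, d), spacing = spec@spacing,
                     projected = TRUE)
    aeration <- classifyAeration(fGas, lung, spacing = spec@spacing)

    mid <- as.integer(ceiling(d[3] / 2))
    k <- .axisIndex(d, 3L)
    sliceMask <- lung & k == mid

    field <- generateDisplacementField(spec)

    # truth-side regional means: direct per-band averaging via a naive scan
    # over the band inequality, written independently of regionalMeans()
    cc <- field@field[, , , 3L]
    idx <- which(sliceMask, arr.ind = TRUE)
    jv <- idx[, 2L]
    jmin <- min(jv); jmax <- max(jv)
    bands <- vapply(jv, function(j) {
        for (k in 1:12)
            if (12L * (2L * (j - jmin) + 1L) <= 2L * k * (jmax - jmin + 1L))
                return(k)
        12L
    }, integer(1))
    reg <- rep(NA_real_, 12L)
    agg <- tapply(cc[sliceMask], bands, mean)
    reg[as.integer(names(agg))] <- agg

    # noiseless tidal waveform truth for the selected slice
    slabGas <- fGas[, , mid, drop = FALSE]
    slabMask <- sliceMask[, , mid, drop = FALSE]
    modulated <- slabMask & fBlood[, , mid, drop = FALSE] < 0.5
    fEI <- .inspiratoryGas(slabGas, spec@tidalAmplitude, modulated)
    w <- .tidalWeights(spec@framesPerCycle, spec@cycles)
    voxML <- prod(spec@spacing) / 1000
    gEE <- sum(slabGas[slabMask]) * voxML
    gEI <- sum(fEI[slabMask]) * voxML
    g <- gEE + w * (gEI - gEE)
    tidalTruth <- data.frame(frame = seq_along(g), time_s = seq_along(g) - 1,
                             gas_volume_ml = g, phase = .phaseTruth(g),
                             stringsAsFactors = FALSE)

    new("GroundTruth", fractions = fractions, lungMask = lung,
        aortaMask = aorta, muscleMask = muscle, aeration = aeration,
        field = field, sliceMask = sliceMask, regionalDisplacement = reg,
        tidalTruth = tidalTruth, spec = spec)
}

# small ROI band anterior or posterior to the lung, middle of the grid in-plane
.roiBand <- function(d, lung, side, jmin, jmax) {
    y <- .axisIndex(d, 2L)
    x <- .axisIndex(d, 1L)
    xin <- x >= round(d[1] / 3) & x <= round(2 * d[1] / 3)
    roi <- if (side == "anterior") {
        y <= max(1L, jmin - 2L) & xin & !lung
    } else {
        y >= min(d[2], jmax + 2L) & xin & !lung
    }
    if (!any(roi)) roi <- (if (side == "anterior") y == 1L else y == d[2]) & !lung
    if (!any(roi)) stop("grid too small to place calibration ROIs")
    roi
}

#' Forward-render a dual-energy pair from known fractions
#'
#' The linear mixing forward model: per voxel and energy e,
#' `HU_e = sum_m f_m C_{m,e} + N(0, noiseSD_e)`, with noise independent
#' across voxels and energies. This is the exact inverse of
#' \code{\link{decomposeDect}} when the noise is zero.
#'
#' @param truth a \linkS4class{GroundTruth} (its fraction maps are rendered),
#'   or a \linkS4class{FractionMaps}.
#' @param basis a \linkS4class{MaterialBasis}.
#' @param noiseSD numeric(2): HU noise SD at (low, high) energy; defaults to
#'   the generating spec's value (0 for a bare FractionMaps).
#' @param seed integer seed for the noise draw.
#' @return A \linkS4class{DectPair}.
#' @export
renderDect <- function(truth, basis, noiseSD = NULL, seed = NULL) {
    stopifnot(is(basis, "MaterialBasis"))
    if (is(truth, "GroundTruth")) {
        if (is.null(noiseSD)) noiseSD <- truth@spec@noiseSD
        if (is.null(seed)) seed <- truth@spec@seed + 202L
        fr <- truth@fractions
    } else if (is(truth, "FractionMaps")) {
        if (is.null(noiseSD)) noiseSD <- c(0, 0)
        if (is.null(seed)) seed <- 1L
        fr <- truth
    } else {
        stop("truth must be a GroundTruth or FractionMaps")
    }
    vols <- .renderFractionArrays(fr@gas, fr@tissue, fr@blood, basis,
                                  noiseSD, seed)
    DectPair(CtVolume(vols$low, fr@spacing), CtVolume(vols$high, fr@spacing))
}

# array-level forward model shared with the pipeline's per-frame rendering
.renderFractionArrays <- function(gas, tissue, blood, basis, noiseSD, seed) {
    if (!identical(dim(gas), dim(tissue)) || !identical(dim(gas), dim(blood)))
        stop("fraction arrays must share one grid")
    if (any(is.na(gas) | is.na(tissue) | is.na(blood)))
        stop("fraction arrays must be fully defined for rendering")
    co <- basis@coefficients
    set.seed(seed)
    d <- dim(gas)
    render1 <- function(e, sd) {
        hu <- gas * co[1L, e] + tissue * co[2L, e] + blood * co[3L, e]
        if (sd > 0) hu <- hu + array(stats::rnorm(length(hu), 0, sd), d)
        hu
    }
    list(low = render1(1L, noiseSD[1]), high = render1(2L, noiseSD[2]))
}

#' Simulate a tidal dynamic-CT frame series
#'
#' Samples the phantom's selected 5-mm slice at 1 Hz through `cycles`
#' breaths. The gas fraction of each modulated voxel follows a raised-cosine
#' blend between its end-expiratory value f and the end-inspiratory value
#' f + amplitude * (1 - f); the per-frame mean gas volume therefore follows
#' a raised cosine between the end-expiratory and end-inspiratory extremes
#' exactly. True phase labels come from the range rule applied to the
#' noiseless waveform.
#'
#' @param spec a \linkS4class{PhantomSpec} (needs framesPerCycle * cycles
#'   >= 2).
#' @param condition optional list of ventilatory condition metadata attached
#'   to the series.
#' @return list with `series` (a \linkS4class{FrameSeries}) and `truth`
#'   (data.frame: frame, time_s, gas_volume_ml, phase; phase is NA when the
#'   amplitude is zero and the waveform degenerate).
#' @export
simulateTidalSeries <- function(spec, condition = list()) {
    stopifnot(is(spec, "PhantomSpec"))
    if (spec@framesPerCycle * spec@cycles < 2L)
        stop("a tidal series needs at least 2 frames")
    truth <- generatePhantom(spec)
    d <- spec@dim
    mid <- as.integer(ceiling(d[3] / 2))
    slabGas <- truth@fractions@gas[, , mid, drop = FALSE]
    slabBlood <- truth@fractions@blood[, , mid, drop = FALSE]
    slabMask <- truth@sliceMask[, , mid, drop = FALSE]
    modulated <- slabMask & slabBlood < 0.5
    fEI <- .inspiratoryGas(slabGas, spec@tidalAmplitude, modulated)
    w <- .tidalWeights(spec@framesPerCycle, spec@cycles)
    frames <- lapply(w, function(wi) slabGas + wi * (fEI - slabGas))
    series <- FrameSeries(frames, mask = slabMask,
                          spacing = spec@spacing, condition = condition)
    list(series = series, truth = truth@tidalTruth)
}

#' Generate a smooth cranio-caudal displacement field
#'
#' Samples caudal displacement on a coarse control-point grid (default 3-mm
#' spacing) and interpolates trilinearly to the voxel grid, mimicking a
#' B-spline free-form deformation consumed from an external registration.
#' The "midlung" profile peaks in the mid-gravitational lung
#' (peak * sin(pi * y)^2 along the anterior-to-posterior axis, with a small
#' multiplicative control-point jitter in [0.9, 1]); "uniform" yields a
#' constant caudal field equal to the peak. The caudal component is bounded
#' by the spec's peak; the in-plane components are zero.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{DisplacementField}.
#' @export
generateDisplacementField <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    set.seed(spec@seed + 101L)
    d <- spec@dim
    ext <- (d - 1L) * spec@spacing
    ctrlCoords <- lapply(1:3, function(a) {
        n <- max(2L, as.integer(ceiling(ext[a] / spec@controlSpacingMM)) + 1L)
        seq(0, by = spec@controlSpacingMM, length.out = n)
    })
    nc <- lengths(ctrlCoords)

    if (spec@displacementProfile == "uniform") {
        ctrl <- array(spec@peakCaudalMM, nc)
    } else {
        yn <- if (ext[2] > 0) ctrlCoords[[2]] / ext[2] else rep(0.5, nc[2])
        profile <- spec@peakCaudalMM * sin(pi * pmin(yn, 1))^2
        ctrl <- aperm(array(profile, c(nc[2], nc[1], nc[3])), c(2, 1, 3))
        ctrl <- ctrl * array(stats::runif(prod(nc), 0.9, 1), nc)
    }

    vox <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spec@spacing[a])
    cc <- .trilinear(ctrl, ctrlCoords, vox)
    field <- array(0, c(d, 3L))
    field[, , , 3L] <- cc
    DisplacementField(field, spacing = spec@spacing)
}

# trilinear interpolation of a control-point array onto query coordinates
# (per-axis vectors); queries outside the control grid are clamped
.trilinear <- function(ctrl, ctrlCoords, query) {
    locate <- function(q, cgrid) {
        i <- findInterval(q, cgrid, all.inside = TRUE)
        w <- (q - cgrid[i]) / (cgrid[i + 1L] - cgrid[i])
        list(i = i, w = pmin(pmax(w, 0), 1))
    }
    lx <- locate(query[[1]], ctrlCoords[[1]])
    ly <- locate(query[[2]], ctrlCoords[[2]])
    lz <- locate(query[[3]], ctrlCoords[[3]])
    nq <- lengths(query)
    out <- array(0, nq)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wx <- if (dx) lx$w else 1 - lx$w
        wy <- if (dy) ly$w else 1 - ly$w
        wz <- if (dz) lz$w else 1 - lz$w
        sub <- ctrl[lx$i + dx, ly$i + dy, lz$i + dz, drop = FALSE]
        out <- out + sub * outer(outer(wx, wy), wz)
    }
    out
}
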