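.VARIABLES <- c("ct_density_hu", "fv_soft_tissue", "fv_gas",
                "fv_iodinated_blood", "fv_atelectasis", "fv_poorly_aerated",
                "fv_normally_aerated", "fv_overdistended")

#' Summarize the eight variables of interest for one imaging context
#'
#' Mean merged CT density (HU) over the analysis mask; mean volume fractions
#' (\%) of soft tissue, gas and iodinated blood; and the volume fractions
#' (\%) of the four aeration compartments. Fraction statistics are reported
#' on the percentage scale.
#'
#' @param merge a \linkS4class{CtVolume}: the merged DECT volume.
#' @param fractions a \linkS4class{FractionMaps} on the same grid.
#' @param labels an \linkS4class{AerationMap} on the same grid.
#' @param mask logical array: analysis mask (defaults to the fraction maps'
#'   mask).
#' @return Named numeric(8): ct_density_hu, fv_soft_tissue, fv_gas,
#'   fv_iodinated_blood, fv_atelectasis, fv_poorly_aerated,
#'   fv_normally_aerated, fv_overdistended.
#' @export
summarizeVariables <- function(merge, fractions, labels, mask = NULL) {
    stopifnot(is(merge, "CtVolume"), is(fractions, "FractionMaps"),
              is(labels, "AerationMap"))
    dims <- dim(merge@voxels)
    if (!identical(dims, dim(fractions@gas)) ||
        !identical(dims, dim(labels@labels)))
        stop("merge volume, fraction maps and aeration map must share one grid")
    if (is.null(mask)) mask <- fractions@mask
    .checkMaskOnGrid(mask, dims, "analysis")
    if (!any(mask)) stop("analysis mask is empty")

    comp <- compartmentFractions(labels)
    out <- c(mean(merge@voxels[mask]),
             mean(fractions@tissue[mask]) * 100,
             mean(fractions@gas[mask]) * 100,
             mean(fractions@blood[mask]) * 100,
             comp$fractions)
    names(out) <- .VARIABLES
    out
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (dCT minus whole-lung), 95\% limits of agreement
#' (mean +/- 1.96 SD of the paired differences), and 95\% confidence
#' intervals: the CI of the mean difference uses SE = SD/sqrt(n), the CI of
#' each limit of agreement the classical large-sample SE = SD * sqrt(3/n),
#' both with the t quantile on n - 1 degrees of freedom. A two-sided paired
#' t test of zero mean difference is included.
#'
#' @param dct,whole paired numeric vectors (n >= 3, finite), e.g. dynamic
#'   single-slice and whole-lung means across ventilatory conditions.
#' @param conf confidence level (default 0.95).
#' @return One-row data.frame: n, mean_diff (+ CI bounds), sd_diff,
#'   loa_lower / loa_upper (+ CI bounds), t, p.
#' @examples
#' blandAltman(c(1, 3, 4, 7), c(2, 3, 5, 6))
#' @export
blandAltman <- function(dct, whole, conf = 0.95) {
    d <- dct - whole
    n <- length(d)
    if (n < 3L) stop("Bland-Altman analysis needs at least 3 pairs")
    if (any(!is.finite(d))) stop("paired values must be finite")
    m <- mean(d)
    s <- stats::sd(d)
    q <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    # the conventional 1.96 multiplier at 95%, the exact normal quantile
    # otherwise
    z <- if (identical(conf, 0.95)) 1.96 else stats::qnorm(1 - (1 - conf) / 2)
    seMean <- s / sqrt(n)
    seLoa <- s * sqrt(3 / n)
    loaLo <- m - z * s
    loaHi <- m + z * s
    if (s == 0) {
        tstat <- if (m == 0) NA_real_ else sign(m) * Inf
        p <- if (m == 0) NA_real_ else 0
    } else {
        tstat <- m / seMean
        p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
    data.frame(n = n, mean_diff = m,
               mean_diff_lo = m - q * seMean, mean_diff_hi = m + q * seMean,
               sd_diff = s,
               loa_lower = loaLo, loa_lower_lo = loaLo - q * seLoa,
               loa_lower_hi = loaLo + q * seLoa,
               loa_upper = loaHi, loa_upper_lo = loaHi - q * seLoa,
               loa_upper_hi = loaHi + q * seLoa,
               t = tstat, p = p)
}

#' Squared correlation of paired means
#'
#' @param dct,whole paired numeric vectors.
#' @return r^2, the squared Pearson correlation.
#' @export
correlateMeans <- function(dct, whole) {
    if (stats::sd(dct) == 0 || stats::sd(whole) == 0) return(NA_real_)
    stats::cor(dct, whole)^2
}

#' Phase-resolved bias between dynamic-slice and whole-lung means
#'
#' Given per-condition biases (dCT minus whole-lung) observed in expiration
#' and in inspiration, reports per variable the phase means (SD), the paired
#' inspiratory-minus-expiratory difference as mean with 95\% limits
#' (+/- 1.96 x SD of the paired differences), and a two-sided paired t-test
#' p value.
#'
#' @param expiratory,inspiratory numeric matrices or data.frames with one
#'   row per paired condition and one column per variable (or plain numeric
#'   vectors for a single variable).
#' @return data.frame per variable: exp_mean, exp_sd, insp_mean, insp_sd,
#'   diff_mean, diff_lo, diff_hi, p.
#' @examples
#' phaseBias(expiratory = c(-2, -2), inspiratory = c(1, 1))
#' @export
phaseBias <- function(expiratory, inspiratory) {
    e <- as.matrix(expiratory)
    i <- as.matrix(inspiratory)
    if (!identical(dim(e), dim(i)))
        stop("expiratory and inspiratory biases must be paired (same shape)")
    if (nrow(e) < 2L) stop("at least 2 paired conditions are required")
    vars <- colnames(e)
    if (is.null(vars)) vars <- paste0("v", seq_len(ncol(e)))
    out <- lapply(seq_len(ncol(e)), function(k) {
        d <- i[, k] - e[, k]
        sdD <- stats::sd(d)
        p <- if (sdD == 0) {
            if (mean(d) == 0) NA_real_ else 0
        } else {
            2 * stats::pt(-abs(mean(d) / (sdD / sqrt(length(d)))),
                          df = length(d) - 1)
        }
        data.frame(variable = vars[k],
                   exp_mean = mean(e[, k]), exp_sd = stats::sd(e[, k]),
                   insp_mean = mean(i[, k]), insp_sd = stats::sd(i[, k]),
                   diff_mean = mean(d),
                   diff_lo = mean(d) - 1.96 * sdD,
                   diff_hi = mean(d) + 1.96 * sdD,
                   p = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Effect of cranio-caudal slice position on each variable
#'
#' Ordinary least-squares regression of each variable on cranial distance
#' (mm), pooling observations expressed relative to the most caudal slice.
#' Returns the slope per mm of cranial movement and the r^2 of the fit.
#'
#' @param values numeric matrix (or data.frame): one row per observation,
#'   one column per variable; or a numeric vector for one variable.
#' @param offsets numeric: cranial distance (mm) of each observation's slice
#'   relative to the most caudal slice; at least two distinct values.
#' @return data.frame per variable: slope_per_mm, r_squared (NA when the
#'   variable is constant).
#' @examples
#' slicePositionRegression(c(0, 15, 30), c(0, 5, 10))  # slope 3 HU/mm
#' @export
slicePositionRegression <- function(values, offsets) {
    v <- as.matrix(values)
    if (length(offsets) != nrow(v))
        stop("one offset per observation row is required")
    if (length(unique(offsets)) < 2L)
        stop("at least 2 distinct slice offsets are required")
    vars <- colnames(v)
    if (is.null(vars)) vars <- paste0("v", seq_len(ncol(v)))
    out <- lapply(seq_len(ncol(v)), function(k) {
        y <- v[, k]
        if (stats::sd(y) == 0) {
            slope <- 0
            r2 <- NA_real_
        } else {
            fit <- stats::lm(y ~ offsets)
            slope <- unname(stats::coef(fit)[2L])
            tss <- sum((y - mean(y))^2)
            r2 <- 1 - sum(stats::residuals(fit)^2) / tss
        }
        data.frame(variable = vars[k], slope_per_mm = slope, r_squared = r2,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
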