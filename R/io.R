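#' Read and write CT volumes as NIfTI-1
#'
#' Thin wrappers around RNifti keeping voxel spacing in the header.
#' `readCtVolume()` returns a \linkS4class{CtVolume}; `writeCtVolume()`
#' writes one (or a bare array) to `.nii`/`.nii.gz`.
#'
#' @param path file path.
#' @param x a \linkS4class{CtVolume}, \linkS4class{AerationMap} (labels are
#'   written as integers) or 3-D array.
#' @param spacing spacing in mm when `x` is a bare array.
#' @return `readCtVolume()`: a CtVolume; `writeCtVolume()`: the path,
#'   invisibly.
#' @export
readCtVolume <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) > 3L)
        stop(sprintf("%s is not a 3-D volume", path))
    # NIfTI drops trailing singleton dimensions on disk; restore them
    d3 <- c(d, rep(1L, 3L - length(d)))
    sp <- c(RNifti::pixdim(img), rep(1, 3L))[1:3]
    CtVolume(array(as.numeric(img), dim = d3), spacing = sp)
}

#' @rdname readCtVolume
#' @export
writeCtVolume <- function(x, path, spacing = c(0.5, 0.5, 5)) {
    if (is(x, "CtVolume")) {
        arr <- x@voxels
        spacing <- x@spacing
    } else if (is(x, "AerationMap")) {
        arr <- x@labels
        spacing <- x@spacing
    } else {
        arr <- x
    }
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing[seq_along(dim(arr))]
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read and write displacement fields as 4-D NIfTI
#'
#' The field is stored as a 4-D volume with the three displacement
#' components (mm) on the fourth axis; component 3 is cranio-caudal,
#' positive = caudal.
#'
#' @param x a \linkS4class{DisplacementField}.
#' @param path file path.
#' @return `readDisplacementField()`: a DisplacementField;
#'   `writeDisplacementField()`: the path, invisibly.
#' @export
readDisplacementField <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L || d[4] != 3L)
        stop(sprintf("%s is not a 3-component 4-D field", path))
    DisplacementField(array(as.numeric(img), dim = d),
                      spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname readDisplacementField
#' @export
writeDisplacementField <- function(x, path) {
    stopifnot(is(x, "DisplacementField"))
    img <- RNifti::asNifti(x@field)
    RNifti::pixdim(img) <- c(x@spacing, 1)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read and write a material basis as JSON
#'
#' JSON shape: `{"gas": [-1000, -1000], "soft_tissue": [low, high],
#' "iodinated_blood": [low, high]}` (HU at the two energies).
#'
#' @param basis a \linkS4class{MaterialBasis}.
#' @param path file path.
#' @return `readMaterialBasis()`: a MaterialBasis; `writeMaterialBasis()`:
#'   the path, invisibly.
#' @export
readMaterialBasis <- function(path) {
    if (!file.exists(path))
        stop(sprintf("basis file not found: %s", path))
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    MaterialBasis(softTissue = x$soft_tissue,
                  iodinatedBlood = x$iodinated_blood,
                  gas = if (is.null(x$gas)) c(-1000, -1000) else x$gas)
}

#' @rdname readMaterialBasis
#' @export
writeMaterialBasis <- function(basis, path) {
    stopifnot(is(basis, "MaterialBasis"))
    co <- basis@coefficients
    jsonlite::write_json(
        list(gas = co[1L, ], soft_tissue = co[2L, ],
             iodinated_blood = co[3L, ]),
        path, digits = NA)
    invisible(path)
}

#' Histogram as a data.frame
#'
#' @param h a \linkS4class{HistogramBins}.
#' @return data.frame: bin_left, bin_right, weight.
#' @export
histogramTable <- function(h) {
    stopifnot(is(h, "HistogramBins"))
    n <- length(h@weights)
    data.frame(bin_left = h@edges[seq_len(n)],
               bin_right = h@edges[seq_len(n) + 1L],
               weight = h@weights)
}
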