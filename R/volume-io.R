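# Volume I/O and conversion between volume space and the flat per-voxel
# feature representation. All volumes are plain R arrays indexed [i, j, k]
# (0-based world mapping carried by the 4x4 affine); inputs must be
# pre-aligned — no resampling is ever performed.

CHANNEL_NAMES <- c("T1", "T1c", "T2", "Flair")

#' Read a 3-D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3-D double array) and `affine` (4x4
#'   voxel-to-world matrix).
#' @export
read_volume <- function(path) {
    if (!file.exists(path)) stopf("input file does not exist: %s", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    d <- dim(arr)
    if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
        arr <- array(arr, d[1:3])
        d <- dim(arr)
    }
    if (length(d) != 3L)
        stopf("expected a 3-D volume, got %d dimensions: %s", length(d), path)
    storage.mode(arr) <- "double"
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    list(data = arr, affine = aff)
}

#' Write a 3-D volume as NIfTI
#'
#' Integer-typed arrays (label volumes) are written with an integer on-disk
#' datatype so codes round-trip exactly.
#'
#' @param volume 3-D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, affine, path) {
    d <- dim(volume)
    if (is.null(d) || length(d) != 3L || any(d < 1L))
        stopf("volume must be a non-empty 3-D array")
    if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
        stopf("affine must be a 4x4 matrix")
    datatype <- if (is.integer(volume)) "int32" else "double"
    img <- RNifti::asNifti(volume)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Construct and validate a multi-channel study
#'
#' @param channels named list of aligned 3-D arrays; must contain
#'   `T1`, `T1c`, `T2`, `Flair`.
#' @param brain_mask 3-D mask (binarized at > 0).
#' @param affine 4x4 voxel-to-world matrix shared by all volumes.
#' @return object of class `multichannel_study`.
#' @export
multichannel_study <- function(channels, brain_mask, affine = diag(4)) {
    missing <- setdiff(CHANNEL_NAMES, names(channels))
    if (length(missing) > 0)
        stopf("missing channel(s): %s", paste(missing, collapse = ", "))
    channels <- channels[CHANNEL_NAMES]
    mask <- as_mask(brain_mask)
    shape <- dim(mask)
    for (nm in CHANNEL_NAMES) {
        ch <- channels[[nm]]
        if (!identical(dim(ch), shape))
            stopf("co-registration error: channel %s shape (%s) differs from mask (%s)",
                  nm, paste(dim(ch), collapse = "x"), paste(shape, collapse = "x"))
        if (any(!is.finite(ch[mask])))
            stopf("channel %s contains non-finite values inside the brain mask", nm)
    }
    if (!any(mask)) stopf("brain mask has no foreground voxels")
    structure(list(channels = channels, brain_mask = mask,
                   shape = shape, affine = affine),
              class = "multichannel_study")
}

#' Assemble a study from NIfTI files
#'
#' All channels and the mask must share shape and affine (affine tolerance
#' 1e-5); the mask is binarized at > 0.
#'
#' @param channel_paths named character vector/list with entries
#'   `T1`, `T1c`, `T2`, `Flair`.
#' @param mask_path path to the binary brain mask.
#' @return a [multichannel_study()] object.
#' @export
assemble_study <- function(channel_paths, mask_path) {
    missing <- setdiff(CHANNEL_NAMES, names(channel_paths))
    if (length(missing) > 0)
        stopf("missing channel(s): %s", paste(missing, collapse = ", "))
    vols <- lapply(CHANNEL_NAMES, function(nm) read_volume(channel_paths[[nm]]))
    names(vols) <- CHANNEL_NAMES
    msk <- read_volume(mask_path)
    ref_aff <- msk$affine
    for (nm in CHANNEL_NAMES) {
        if (!identical(dim(vols[[nm]]$data), dim(msk$data)))
            stopf("co-registration error: channel %s shape differs from mask", nm)
        if (max(abs(vols[[nm]]$affine - ref_aff)) > 1e-5)
            stopf("co-registration error: channel %s affine differs from mask", nm)
    }
    multichannel_study(lapply(vols, `[[`, "data"), msk$data, ref_aff)
}

#' @export
print.multichannel_study <- function(x, ...) {
    cat(sprintf("<multichannel_study> %s voxels, %d in brain mask\n",
                paste(x$shape, collapse = "x"), sum(x$brain_mask)))
    invisible(x)
}

#' Flatten a stack of volumes to a per-voxel feature matrix
#'
#' Row n holds the values of all stacked volumes at the n-th in-mask voxel.
#' Voxels are ordered by the array's native (column-major) linear index, so
#' the ordering is deterministic and shared by every per-voxel structure in
#' the package (feature rows, MRF neighbour pairs, ICM visit order).
#'
#' @param stack list of aligned 3-D volumes.
#' @param mask 3-D brain mask.
#' @return object of class `feature_matrix`: `values` (N x D), `index_map`
#'   (N x 3 integer voxel coordinates), `shape`.
#' @export
flatten_to_features <- function(stack, mask) {
    if (length(stack) < 1) stopf("stack must contain at least one volume")
    mask <- as_mask(mask)
    if (!any(mask)) stopf("mask has no foreground voxels")
    for (v in stack) check_same_shape(v, mask, "stack volume and mask")
    idx_lin <- which(mask)
    index_map <- which(mask, arr.ind = TRUE)
    dimnames(index_map) <- NULL
    values <- vapply(stack, function(v) v[idx_lin], numeric(length(idx_lin)))
    if (is.null(dim(values))) values <- matrix(values, nrow = length(idx_lin))
    if (any(!is.finite(values))) stopf("non-finite feature values inside the mask")
    structure(list(values = values, index_map = index_map,
                   shape = dim(mask), D = ncol(values)),
              class = "feature_matrix")
}

feature_values <- function(x) {
    if (inherits(x, "feature_matrix")) x$values
    else if (is.matrix(x)) x
    else matrix(as.numeric(x), ncol = 1L)
}

#' Scatter a per-voxel assignment back into a label volume
#'
#' @param assignment length-N integer vector (one entry per in-mask voxel).
#' @param index_map N x 3 integer matrix of voxel coordinates (as produced
#'   by [flatten_to_features()]) or a `feature_matrix`.
#' @param shape integer triple; ignored when `index_map` is a
#'   `feature_matrix`.
#' @param legend optional named character vector mapping labels to names.
#' @return object of class `label_volume` with integer `labels` (0 outside
#'   the mask) and `legend`.
#' @export
scatter_labels <- function(assignment, index_map, shape = NULL, legend = NULL) {
    if (inherits(index_map, "feature_matrix")) {
        shape <- index_map$shape
        index_map <- index_map$index_map
    }
    if (length(assignment) != nrow(index_map))
        stopf("assignment length (%d) does not match index map (%d rows)",
              length(assignment), nrow(index_map))
    labels <- array(0L, shape)
    labels[index_map] <- as.integer(assignment)
    label_volume(labels, legend)
}

#' Construct a label volume
#'
#' @param labels 3-D integer array; 0 is background.
#' @param legend optional named character vector (names = label codes).
#' @export
label_volume <- function(labels, legend = NULL) {
    storage.mode(labels) <- "integer"
    present <- sort(unique(labels[labels > 0L]))
    if (is.null(legend)) {
        legend <- stats::setNames(sprintf("class_%d", present), present)
    } else {
        miss <- setdiff(present, as.integer(names(legend)))
        if (length(miss) > 0)
            stopf("labels %s present but absent from legend", paste(miss, collapse = ", "))
    }
    structure(list(labels = labels, legend = legend), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
    tab <- table(x$labels[x$labels > 0L])
    cat(sprintf("<label_volume> %s; %d positive classes\n",
                paste(dim(x$labels), collapse = "x"), length(tab)))
    invisible(x)
}
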