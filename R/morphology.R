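# 3-D binary morphology on logical arrays. The structuring element is the
# 6-connected cross applied `radius` times (a discrete diamond of the given
# radius); out-of-volume voxels count as background.

#' Binary erosion of a 3-D mask
#'
#' @param mask logical 3-D array.
#' @param radius non-negative integer; number of 6-connected erosion passes.
#' @return logical array of the same shape.
#' @export
binary_erode <- function(mask, radius = 1L) {
    mask <- as_mask(mask)
    if (radius < 0) stopf("radius must be >= 0")
    offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    for (r in seq_len(radius)) {
        out <- mask
        for (q in seq_len(nrow(offs)))
            out <- out & shift_array(mask, offs[q,1], offs[q,2], offs[q,3], fill = FALSE)
        mask <- out
    }
    mask
}

#' Binary dilation of a 3-D mask
#'
#' @inheritParams binary_erode
#' @return logical array of the same shape.
#' @export
binary_dilate <- function(mask, radius = 1L) {
    mask <- as_mask(mask)
    if (radius < 0) stopf("radius must be >= 0")
    offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    for (r in seq_len(radius)) {
        out <- mask
        for (q in seq_len(nrow(offs)))
            out <- out | shift_array(mask, offs[q,1], offs[q,2], offs[q,3], fill = FALSE)
        mask <- out
    }
    mask
}

#' Fill interior holes of a 3-D binary mask
#'
#' A hole is a background component (6-connectivity) not reachable from the
#' volume border.
#' @param mask logical 3-D array.
#' @return logical array with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
    mask <- as_mask(mask)
    reach <- border_background_cpp(mask)
    mask | (!mask & !reach)
}

#' Connected components of a 3-D binary mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 or 26.
#' @return integer array; 0 = background, components numbered from 1.
#' @export
connected_components <- function(mask, connectivity = 26L) {
    mask <- as_mask(mask)
    if (!connectivity %in% c(6L, 26L)) stopf("connectivity must be 6 or 26")
    label_components_cpp(mask, as.integer(connectivity))
}
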