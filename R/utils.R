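stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary_volume <- function(x) {
    is.array(x) && length(dim(x)) == 3L && (is.logical(x) || all(x %in% c(0, 1)))
}

as_mask <- function(x) {
    if (is.logical(x)) return(x)
    m <- x > 0
    storage.mode(m) <- "logical"
    m
}

check_same_shape <- function(a, b, what = "volumes") {
    if (!identical(dim(a), dim(b)))
        stopf("%s have mismatching shapes (%s vs %s)", what,
              paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
    invisible(TRUE)
}

#' Shift a 3-D array by an integer offset
#'
#' Values moved off the grid are discarded; vacated voxels are filled with
#' `fill`. Used by the binary morphology and smoothing helpers.
#' @noRd
shift_array <- function(a, dx, dy, dz, fill = 0) {
    d <- dim(a)
    out <- array(fill, d)
    if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
    sx <- seq.int(max(1, 1 + dx), min(d[1], d[1] + dx))
    sy <- seq.int(max(1, 1 + dy), min(d[2], d[2] + dy))
    sz <- seq.int(max(1, 1 + dz), min(d[3], d[3] + dz))
    out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
    out
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Truncated at 3 sigma; borders are renormalized by smoothing a constant
#' volume so that flat regions stay flat.
#' @noRd
gaussian_smooth_3d <- function(vol, sigma) {
    if (sigma <= 0) return(vol)
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    w <- exp(-((-r:r)^2) / (2 * sigma^2))
    w <- w / sum(w)
    smooth_axis <- function(a, axis) {
        out <- array(0, dim(a))
        for (t in -r:r) {
            off <- c(0L, 0L, 0L)
            off[axis] <- t
            out <- out + w[t + r + 1L] * shift_array(a, off[1], off[2], off[3])
        }
        out
    }
    num <- vol
    den <- array(1, dim(vol))
    for (axis in 1:3) {
        num <- smooth_axis(num, axis)
        den <- smooth_axis(den, axis)
    }
    num / den
}

logsumexp_rows <- function(m) {
    mx <- apply(m, 1L, max)
    mx + log(rowSums(exp(m - mx)))
}

#' Squared Euclidean distances from rows of x to rows of centers
#' @noRd
dist2_to_centers <- function(x, centers) {
    d2 <- matrix(rowSums(x^2), nrow(x), nrow(centers)) +
        rep(rowSums(centers^2), each = nrow(x)) -
        2 * x %*% t(centers)
    d2[d2 < 0] <- 0
    d2
}
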