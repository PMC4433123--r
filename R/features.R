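# First-order texture feature stack and PCA dimensionality reduction.
#
# For each base image (T1, T1c, T2, Flair and the derived T1d = |T1c - T1|)
# the mean, skewness and kurtosis of the intensity values in a local
# (2r+1)^3 neighbourhood are computed at every in-mask voxel, yielding a
# stack of 20 images per study. The stack is standardized and reduced with
# PCA, keeping the smallest number of components explaining at least 99% of
# the variance.

BASE_IMAGE_NAMES <- c("T1", "T1c", "T2", "Flair", "T1d")

#' Contrast-enhancement difference image
#'
#' Element-wise absolute difference |T1c - T1|, highlighting
#' gadolinium-enhancing tissue.
#'
#' @param t1c,t1 aligned 3-D volumes.
#' @return non-negative 3-D volume.
#' @export
compute_t1d <- function(t1c, t1) {
    check_same_shape(t1c, t1, "T1c and T1")
    abs(t1c - t1)
}

#' Local first-order moments of a volume
#'
#' At every in-mask voxel the sample mean, skewness (third standardized
#' moment) and kurtosis (plain fourth standardized moment, Gaussian = 3)
#' of the in-mask voxels of the (2*radius+1)^3 neighbourhood are computed.
#' Neighbourhoods are clipped at volume borders; voxels outside the mask
#' are 0 in all three outputs. Neighbourhoods with fewer than two in-mask
#' voxels, or zero variance, fall back to (value, 0, 0).
#'
#' @param volume 3-D volume.
#' @param mask 3-D brain mask.
#' @param radius neighbourhood radius in voxels (default 2, i.e. 5x5x5).
#' @return list of three 3-D volumes: `mean`, `skewness`, `kurtosis`.
#' @export
local_first_order_moments <- function(volume, mask, radius = 2L) {
    if (radius < 1) stopf("radius must be >= 1")
    mask <- as_mask(mask)
    check_same_shape(volume, mask, "volume and mask")
    if (!any(mask)) stopf("mask has no foreground voxels")
    storage.mode(volume) <- "double"
    local_moments_cpp(volume, mask, as.integer(radius))
}

#' Build the 20-image first-order feature stack
#'
#' Order: the 5 base images (T1, T1c, T2, Flair, T1d), then the local mean
#' of each base, then the local skewness of each, then the local kurtosis
#' of each.
#'
#' @param study a [multichannel_study()].
#' @param radius moment neighbourhood radius (default 2).
#' @return object of class `feature_stack` with `images` (named list of
#'   20 volumes), `radius` and `brain_mask`.
#' @export
build_feature_stack <- function(study, radius = 2L) {
    stopifnot(inherits(study, "multichannel_study"))
    ch <- study$channels
    bases <- list(T1 = ch$T1, T1c = ch$T1c, T2 = ch$T2, Flair = ch$Flair,
                  T1d = compute_t1d(ch$T1c, ch$T1))
    moments <- lapply(bases, local_first_order_moments,
                      mask = study$brain_mask, radius = radius)
    images <- c(bases,
                stats::setNames(lapply(moments, `[[`, "mean"),
                                paste0("mu_", BASE_IMAGE_NAMES)),
                stats::setNames(lapply(moments, `[[`, "skewness"),
                                paste0("skew_", BASE_IMAGE_NAMES)),
                stats::setNames(lapply(moments, `[[`, "kurtosis"),
                                paste0("kurt_", BASE_IMAGE_NAMES)))
    structure(list(images = images, radius = as.integer(radius),
                   brain_mask = study$brain_mask, shape = study$shape,
                   affine = study$affine),
              class = "feature_stack")
}

#' Reduce a feature stack with PCA
#'
#' The stack is flattened over in-mask voxels, each feature standardized
#' (zero mean, unit variance; zero-variance features are centred only), and
#' decomposed with PCA. The smallest K whose cumulative explained variance
#' fraction reaches `var_threshold` is retained.
#'
#' @param stack a `feature_stack` (or any named list of aligned volumes).
#' @param mask brain mask; taken from the stack when omitted.
#' @param var_threshold cumulative explained-variance target (default 0.99).
#' @param standardize scale features to unit variance before PCA
#'   (default TRUE); features are always centred.
#' @return list with `model` (class `pca_model`: `center`, `scale`,
#'   `components` K x D, `rotation_full`, `explained_fractions`, `K`) and
#'   `features` (a `feature_matrix` of N x K component scores).
#' @export
reduce_dimensionality <- function(stack, mask = NULL, var_threshold = 0.99,
                                  standardize = TRUE) {
    if (inherits(stack, "feature_stack")) {
        mask <- mask %||% stack$brain_mask
        images <- stack$images
    } else images <- stack
    if (is.null(mask)) stopf("a brain mask is required")
    fm <- flatten_to_features(images, mask)
    x <- fm$values
    if (nrow(x) <= ncol(x))
        stopf("PCA needs more in-mask voxels (%d) than features (%d)",
              nrow(x), ncol(x))
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    if (!standardize) scl <- rep(1, ncol(x))
    scl[scl == 0] <- 1  # zero-variance features: centre only
    xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    frac <- ev / sum(ev)
    K <- which(cumsum(frac) >= var_threshold - 1e-12)[1]
    model <- structure(list(center = ctr, scale = scl,
                            components = t(pc$rotation[, seq_len(K), drop = FALSE]),
                            rotation_full = pc$rotation,
                            explained_fractions = frac, K = K,
                            feature_names = names(images)),
                       class = "pca_model")
    scores <- xs %*% pc$rotation[, seq_len(K), drop = FALSE]
    features <- structure(list(values = scores, index_map = fm$index_map,
                               shape = fm$shape, D = K),
                          class = "feature_matrix")
    list(model = model, features = features)
}

#' Project new data with a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param x N x D matrix in the original feature space.
#' @param K number of components (default the model's retained K).
#' @export
pca_project <- function(model, x, K = model$K) {
    xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
    xs %*% model$rotation_full[, seq_len(K), drop = FALSE]
}

#' Reconstruct standardized features from component scores
#'
#' @param model a `pca_model`.
#' @param scores N x K matrix of component scores.
#' @export
pca_reconstruct <- function(model, scores) {
    K <- ncol(scores)
    scores %*% t(model$rotation_full[, seq_len(K), drop = FALSE])
}

#' Export the images of a feature stack as NIfTI files
#'
#' Debug aid: writes one file per stack image into `dir`.
#' @param stack a `feature_stack`.
#' @param dir output directory.
#' @export
export_feature_stack <- function(stack, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(stack$images))
        write_volume(stack$images[[nm]], stack$affine,
                     file.path(dir, paste0(nm, ".nii.gz")))
    invisible(dir)
}
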