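# Synthetic multi-channel brain phantom: nested ellipsoidal geometry
# (brain with a cortical GM shell, interior WM, central CSF ventricle, and
# a nested tumour of necrotic core, enhancing rim, non-enhancing region and
# edema halo), per-tissue Gaussian channel intensities, aligned WM/GM/CSF
# probability maps built from the HEALTHY geometry (tumour region filled
# with the enclosing WM), and ground-truth labels. Every pipeline stage is
# testable from these volumes alone.

PHANTOM_TISSUES <- c("CSF", "GM", "WM", "necrosis", "enhancing",
                     "nonenhancing", "edema")
BRATS_CODE <- c(CSF = 0L, GM = 0L, WM = 0L, necrosis = 1L, enhancing = 4L,
                nonenhancing = 3L, edema = 2L)

default_channel_means <- function() {
    m <- rbind(CSF          = c(25, 25, 85, 20),
               GM           = c(55, 55, 55, 45),
               WM           = c(70, 70, 45, 40),
               necrosis     = c(35, 28, 70, 55),
               enhancing    = c(60, 95, 60, 65),
               nonenhancing = c(45, 48, 65, 70),
               edema        = c(50, 52, 75, 90))
    colnames(m) <- CHANNEL_NAMES
    m
}

default_geometry <- function(shape) {
    s <- shape
    ctr <- (s + 1) / 2
    list(brain_center = ctr,
         brain_semi = c(0.406, 0.375, 0.344) * s,
         gm_inner_q = 0.80,               # GM shell: q in (gm_inner_q, 1]
         ventricle_center = ctr + c(-0.075, 0, 0) * s,
         ventricle_semi = c(0.078, 0.0625, 0.0625) * s,
         tumour_center = ctr + c(0.152, 0.100, 0.023) * s,
         edema_semi = c(0.172, 0.155, 0.146) * s,
         nonenh_semi = c(0.135, 0.122, 0.114) * s,
         enh_semi = c(0.098, 0.088, 0.082) * s,
         necro_semi = c(0.062, 0.055, 0.052) * s)
}

#' Specify a synthetic brain phantom
#'
#' @param shape integer triple of volume dimensions (default 64^3).
#' @param geometry nested-ellipsoid parameters; see `default_geometry` in
#'   the package source. Defaults scale with `shape`.
#' @param channel_means 7 x 4 matrix of per-tissue channel means
#'   (rows CSF, GM, WM, necrosis, enhancing, nonenhancing, edema; columns
#'   T1, T1c, T2, Flair), arbitrary intensity units.
#' @param channel_stds per-tissue channel noise standard deviations: a
#'   scalar or a matrix shaped like `channel_means` (default 1.5).
#' @param mode_delta half-distance (intensity units) between the two T1
#'   intensity modes of every tissue (default 2.5). Each tissue is a
#'   mixture of two Gaussians whose T1 means sit at `mean +/- mode_delta`,
#'   assigned to spatially coherent halves of the tissue; 0 disables the
#'   second mode.
#' @param noise_seed RNG seed for the intensity noise (default 42).
#' @param prob_map_smoothing Gaussian sigma (voxels) for the tissue
#'   probability maps (default 1.5).
#' @param name preset name (informational).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), geometry = NULL,
                         channel_means = default_channel_means(),
                         channel_stds = 1.5, mode_delta = 2.5, noise_seed = 42L,
                         prob_map_smoothing = 1.5, name = "custom") {
    shape <- as.integer(shape)
    if (length(shape) != 3L || any(shape < 16L))
        stopf("shape must be three integers >= 16")
    geometry <- geometry %||% default_geometry(shape)
    if (!identical(rownames(channel_means), PHANTOM_TISSUES))
        stopf("channel_means rows must be: %s", paste(PHANTOM_TISSUES, collapse = ", "))
    if (length(channel_stds) == 1L)
        channel_stds <- matrix(channel_stds, 7L, 4L,
                               dimnames = dimnames(default_channel_means()))
    # contrast constraints that the BRATS mapping heuristic relies on
    t1d <- channel_means[, "T1c"] - channel_means[, "T1"]
    tum <- c("necrosis", "enhancing", "nonenhancing", "edema")
    if (names(which.max(t1d)) != "enhancing")
        stopf("enhancing rim must have the maximum T1c - T1 mean")
    if (tum[which.max(channel_means[tum, "Flair"])] != "edema")
        stopf("edema must have the maximum Flair mean among tumour tissues")
    if (tum[which.min(channel_means[tum, "T1c"])] != "necrosis")
        stopf("necrosis must have the minimum T1c mean among tumour tissues")
    structure(list(shape = shape, geometry = geometry,
                   channel_means = channel_means, channel_stds = channel_stds,
                   mode_delta = mode_delta, noise_seed = as.integer(noise_seed),
                   prob_map_smoothing = prob_map_smoothing, name = name),
              class = "phantom_spec")
}

# Quadratic form of the ellipsoid ((x-c)/a)^2 summed over axes, evaluated
# on the full voxel grid.
ellipsoid_q <- function(shape, center, semi) {
    gx <- (seq_len(shape[1]) - center[1]) / semi[1]
    gy <- (seq_len(shape[2]) - center[2]) / semi[2]
    gz <- (seq_len(shape[3]) - center[3]) / semi[3]
    outer(outer(gx^2, gy^2, "+"), gz^2, "+")
}

#' Built-in phantom presets
#'
#' * `low_noise`: default geometry, noise sd 1.5 — inter-tissue channel
#'   separation at least 5x the noise sd.
#' * `moderate_noise`: same geometry, noise sd 4.
#' * `thin_rim`: large necrotic core with an enhancing rim at most 2 voxels
#'   thick, noise sd 1.5.
#' @return named list of `phantom_spec` objects.
#' @export
default_specs <- function() {
    thin_geom <- default_geometry(c(64L, 64L, 64L))
    thin_geom$edema_semi <- c(11.0, 9.9, 9.3)
    thin_geom$nonenh_semi <- c(8.6, 7.8, 7.3)
    thin_geom$enh_semi <- c(7.6, 7.0, 6.6)
    thin_geom$necro_semi <- c(6.6, 6.1, 5.8)
    list(low_noise = phantom_spec(name = "low_noise"),
         moderate_noise = phantom_spec(channel_stds = 4, name = "moderate_noise"),
         thin_rim = phantom_spec(geometry = thin_geom, name = "thin_rim"))
}

#' Generate a synthetic brain study
#'
#' Voxel tissue labels follow the nested-ellipsoid geometry in `spec`;
#' channel
#' intensities are drawn per tissue from the specified Gaussians; WM/GM/CSF
#' probability maps are Gaussian-smoothed indicators of the HEALTHY
#' geometry (the tumour region carries the enclosing WM's probabilities, so
#' the isolation stage's lesion correction is genuinely exercised),
#' renormalized to sum to 1 inside the brain. Deterministic given
#' `spec$noise_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `study` ([multichannel_study()]), `truth`
#'   (`label_volume`, BRATS codes 0-4), `tissues` (`label_volume`, all 7
#'   tissues coded 1-7 in the order CSF, GM, WM, necrosis, enhancing,
#'   nonenhancing, edema), `maps` ([tissue_probability_maps()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
    stopifnot(inherits(spec, "phantom_spec"))
    g <- spec$geometry
    shape <- spec$shape
    qb <- ellipsoid_q(shape, g$brain_center, g$brain_semi)
    brain <- qb <= 1
    tissue <- array(0L, shape)
    tissue[brain & qb > g$gm_inner_q] <- 2L                 # GM shell
    tissue[brain & qb <= g$gm_inner_q] <- 3L                # WM interior
    vent <- ellipsoid_q(shape, g$ventricle_center, g$ventricle_semi) <= 1
    q_ede <- ellipsoid_q(shape, g$tumour_center, g$edema_semi)
    q_non <- ellipsoid_q(shape, g$tumour_center, g$nonenh_semi)
    q_enh <- ellipsoid_q(shape, g$tumour_center, g$enh_semi)
    q_nec <- ellipsoid_q(shape, g$tumour_center, g$necro_semi)
    tumour <- q_ede <= 1
    if (any(tumour & !(tissue == 3L)))
        stopf("phantom spec error: tumour overlaps GM shell, ventricle or background")
    if (any(tumour & vent))
        stopf("phantom spec error: tumour overlaps the ventricle")
    tissue[vent] <- 1L                                      # CSF ventricle
    healthy <- tissue                                       # pre-lesion atlas truth
    tissue[tumour] <- 7L                                    # edema halo
    tissue[q_non <= 1] <- 6L                                # non-enhancing region
    tissue[q_enh <= 1] <- 5L                                # enhancing rim
    tissue[q_nec <= 1] <- 4L                                # necrotic core
    counts <- tabulate(tissue, 7L)
    if (any(counts == 0))
        stopf("phantom spec error: empty compartment(s): %s",
              paste(PHANTOM_TISSUES[counts == 0], collapse = ", "))

    # each tissue is a two-component Gaussian mixture; the modes occupy
    # spatially coherent halves (split at the tissue's median z), keeping
    # the label field smooth as the Ising prior assumes
    kz <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
    mode_b <- array(FALSE, shape)
    for (t in seq_along(PHANTOM_TISSUES)) {
        idx <- which(tissue == t)
        if (length(idx) > 0) mode_b[idx] <- kz[idx] > stats::median(kz[idx])
    }

    set.seed(spec$noise_seed)
    channels <- stats::setNames(vector("list", 4L), CHANNEL_NAMES)
    for (ch in CHANNEL_NAMES) {
        vol <- array(0, shape)
        for (t in seq_along(PHANTOM_TISSUES)) {
            idx <- which(tissue == t)
            mu <- rep(spec$channel_means[PHANTOM_TISSUES[t], ch], length(idx))
            if (ch == "T1" && spec$mode_delta > 0)
                mu <- mu + ifelse(mode_b[idx], spec$mode_delta, -spec$mode_delta)
            vol[idx] <- stats::rnorm(length(idx), mu,
                                     spec$channel_stds[PHANTOM_TISSUES[t], ch])
        }
        channels[[ch]] <- vol
    }

    sigma <- spec$prob_map_smoothing
    raw <- lapply(c(WM = 3L, GM = 2L, CSF = 1L), function(code)
        gaussian_smooth_3d(array(as.numeric(healthy == code), shape), sigma))
    tot <- raw$WM + raw$GM + raw$CSF
    maps <- lapply(raw, function(m) {
        m[brain] <- m[brain] / tot[brain]
        m[!brain] <- 0
        m
    })

    truth <- array(0L, shape)
    for (t in seq_along(PHANTOM_TISSUES))
        truth[tissue == t] <- BRATS_CODE[PHANTOM_TISSUES[t]]

    study <- multichannel_study(channels, brain, affine = diag(4))
    list(study = study,
         truth = label_volume(truth, c(`1` = "necrosis", `2` = "edema",
                                       `3` = "non-enhancing tumour",
                                       `4` = "enhancing tumour")),
         tissues = label_volume(tissue,
                                stats::setNames(PHANTOM_TISSUES, 1:7)),
         maps = tissue_probability_maps(maps),
         spec = spec)
}

#' Write a phantom to the NIfTI file layout the CLI consumes
#'
#' Emits t1, t1c, t2, flair, mask, wm, gm, csf and truth volumes into
#' `dir`.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    st <- phantom$study
    files <- c(t1 = "T1", t1c = "T1c", t2 = "T2", flair = "Flair")
    for (f in names(files))
        write_volume(st$channels[[files[f]]], st$affine,
                     file.path(dir, paste0(f, ".nii.gz")))
    mask <- array(0L, st$shape); mask[st$brain_mask] <- 1L
    write_volume(mask, st$affine, file.path(dir, "mask.nii.gz"))
    for (t in c("wm", "gm", "csf"))
        write_volume(phantom$maps$maps[[toupper(t)]], st$affine,
                     file.path(dir, paste0(t, ".nii.gz")))
    write_volume(phantom$truth$labels, st$affine, file.path(dir, "truth.nii.gz"))
    invisible(dir)
}
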