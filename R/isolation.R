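# Automatic tumour class isolation: identify and remove the classes
# explaining normal tissue (via atlas tissue probability maps corrected in
# a roughly estimated lesion area), remove perimeter and low-rate outlier
# classes, and merge the survivors by statistical distribution similarity.

TISSUE_NAMES <- c("WM", "GM", "CSF")

#' Construct tissue probability maps
#'
#' @param maps named list of aligned 3-D volumes `WM`, `GM`, `CSF` with
#'   values in `[0, 1]`; at each voxel the three probabilities may sum to
#'   at most 1 (lesion correction can remove mass).
#' @param corrected has lesion correction been applied (default FALSE).
#' @export
tissue_probability_maps <- function(maps, corrected = FALSE) {
    missing <- setdiff(TISSUE_NAMES, names(maps))
    if (length(missing) > 0)
        stopf("missing tissue map(s): %s", paste(missing, collapse = ", "))
    maps <- maps[TISSUE_NAMES]
    for (nm in TISSUE_NAMES) {
        m <- maps[[nm]]
        if (min(m) < -1e-6 || max(m) > 1 + 1e-6)
            stopf("tissue map %s has values outside [0, 1]", nm)
    }
    tot <- maps$WM + maps$GM + maps$CSF
    if (max(tot) > 1 + 1e-6)
        stopf("tissue probabilities sum to more than 1 at some voxels (max %.4f)",
              max(tot))
    structure(list(maps = maps, corrected = corrected),
              class = "tissue_probability_maps")
}

#' Approximate lesion mask from FLAIR and T1c hyper-intensity
#'
#' A voxel enters the mask when its intensity exceeds `median + sd`
#' (computed over in-mask voxels) of the FLAIR or of the T1c channel.
#' Interior holes are then filled (6-connectivity background) and voxels in
#' the brain-perimeter shell (brain mask minus its erosion by
#' `perimeter_radius`) are removed. The mask only serves to correct the
#' tissue probability maps; it never alters class shapes.
#'
#' @param study a [multichannel_study()].
#' @param perimeter_radius erosion radius defining the perimeter shell
#'   (default 2).
#' @return logical 3-D lesion mask.
#' @export
compute_lesion_mask <- function(study, perimeter_radius = 2L) {
    stopifnot(inherits(study, "multichannel_study"))
    mask <- study$brain_mask
    if (!any(mask)) stopf("brain mask is empty")
    lesion <- array(FALSE, study$shape)
    for (nm in c("Flair", "T1c")) {
        v <- study$channels[[nm]]
        vals <- v[mask]
        thr <- stats::median(vals) + stats::sd(vals)
        lesion <- lesion | (mask & v > thr)
    }
    lesion <- fill_holes(lesion)
    shell <- mask & !binary_erode(mask, perimeter_radius)
    lesion & mask & !shell
}

#' Correct tissue probability maps inside a lesion mask
#'
#' Every tissue probability at a lesion voxel is set to `epsilon`, removing
#' (nearly all) normal-tissue mass from the lesion area so that tumour
#' classes are not attributed to WM/GM/CSF.
#'
#' @param maps a [tissue_probability_maps()].
#' @param lesion logical 3-D lesion mask.
#' @param epsilon replacement probability in `[0, 1)` (default 1e-6).
#' @export
correct_tissue_maps <- function(maps, lesion, epsilon = 1e-6) {
    stopifnot(inherits(maps, "tissue_probability_maps"))
    if (epsilon < 0 || epsilon >= 1) stopf("epsilon must be in [0, 1)")
    lesion <- as_mask(lesion)
    check_same_shape(maps$maps$WM, lesion, "tissue map and lesion mask")
    out <- maps$maps
    for (nm in TISSUE_NAMES) out[[nm]][lesion] <- epsilon
    tissue_probability_maps(out, corrected = TRUE)
}

#' Attribute segmentation classes to normal tissues
#'
#' For each normal tissue t, computes
#' p(c | t, S) = sum over voxels of class c of p(t|v), divided by the total
#' p(t|v) mass — the share of tissue t explained by class c. Per tissue the
#' shares are sorted descending (ties to the lower class id), cumulative
#' sums are taken, and the classes whose cumulative sum strictly exceeds
#' `tau` form the set Z_t of classes explaining (almost) none of tissue t.
#' The pathological set is the intersection Z of the three Z_t.
#'
#' `rule = "inclusive"` keeps the literal selection (every class with
#' cumulative sum > tau, including the class at which the threshold is
#' crossed); `rule = "exclusive"` starts strictly after the crossing class.
#'
#' @param labelling a `labelling` or an integer assignment vector over the
#'   in-mask voxels.
#' @param index_map N x 3 voxel coordinates (or a `feature_matrix`).
#' @param maps (corrected) [tissue_probability_maps()].
#' @param tau cumulative threshold in (0, 1), default 0.8.
#' @param rule "inclusive" (default) or "exclusive".
#' @return object of class `attribution_table` with `p_ct` (C x 3 matrix),
#'   per-tissue `sorted_classes`, `sorted_probs`, `cumsums`, `z_sets`, the
#'   final `z`, and `tau`.
#' @export
attribute_classes <- function(labelling, index_map, maps, tau = 0.8,
                              rule = c("inclusive", "exclusive")) {
    rule <- match.arg(rule)
    if (tau <= 0 || tau >= 1) stopf("tau must be in (0, 1)")
    stopifnot(inherits(maps, "tissue_probability_maps"))
    assignment <- if (inherits(labelling, "labelling")) labelling$assignment
                  else as.integer(labelling)
    if (inherits(index_map, "feature_matrix")) index_map <- index_map$index_map
    if (length(assignment) != nrow(index_map))
        stopf("assignment length does not match index map")
    classes <- sort(unique(assignment))
    if (length(classes) == 1L)
        warnf("segmentation has a single class; tissue attribution is degenerate")
    C <- length(classes)
    p_ct <- matrix(0, C, 3L, dimnames = list(classes, TISSUE_NAMES))
    sorted_classes <- sorted_probs <- cumsums <- z_sets <- list()
    for (t in TISSUE_NAMES) {
        w <- maps$maps[[t]][index_map]
        denom <- sum(w)
        if (denom <= 0) {
            warnf("tissue %s has zero probability mass; its constraint is vacuous", t)
            p_ct[, t] <- NA_real_
            sorted_classes[[t]] <- classes
            sorted_probs[[t]] <- rep(NA_real_, C)
            cumsums[[t]] <- rep(NA_real_, C)
            z_sets[[t]] <- classes
            next
        }
        pc <- vapply(classes, function(cl) sum(w[assignment == cl]), numeric(1)) / denom
        p_ct[, t] <- pc
        ord <- order(-pc, classes)
        sorted_classes[[t]] <- classes[ord]
        sorted_probs[[t]] <- pc[ord]
        cs <- cumsum(pc[ord])
        cumsums[[t]] <- cs
        sel <- if (rule == "inclusive") which(cs > tau)
               else { k <- which(cs > tau)[1]; if (is.na(k) || k >= C) integer(0) else (k + 1):C }
        z_sets[[t]] <- sorted_classes[[t]][sel]
    }
    z <- Reduce(intersect, z_sets)
    structure(list(p_ct = p_ct, sorted_classes = sorted_classes,
                   sorted_probs = sorted_probs, cumsums = cumsums,
                   z_sets = z_sets, z = sort(z), tau = tau, rule = rule),
              class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
    cat(sprintf("<attribution_table> tau=%.2f rule=%s\n", x$tau, x$rule))
    print(round(x$p_ct, 4))
    cat("pathological classes Z:", paste(x$z, collapse = ", "), "\n")
    invisible(x)
}

#' Remove class components lying on the brain perimeter
#'
#' The perimeter mask is the dilation (by `dilation_radius`) of the
#' brain-boundary shell (brain mask minus its erosion by `erosion_radius`).
#' For every positive class, each 26-connected component with strictly more
#' than 50% of its voxels inside the perimeter mask is erased.
#'
#' @param labels a `label_volume`.
#' @param brain_mask 3-D brain mask.
#' @param dilation_radius default 2.
#' @param erosion_radius default 2.
#' @param max_inside_fraction erase components with a larger inside
#'   fraction (strict; default 0.5).
#' @export
remove_perimeter_classes <- function(labels, brain_mask, dilation_radius = 2L,
                                     erosion_radius = 2L, max_inside_fraction = 0.5) {
    stopifnot(inherits(labels, "label_volume"))
    mask <- as_mask(brain_mask)
    check_same_shape(labels$labels, mask, "label volume and brain mask")
    shell <- mask & !binary_erode(mask, erosion_radius)
    perim <- binary_dilate(shell, dilation_radius)
    lab <- labels$labels
    for (cl in sort(unique(lab[lab > 0L]))) {
        comp <- connected_components(lab == cl, connectivity = 26L)
        for (k in seq_len(max(comp))) {
            inside <- comp == k
            if (sum(inside & perim) > max_inside_fraction * sum(inside))
                lab[inside] <- 0L
        }
    }
    label_volume(lab, labels$legend[as.character(sort(unique(lab[lab > 0L])))])
}

#' Remove classes occurring at a low rate
#'
#' Class occurrence = class voxel count over the total voxel count of all
#' positive classes, computed once before any deletion; classes with
#' occurrence strictly below `min_fraction` are erased.
#'
#' @param labels a `label_volume`.
#' @param min_fraction default 0.01.
#' @export
remove_low_rate_classes <- function(labels, min_fraction = 0.01) {
    stopifnot(inherits(labels, "label_volume"))
    if (min_fraction < 0 || min_fraction >= 1) stopf("min_fraction must be in [0, 1)")
    lab <- labels$labels
    tab <- table(lab[lab > 0L])
    if (length(tab) == 0) stopf("label volume has no positive classes")
    frac <- as.numeric(tab) / sum(tab)
    drop <- as.integer(names(tab))[frac < min_fraction]
    if (length(drop) == length(tab))
        stopf("all classes fall below min_fraction = %g; review the threshold",
              min_fraction)
    lab[lab %in% drop] <- 0L
    label_volume(lab, labels$legend[as.character(sort(unique(lab[lab > 0L])))])
}

#' Kernel density estimates of class feature distributions
#'
#' For every class and every feature dimension a Gaussian-kernel density
#' with Silverman's bandwidth is evaluated on a shared 256-point grid
#' spanning the pooled per-dimension range (padded by 5%), then
#' renormalized to integrate to 1 (trapezoid rule). Degenerate classes
#' (zero spread) fall back to a bandwidth of one grid step.
#'
#' @param features `feature_matrix` or matrix (the reduced feature space).
#' @param labelling `labelling` or assignment vector.
#' @param classes classes to estimate (default: all present).
#' @param n_grid grid resolution (default 256).
#' @param pad fractional range padding (default 0.05).
#' @return object of class `class_density`: `grid` (n_grid x D), `dens`
#'   (list per class of n_grid x D matrices), `bandwidths`, `classes`.
#' @export
estimate_class_densities <- function(features, labelling, classes = NULL,
                                     n_grid = 256L, pad = 0.05) {
    x <- feature_values(features)
    assignment <- if (inherits(labelling, "labelling")) labelling$assignment
                  else as.integer(labelling)
    classes <- classes %||% sort(unique(assignment[assignment > 0L]))
    counts <- vapply(classes, function(cl) sum(assignment == cl), integer(1))
    if (any(counts < 2))
        stopf("class(es) %s have fewer than 2 member voxels",
              paste(classes[counts < 2], collapse = ", "))
    D <- ncol(x)
    keep <- assignment %in% classes
    grid <- sapply(seq_len(D), function(d) {
        rng <- range(x[keep, d])
        span <- diff(rng)
        if (span == 0) span <- max(abs(rng[1]), 1)
        seq(rng[1] - pad * span, rng[2] + pad * span, length.out = n_grid)
    })
    bw <- matrix(0, length(classes), D, dimnames = list(classes, NULL))
    dens <- lapply(classes, function(cl) {
        out <- matrix(0, n_grid, D)
        for (d in seq_len(D)) {
            v <- x[assignment == cl, d]
            b <- stats::bw.nrd0(v)
            if (!is.finite(b) || b <= 0) b <- grid[2, d] - grid[1, d]
            bw[as.character(cl), d] <<- b
            dd <- stats::density(v, bw = b, kernel = "gaussian",
                                 from = grid[1, d], to = grid[n_grid, d], n = n_grid)
            y <- dd$y
            h <- grid[2, d] - grid[1, d]
            area <- h * (sum(y) - (y[1] + y[n_grid]) / 2)
            out[, d] <- if (area > 0) y / area else y
        }
        out
    })
    names(dens) <- classes
    structure(list(grid = grid, dens = dens, bandwidths = bw, classes = classes),
              class = "class_density")
}

#' Jensen-Shannon divergence between two densities on a shared grid
#'
#' Base-2 JSD: \eqn{\tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)},
#' \eqn{m = (p+q)/2}, with the 0 log 0 = 0 convention. Bounded in [0, 1];
#' 0 iff the (normalized) densities are equal, 1 for disjoint supports.
#' Matrix inputs (one column per dimension) are combined by averaging the
#' per-dimension divergences.
#'
#' @param p,q non-negative density values on the same grid (vectors, or
#'   matrices with matching dimensions).
#' @export
js_divergence <- function(p, q) {
    if (is.matrix(p) || is.matrix(q)) {
        if (!identical(dim(p), dim(q))) stopf("density grids do not match")
        return(mean(vapply(seq_len(ncol(p)),
                           function(d) js_divergence(p[, d], q[, d]), numeric(1))))
    }
    if (length(p) != length(q)) stopf("density grids do not match")
    p <- p / sum(p)
    q <- q / sum(q)
    m <- (p + q) / 2
    kl <- function(a, b) {
        nz <- a > 0
        sum(a[nz] * log2(a[nz] / b[nz]))
    }
    0.5 * kl(p, m) + 0.5 * kl(q, m)
}

js_distance_matrix <- function(densities) {
    cl <- densities$classes
    K <- length(cl)
    d <- matrix(0, K, K, dimnames = list(cl, cl))
    if (K > 1)
        for (i in 1:(K - 1)) for (j in (i + 1):K)
            d[i, j] <- d[j, i] <- js_divergence(densities$dens[[i]], densities$dens[[j]])
    d
}

#' Merge similar classes by average-link agglomeration of JSD distances
#'
#' UPGMA agglomeration on the pairwise Jensen-Shannon divergence matrix.
#' Merging continues while the next (smallest average-link) merge distance
#' is strictly below `merge_threshold` or more than `max_classes` groups
#' remain; ties are broken towards the lowest class-id pair. The result
#' always has between 1 and `max_classes` groups.
#'
#' @param densities a `class_density`.
#' @param max_classes maximum surviving groups (default 4).
#' @param merge_threshold JSD (bits) below which classes merge regardless
#'   of the group count (default 0.1).
#' @return named integer vector mapping each input class id to its merged
#'   group (groups numbered 1..K by smallest member id).
#' @export
merge_similar_classes <- function(densities, max_classes = 4L, merge_threshold = 0.1) {
    stopifnot(inherits(densities, "class_density"))
    cl <- as.integer(densities$classes)
    if (length(cl) < 1) stopf("no classes to merge")
    dmat <- js_distance_matrix(densities)
    groups <- as.list(cl)  # members of each active group
    # average-link distance between active groups, updated per merge
    gd <- dmat
    while (length(groups) > 1) {
        K <- length(gd[1, ])
        best <- c(NA_integer_, NA_integer_); bestd <- Inf
        for (i in 1:(K - 1)) for (j in (i + 1):K)
            if (gd[i, j] < bestd) { bestd <- gd[i, j]; best <- c(i, j) }
        if (!(length(groups) > max_classes || bestd < merge_threshold)) break
        i <- best[1]; j <- best[2]
        ni <- length(groups[[i]]); nj <- length(groups[[j]])
        # UPGMA update: unweighted average over all member pairs
        newd <- (ni * gd[i, ] + nj * gd[j, ]) / (ni + nj)
        groups[[i]] <- c(groups[[i]], groups[[j]])
        groups[[j]] <- NULL
        gd[i, ] <- gd[, i] <- newd
        gd <- gd[-j, -j, drop = FALSE]
        diag(gd) <- 0
    }
    ord <- order(vapply(groups, min, integer(1)))
    map <- integer(length(cl))
    names(map) <- cl
    for (g in seq_along(ord)) map[as.character(groups[[ord[g]]])] <- g
    map
}

#' Map merged tumour classes to BRATS label codes
#'
#' Heuristic contrast-based mapping (the compartments' defining MR
#' signatures): the class with the highest mean T1d (= |T1c - T1|) becomes
#' enhancing tumour (4); among the rest, the highest mean FLAIR becomes
#' edema (2); among the rest, the lowest mean T1c becomes necrosis (1); a
#' remaining class becomes non-enhancing tumour (3). With fewer than four
#' classes, codes are assigned in that priority order. Ties break to the
#' lower class id. The mapping is returned in the legend and the `mapping`
#' attribute.
#'
#' @param labels a `label_volume` with at most 4 positive merged classes.
#' @param study the originating [multichannel_study()].
#' @return a `label_volume` using BRATS codes, with a `mapping` attribute
#'   (old class -> BRATS code).
#' @export
assign_brats_labels <- function(labels, study) {
    stopifnot(inherits(labels, "label_volume"),
              inherits(study, "multichannel_study"))
    lab <- labels$labels
    classes <- sort(unique(lab[lab > 0L]))
    if (length(classes) == 0) stopf("no classes to map to BRATS codes")
    if (length(classes) > 4) stopf("more than 4 classes (%d)", length(classes))
    t1d <- compute_t1d(study$channels$T1c, study$channels$T1)
    stat <- function(vol, cl) mean(vol[lab == cl])
    m_t1d <- vapply(classes, stat, numeric(1), vol = t1d)
    m_flair <- vapply(classes, stat, numeric(1), vol = study$channels$Flair)
    m_t1c <- vapply(classes, stat, numeric(1), vol = study$channels$T1c)
    remaining <- classes
    mapping <- integer(0)
    pick <- function(values, decreasing) {
        v <- values[match(remaining, classes)]
        remaining[order(if (decreasing) -v else v, remaining)[1]]
    }
    enh <- pick(m_t1d, TRUE)
    mapping[as.character(enh)] <- 4L
    remaining <- setdiff(remaining, enh)
    if (length(remaining) > 0) {
        ede <- pick(m_flair, TRUE)
        mapping[as.character(ede)] <- 2L
        remaining <- setdiff(remaining, ede)
    }
    if (length(remaining) > 0) {
        nec <- pick(m_t1c, FALSE)
        mapping[as.character(nec)] <- 1L
        remaining <- setdiff(remaining, nec)
    }
    if (length(remaining) > 0) mapping[as.character(remaining)] <- 3L
    out <- array(0L, dim(lab))
    for (cl in classes) out[lab == cl] <- mapping[as.character(cl)]
    legend <- c(`1` = "necrosis", `2` = "edema", `3` = "non-enhancing tumour",
                `4` = "enhancing tumour")
    lv <- label_volume(out, legend[as.character(sort(unique(out[out > 0L])))])
    attr(lv, "mapping") <- mapping
    lv
}
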