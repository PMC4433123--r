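# Gaussian hidden Markov random field segmentation. The generative model is
# p(X, Y) = (1/Z) exp(-U(X|Y) - U(Y)) with Gaussian emission energy
# U(X|Y) = sum_n -log N(x_n | mu_{y_n}, Sigma_{y_n}) and an Ising prior
# U(Y) = beta * sum_{(n,m) in Q} [y_n != y_m] over the 6-connected in-mask
# neighbour pairs Q. The partition function Z is never needed for MAP
# labelling or hard-EM parameter estimation and is not computed. MAP
# labelling uses iterated conditional modes (deterministic, energy
# non-increasing); parameters are ML Gaussian updates from the hard labels.

#' Build the MRF specification for a brain mask
#'
#' Enumerates the unordered 6-connectivity neighbour pairs between in-mask
#' voxels, indexed by the voxel's row in the flattened feature matrix
#' (column-major in-mask order).
#'
#' @param mask 3-D brain mask.
#' @param beta pairwise Ising weight (default 1).
#' @return object of class `mrf_spec` with `pairs` (M x 2 integer matrix),
#'   `beta` and `n_voxels`.
#' @export
make_mrf_spec <- function(mask, beta = 1.0) {
    mask <- as_mask(mask)
    rowid <- array(0L, dim(mask))
    rowid[mask] <- seq_len(sum(mask))
    pairs <- vector("list", 3L)
    for (axis in 1:3) {
        off <- c(0L, 0L, 0L); off[axis] <- 1L
        nb <- shift_array(rowid, -off[1], -off[2], -off[3], fill = 0L)
        ok <- mask & nb > 0L
        pairs[[axis]] <- cbind(rowid[ok], nb[ok])
    }
    pairs <- do.call(rbind, pairs)
    structure(list(pairs = pairs, beta = beta, n_voxels = sum(mask)),
              class = "mrf_spec")
}

#' Ising prior energy of a labelling
#'
#' `beta` times the number of neighbour pairs with differing labels.
#'
#' @param assignment integer label per in-mask voxel.
#' @param mrf an `mrf_spec`.
#' @export
ising_energy <- function(assignment, mrf) {
    p <- mrf$pairs
    if (length(p) > 0 && max(p) > length(assignment))
        stopf("assignment (length %d) does not cover all pair endpoints (max %d)",
              length(assignment), max(p))
    mrf$beta * sum(assignment[p[, 1]] != assignment[p[, 2]])
}

ghmrf_total_energy <- function(logd, assignment, mrf) {
    -sum(logd[cbind(seq_along(assignment), assignment)]) +
        ising_energy(assignment, mrf)
}

#' Fit a Gaussian hidden Markov random field by hard EM
#'
#' Each cycle alternates a labelling step — ICM sweeps minimizing the total
#' energy, visiting voxels in the deterministic flattened order with ties
#' broken towards the lowest label — and a parameter step updating each
#' class's Gaussian by maximum likelihood from the hard labels (with the
#' covariance ridge). The total energy is non-increasing within each
#' labelling step; the fit stops when a full cycle leaves the labelling
#' unchanged or `max_iter` cycles are reached. With `beta = 0` the
#' procedure reduces exactly to uniform-prior classification EM.
#'
#' Emptied classes are re-seeded to the worst-fit voxel under the current
#' model.
#'
#' @inheritParams fit_kmeans
#' @param mrf an `mrf_spec` over the same voxels as `features` (its `beta`
#'   is used).
#' @param icm_sweeps ICM sweeps per labelling step (default 5).
#' @param tol unused (labelling stability is the stop rule); kept for
#'   interface symmetry.
#' @param ridge covariance regularization factor (default 1e-6).
#' @return list with `model` (`cluster_model`, `nll` = uniform-prior
#'   mixture NLL), `labelling`, and `energy_trace` (total energy after each
#'   labelling step).
#' @export
fit_ghmrf <- function(features, seeds, mrf, max_iter = 200L, icm_sweeps = 5L,
                      tol = 1e-6, ridge = 1e-6) {
    stopifnot(inherits(mrf, "mrf_spec"))
    x <- feature_values(features)
    N <- nrow(x); D <- ncol(x)
    if (mrf$n_voxels != N)
        stopf("MRF spec covers %d voxels but features have %d rows", mrf$n_voxels, N)
    means <- as.matrix(seeds)
    C <- nrow(means)
    gcov <- global_covariance(x)
    covariances <- array(0, c(C, D, D))
    for (c in seq_len(C)) covariances[c, , ] <- gcov
    logd <- gaussian_log_densities(x, means, covariances)
    labels <- max.col(logd, ties.method = "first")
    energy_trace <- numeric(0)
    iter <- 0L
    repeat {
        iter <- iter + 1L
        # labelling step: ICM on the current emission energies
        icm <- icm_sweeps_cpp(-logd, mrf$pairs[, 1], mrf$pairs[, 2], mrf$beta,
                              labels, as.integer(icm_sweeps))
        new_labels <- icm$labels
        energy_trace <- c(energy_trace, icm$energy[length(icm$energy)])
        empty <- setdiff(seq_len(C), unique(new_labels))
        if (length(empty) > 0) {
            rs <- reseed_empty_classes(x, new_labels, means, covariances, empty)
            new_labels <- rs$assignment; means <- rs$means; covariances <- rs$covariances
        }
        converged <- identical(new_labels, labels) && iter > 1L
        labels <- new_labels
        # parameter step: ML Gaussian update from the hard labels
        ms <- mstep_hard_cpp(x, labels, C, ridge)
        means <- ms$means
        covariances <- aperm(ms$covariances, c(3, 1, 2))
        logd <- gaussian_log_densities(x, means, covariances)
        if (converged || iter >= max_iter) break
    }
    priors <- rep(1 / C, C)
    nll <- -sum(logsumexp_rows(sweep(logd, 2L, log(priors), "+")))
    model <- new_cluster_model("ghmrf", means, covariances, priors,
                               objective = ghmrf_total_energy(logd, labels, mrf),
                               nll = nll, n_iter = iter)
    list(model = model, labelling = new_labelling(labels),
         energy_trace = energy_trace)
}

#' Run ICM sweeps on fixed emission energies
#'
#' Exposed for inspection and testing of the labelling step in isolation.
#'
#' @param cost N x C emission energy matrix (-log densities).
#' @param mrf an `mrf_spec`.
#' @param labels initial labels (1..C).
#' @param sweeps maximum number of sweeps.
#' @return list with `labels`, per-sweep total `energy`, and `changed`.
#' @export
icm_label <- function(cost, mrf, labels, sweeps = 5L) {
    icm_sweeps_cpp(cost, mrf$pairs[, 1], mrf$pairs[, 2], mrf$beta,
                   as.integer(labels), as.integer(sweeps))
}
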