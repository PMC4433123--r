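# K-means++ multi-start model selection: 100 seedings, keep the 10 with the
# lowest mean nearest-seed squared distance, fit each, select the best fit
# by intra-cluster distance objective (k-means variants) or lowest mixture
# negative log-likelihood (GMM, GHMRF).

#' Multi-start fitting with K-means++ seeding
#'
#' Generates `n_inits` K-means++ seedings, ranks them with
#' [rank_seedings()] keeping `keep`, fits the chosen algorithm from each
#' kept seeding, and returns the best fit: lowest distance objective for
#' `kmeans`/`fuzzy`, lowest negative log-likelihood for `gmm`/`ghmrf`.
#' Deterministic given `seed`.
#'
#' @param features a `feature_matrix` or matrix.
#' @param C number of classes.
#' @param algorithm one of "kmeans", "fuzzy", "gmm", "ghmrf".
#' @param n_inits number of K-means++ seedings (default 100).
#' @param keep number of seedings fitted (default 10).
#' @param seed integer RNG seed for the seeding stage.
#' @param mrf an `mrf_spec`; required for (and only for) "ghmrf".
#' @param ... further arguments passed to the fitting function
#'   (`m`, `max_iter`, `tol`, `icm_sweeps`, ...).
#' @return list with `model`, `labelling`, `selection` (criterion values of
#'   all fitted candidates) and `best` (index of the chosen candidate).
#' @export
run_multistart <- function(features, C, algorithm = c("kmeans", "fuzzy", "gmm", "ghmrf"),
                           n_inits = 100L, keep = 10L, seed = NULL, mrf = NULL, ...) {
    algorithm <- match.arg(algorithm)
    if (algorithm == "ghmrf" && is.null(mrf))
        stopf("algorithm 'ghmrf' requires an mrf_spec")
    if (keep > n_inits) stopf("keep (%d) cannot exceed n_inits (%d)", keep, n_inits)
    if (!is.null(seed)) set.seed(seed)
    seed_sets <- lapply(seq_len(n_inits), function(i) kmeanspp_seed(features, C))
    kept <- rank_seedings(features, seed_sets, keep = keep)
    fits <- lapply(kept, function(s) {
        switch(algorithm,
               kmeans = fit_kmeans(features, s, ...),
               fuzzy  = fit_fuzzy_kmeans(features, s, ...),
               gmm    = fit_gmm(features, s, ...),
               ghmrf  = fit_ghmrf(features, s, mrf = mrf, ...))
    })
    crit <- vapply(fits, function(f) {
        if (algorithm %in% c("kmeans", "fuzzy")) f$model$objective else f$model$nll
    }, numeric(1))
    best <- which.min(crit)
    c(fits[[best]], list(selection = crit, best = best))
}
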