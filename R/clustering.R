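# Unsupervised voxel classifiers: K-means++, K-means, fuzzy K-means and
# Gaussian mixture EM. All fits are deterministic given their inputs; the
# only randomness is in the K-means++ seeding.

new_cluster_model <- function(kind, means, covariances, priors, objective,
                              nll = NA_real_, n_iter = 0L) {
    structure(list(model_kind = kind, C = nrow(means), D = ncol(means),
                   means = means, covariances = covariances, priors = priors,
                   objective = objective, nll = nll, n_iter = n_iter),
              class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
    cat(sprintf("<cluster_model:%s> C=%d D=%d objective=%.6g n_iter=%d\n",
                x$model_kind, x$C, x$D, x$objective, x$n_iter))
    invisible(x)
}

new_labelling <- function(assignment, memberships = NULL) {
    structure(list(assignment = as.integer(assignment), memberships = memberships),
              class = "labelling")
}

identity_covariances <- function(C, D) {
    cov <- array(0, c(C, D, D))
    for (c in seq_len(C)) cov[c, , ] <- diag(D)
    cov
}

#' K-means++ seeding
#'
#' The first seed is drawn uniformly from the data rows; each further seed
#' is drawn with probability proportional to the squared distance to the
#' nearest already-chosen seed.
#'
#' @param features a `feature_matrix` or plain matrix.
#' @param C number of seeds.
#' @param seed optional integer; when given, `set.seed` is called so the
#'   seeding is reproducible. When NULL the current RNG stream is used.
#' @return C x D matrix of seed points.
#' @export
kmeanspp_seed <- function(features, C, seed = NULL) {
    x <- feature_values(features)
    N <- nrow(x)
    if (C < 1 || C > N) stopf("need 1 <= C (%d) <= N (%d)", C, N)
    if (!is.null(seed)) set.seed(seed)
    chosen <- integer(C)
    chosen[1] <- sample.int(N, 1L)
    if (C > 1) {
        d2 <- rowSums(sweep(x, 2L, x[chosen[1], ])^2)
        for (c in 2:C) {
            tot <- sum(d2)
            if (tot <= 0) {
                # all remaining points coincide with a seed: pick uniformly
                chosen[c] <- sample.int(N, 1L)
            } else {
                chosen[c] <- sample.int(N, 1L, prob = d2 / tot)
            }
            d2 <- pmin(d2, rowSums(sweep(x, 2L, x[chosen[c], ])^2))
        }
    }
    x[chosen, , drop = FALSE]
}

#' Rank candidate seedings by their intra-cluster distance score
#'
#' Score of a seed-set = mean over data points of the squared distance to
#' the nearest seed; the `keep` lowest-scoring sets are returned (ties kept
#' in input order). Duplicate seed-sets — which arise when the data has few
#' distinct rows, never at voxel scale — count once, so the kept list holds
#' `keep` distinct initializations whenever that many exist.
#'
#' @param features a `feature_matrix` or matrix.
#' @param seed_sets list of C x D seed matrices.
#' @param keep number of seedings to keep (default 10).
#' @return list of the kept seed matrices, best first.
#' @export
rank_seedings <- function(features, seed_sets, keep = 10L) {
    if (length(seed_sets) < 1) stopf("no seed-sets provided")
    if (length(seed_sets) < keep)
        stopf("need at least `keep` (%d) seed-sets, got %d", keep, length(seed_sets))
    x <- feature_values(features)
    scores <- vapply(seed_sets, function(s) mean(apply(dist2_to_centers(x, s), 1L, min)),
                     numeric(1))
    ord <- order(scores)
    # drop duplicate seed-sets (row order within a set is irrelevant)
    keys <- vapply(seed_sets, function(s) {
        s <- s[do.call(order, as.data.frame(s)), , drop = FALSE]
        paste(signif(s, 12), collapse = ",")
    }, character(1))
    ord_distinct <- ord[!duplicated(keys[ord])]
    if (length(ord_distinct) < keep)
        ord_distinct <- c(ord_distinct,
                          setdiff(ord, ord_distinct)[seq_len(keep - length(ord_distinct))])
    seed_sets[ord_distinct[seq_len(keep)]]
}

#' K-means clustering (Lloyd iterations)
#'
#' Minimizes the total within-cluster sum of squared point-to-centroid
#' distances. Statistically this is the hard-EM limit of a Gaussian mixture
#' with shared identity covariance and uniform priors, which is how the
#' returned `cluster_model` reports its covariances and priors. An emptied
#' cluster is re-seeded to the point farthest from its assigned centroid.
#'
#' @param features a `feature_matrix` or matrix.
#' @param seeds C x D initial centroid matrix.
#' @param max_iter iteration cap (default 200).
#' @param tol unused for k-means (assignment stability is the stop rule);
#'   kept for interface symmetry.
#' @return list with `model` (`cluster_model`) and `labelling`.
#' @export
fit_kmeans <- function(features, seeds, max_iter = 200L, tol = 1e-6) {
    x <- feature_values(features)
    centers <- as.matrix(seeds)
    C <- nrow(centers)
    assign_old <- rep(0L, nrow(x))
    iter <- 0L
    repeat {
        iter <- iter + 1L
        d2 <- dist2_to_centers(x, centers)
        assignment <- max.col(-d2, ties.method = "first")
        for (c in seq_len(C)) {
            if (!any(assignment == c)) {
                # empty cluster: re-seed to the globally farthest point
                far <- which.max(d2[cbind(seq_len(nrow(x)), assignment)])
                centers[c, ] <- x[far, ]
                assignment[far] <- c
            }
        }
        if (identical(assignment, assign_old) || iter >= max_iter) break
        assign_old <- assignment
        for (c in seq_len(C))
            centers[c, ] <- colMeans(x[assignment == c, , drop = FALSE])
    }
    d2 <- dist2_to_centers(x, centers)
    objective <- sum(d2[cbind(seq_along(assignment), assignment)])
    model <- new_cluster_model("kmeans", centers, identity_covariances(C, ncol(x)),
                               rep(1 / C, C), objective, n_iter = iter)
    list(model = model, labelling = new_labelling(assignment))
}

#' Fuzzy K-means (fuzzy c-means) clustering
#'
#' Alternates the membership update
#' \deqn{u_{nc} = 1 / \sum_j (d_{nc}^2 / d_{nj}^2)^{1/(m-1)}}
#' with the weighted centroid update \eqn{\mu_c = \sum_n u_{nc}^m x_n /
#' \sum_n u_{nc}^m}. A point coincident with a centroid takes membership 1
#' there (limit convention, lowest such centroid on ties).
#'
#' @inheritParams fit_kmeans
#' @param m fuzziness exponent, > 1 (default 2).
#' @param tol stopping tolerance on the largest membership change between
#'   consecutive iterations.
#' @return list with `model` and `labelling` (memberships included).
#' @export
fit_fuzzy_kmeans <- function(features, seeds, m = 2, max_iter = 200L, tol = 1e-6) {
    if (m <= 1) stopf("fuzziness m must be > 1")
    x <- feature_values(features)
    centers <- as.matrix(seeds)
    C <- nrow(centers)
    N <- nrow(x)
    u_old <- NULL
    iter <- 0L
    repeat {
        iter <- iter + 1L
        d2 <- dist2_to_centers(x, centers)
        w <- d2^(-1 / (m - 1))
        zero <- d2 <= .Machine$double.eps
        u <- w / rowSums(w)
        hit <- rowSums(zero) > 0
        if (any(hit)) {
            u[hit, ] <- 0
            first0 <- apply(zero[hit, , drop = FALSE], 1L, which.max)
            u[cbind(which(hit), first0)] <- 1
        }
        um <- u^m
        objective <- sum(um * d2)
        wsum <- colSums(um)
        centers <- (t(um) %*% x) / wsum
        delta <- if (is.null(u_old)) Inf else max(abs(u - u_old))
        u_old <- u
        if (delta <= tol || iter >= max_iter) break
    }
    assignment <- max.col(u, ties.method = "first")
    model <- new_cluster_model("fuzzy", centers, identity_covariances(C, ncol(x)),
                               rep(1 / C, C), objective, n_iter = iter)
    list(model = model, labelling = new_labelling(assignment, memberships = u))
}

# Per-class Gaussian log densities; cov array C x D x D (converted to the
# compiled kernel's D x D x C layout). Errors when a class covariance is
# not positive definite.
gaussian_log_densities <- function(x, means, covariances) {
    gauss_logdens_cpp(x, means, aperm(covariances, c(2, 3, 1)))
}

cov_ridge <- function(S, eps = 1e-6) {
    D <- ncol(S)
    lambda <- max(eps * sum(diag(S)) / D, 1e-12)
    S + diag(lambda, D)
}

global_covariance <- function(x) {
    xc <- sweep(x, 2L, colMeans(x))
    cov_ridge(crossprod(xc) / nrow(x))
}

# Re-seed an emptied class to the worst-fit voxel under the current model
# (shared by hard-EM GMM and GHMRF so their beta = 0 behaviour coincides).
reseed_empty_classes <- function(x, assignment, means, covariances, empty) {
    logd <- gaussian_log_densities(x, means, covariances)
    fit <- logd[cbind(seq_along(assignment), assignment)]
    gcov <- global_covariance(x)
    for (c in empty) {
        worst <- which.min(fit)
        means[c, ] <- x[worst, ]
        covariances[c, , ] <- gcov
        assignment[worst] <- c
        fit[worst] <- Inf
    }
    list(assignment = assignment, means = means, covariances = covariances)
}

#' Gaussian mixture model clustering by (hard or soft) EM
#'
#' Full-covariance EM for \eqn{p(x) = \sum_c p_c N(x | \mu_c, \Sigma_c)}.
#' Means start from the seeds, covariances from the global data covariance
#' and priors uniform. Each M-step adds a covariance ridge
#' `ridge * trace/D` to keep the estimates positive definite.
#'
#' With `assignment = "soft"` (default) responsibilities are used and the
#' fit stops when the relative NLL change drops below `tol`. With
#' `assignment = "hard"` the fit is classification EM: each voxel is wholly
#' assigned to its best class, parameters are ML estimates from the hard
#' partition, and the fit stops when the labelling stabilizes. With
#' `update_priors = FALSE` the priors stay uniform (the no-prior
#' classification EM matched by the MRF model at beta = 0).
#'
#' @inheritParams fit_kmeans
#' @param tol relative NLL stopping tolerance (soft EM).
#' @param assignment "soft" or "hard".
#' @param update_priors update mixing priors each M-step (default TRUE).
#' @param ridge covariance regularization factor (default 1e-6).
#' @return list with `model` and `labelling` (posterior memberships for
#'   soft EM).
#' @export
fit_gmm <- function(features, seeds, max_iter = 200L, tol = 1e-6,
                    assignment = c("soft", "hard"), update_priors = TRUE,
                    ridge = 1e-6) {
    assignment <- match.arg(assignment)
    x <- feature_values(features)
    N <- nrow(x); D <- ncol(x)
    means <- as.matrix(seeds)
    C <- nrow(means)
    if (N <= C * D)
        warnf("only %d points for %d Gaussian components in %d dimensions", N, C, D)
    gcov <- global_covariance(x)
    covariances <- array(0, c(C, D, D))
    for (c in seq_len(C)) covariances[c, , ] <- gcov
    priors <- rep(1 / C, C)
    if (assignment == "soft") {
        fit <- gmm_em_cpp(x, means, aperm(covariances, c(2, 3, 1)), priors,
                          as.integer(max_iter), tol, ridge, update_priors)
        model <- new_cluster_model("gmm", fit$means,
                                   aperm(fit$covariances, c(3, 1, 2)),
                                   as.numeric(fit$priors),
                                   objective = fit$nll, nll = fit$nll,
                                   n_iter = fit$n_iter)
        model$nll_trace <- as.numeric(fit$nll_trace)
        lab <- new_labelling(max.col(fit$resp, ties.method = "first"),
                             memberships = fit$resp)
        return(list(model = model, labelling = lab))
    }
    # classification (hard) EM
    labels_old <- rep(0L, N)
    iter <- 0L
    hard <- NULL
    repeat {
        iter <- iter + 1L
        logd <- gaussian_log_densities(x, means, covariances)
        logj <- sweep(logd, 2L, log(priors), "+")
        hard <- max.col(logj, ties.method = "first")
        empty <- setdiff(seq_len(C), unique(hard))
        if (length(empty) > 0) {
            rs <- reseed_empty_classes(x, hard, means, covariances, empty)
            hard <- rs$assignment; means <- rs$means; covariances <- rs$covariances
        }
        converged <- identical(hard, labels_old)
        labels_old <- hard
        if (update_priors) priors <- tabulate(hard, C) / N
        ms <- mstep_hard_cpp(x, hard, C, ridge)
        means <- ms$means
        covariances <- aperm(ms$covariances, c(3, 1, 2))
        if (converged || iter >= max_iter) break
    }
    nll <- negative_log_likelihood(x, list(means = means, covariances = covariances,
                                           priors = priors))
    model <- new_cluster_model("gmm", means, covariances, priors,
                               objective = nll, nll = nll, n_iter = iter)
    list(model = model, labelling = new_labelling(hard))
}

#' Negative log-likelihood of data under a Gaussian mixture model
#'
#' \eqn{-\sum_n \log \sum_c p_c N(x_n|\mu_c,\Sigma_c)}, computed with
#' log-sum-exp stabilization.
#'
#' @param features a `feature_matrix` or matrix.
#' @param model a `cluster_model` with Gaussian parameters.
#' @export
negative_log_likelihood <- function(features, model) {
    x <- feature_values(features)
    logd <- gaussian_log_densities(x, model$means, model$covariances)
    logj <- sweep(logd, 2L, log(model$priors), "+")
    -sum(logsumexp_rows(logj))
}
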