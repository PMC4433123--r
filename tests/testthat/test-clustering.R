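test_that("k-means++ seeding follows the D^2 protocol", {
    set.seed(1)
    x <- matrix(rnorm(40), 20, 2)
    s1 <- kmeanspp_seed(x, 1, seed = 5)
    expect_true(any(apply(x, 1, function(r) all(r == s1[1, ]))))
    expect_identical(kmeanspp_seed(x, 1, seed = 5), s1)

    # C = N on distinct rows exhausts the data
    xd <- matrix(1:12, 6, 2)
    sall <- kmeanspp_seed(xd, 6, seed = 2)
    expect_equal(nrow(unique(sall)), 6L)

    # two far clouds: both nearly always get a seed (Monte-Carlo check of
    # the squared-distance seeding law)
    clouds <- rbind(matrix(rnorm(40), 20, 2),
                    matrix(rnorm(40, mean = 50), 20, 2))
    hits <- vapply(1:200, function(i) {
        s <- kmeanspp_seed(clouds, 2, seed = i)
        length(unique(s[, 1] > 25)) == 2L
    }, logical(1))
    expect_gte(mean(hits), 0.95)

    expect_error(kmeanspp_seed(x, 21), "C")
})

test_that("rank_seedings scores by mean nearest-seed squared distance", {
    x <- matrix(c(0, 1, 5, 6, 10), ncol = 1)
    sets <- list(matrix(c(0, 10), 2, 1), matrix(c(5, 5), 2, 1),
                 matrix(c(0.5, 7), 2, 1))
    # hand enumeration of the three scores
    score <- function(s) mean(apply(dist2_to_centers_oracle(x, s), 1, min))
    dist2_to_centers_oracle <- function(x, s)
        outer(seq_len(nrow(x)), seq_len(nrow(s)),
              Vectorize(function(i, j) sum((x[i, ] - s[j, ])^2)))
    scores <- sapply(sets, score)
    kept <- rank_seedings(x, sets, keep = 3)
    expect_identical(kept, sets[order(scores)])
    # good seeds beat a degenerate all-same-point set
    expect_identical(rank_seedings(x, sets[1:2], keep = 1)[[1]], sets[[1]])
    expect_error(rank_seedings(x, list(), keep = 1), "seed")
})

test_that("k-means solves the 1-D toy problem and matches brute force", {
    x <- matrix(c(0, 1, 10, 11), ncol = 1)
    fit <- fit_kmeans(x, matrix(c(1, 10), 2, 1))
    expect_equal(sort(fit$model$means[, 1]), c(0.5, 10.5))
    expect_equal(fit$model$objective, 1.0)

    # C = 1: centroid is the global mean
    f1 <- fit_kmeans(x, matrix(5, 1, 1))
    expect_equal(f1$model$means[1, 1], mean(x))

    # multistart objective is a Lloyd fixpoint bounded below by the
    # exhaustive-bipartition optimum and never worse than any kept candidate
    set.seed(7)
    for (rep in 1:5) {
        xs <- matrix(rnorm(8 * 2, sd = 3), 8, 2)
        ms <- run_multistart(xs, C = 2, algorithm = "kmeans",
                             n_inits = 100, keep = 10, seed = rep)
        expect_gte(ms$model$objective, brute_force_kmeans2(xs) - 1e-8)
        expect_equal(ms$model$objective, min(ms$selection))
    }
})

test_that("fuzzy k-means memberships follow the limit conventions", {
    # equidistant point, m = 2: memberships (0.5, 0.5)
    x <- matrix(c(0, 10, 5), ncol = 1)
    fit <- fit_fuzzy_kmeans(x, matrix(c(0, 10), 2, 1), m = 2, max_iter = 1)
    expect_equal(fit$labelling$memberships[3, ], c(0.5, 0.5))
    # point exactly at a centroid: membership 1 there
    expect_equal(fit$labelling$memberships[1, ], c(1, 0))
    # rows stochastic and assignment = argmax
    expect_equal(rowSums(fit$labelling$memberships), rep(1, 3))
    expect_equal(fit$labelling$assignment,
                 max.col(fit$labelling$memberships, ties.method = "first"))
    expect_error(fit_fuzzy_kmeans(x, matrix(c(0, 10), 2, 1), m = 1), "m must")
})

test_that("fuzzy k-means converges to the long-run fixed point", {
    x <- matrix(c(0, 1, 10, 11), ncol = 1)
    fit <- fit_fuzzy_kmeans(x, matrix(c(2, 9), 2, 1), m = 2,
                            max_iter = 200, tol = 1e-12)
    # independent fixed-point iteration run to 10^4 steps
    centers <- matrix(c(2, 9), 2, 1)
    for (i in 1:10000) {
        d2 <- (matrix(x, 4, 2) - matrix(centers, 4, 2, byrow = TRUE))^2
        u <- (1 / d2) / rowSums(1 / d2)
        centers <- matrix(colSums(u^2 * matrix(x, 4, 2)) / colSums(u^2), 2, 1)
    }
    expect_equal(sort(fit$model$means[, 1]), sort(centers[, 1]), tolerance = 1e-6)
})

test_that("fuzzy memberships approach uniform as m grows", {
    set.seed(33)
    x <- matrix(rnorm(60), 30, 2)
    # the membership update at huge m is near-uniform for any centroids not
    # sitting exactly on a data point (the coincident convention, and the
    # centre collapse it feeds at large m, are the documented exceptions)
    seeds <- matrix(rnorm(6, sd = 0.5), 3, 2) + 0.1
    fit <- fit_fuzzy_kmeans(x, seeds, m = 50, max_iter = 1)
    expect_lte(max(abs(fit$labelling$memberships - 1 / 3)), 0.05)
})

test_that("GMM with one component recovers mean and biased covariance in one step", {
    set.seed(8)
    x <- matrix(rnorm(400), 100, 4)
    fit <- fit_gmm(x, matrix(colMeans(x), 1, 4), max_iter = 1)
    expect_equal(fit$model$means[1, ], colMeans(x))
    xc <- sweep(x, 2, colMeans(x))
    expect_equal(matrix(fit$model$covariances[1, , ], 4, 4),
                 crossprod(xc) / nrow(x), tolerance = 1e-4)
})

test_that("GMM recovers the parameters of a separable mixture", {
    set.seed(21)
    mix <- random_mixture(n_per = 1000, centers = rbind(c(0, 0), c(10, 10)))
    seeds <- rbind(c(1, 1), c(9, 9))
    fit <- fit_gmm(mix$x, seeds, max_iter = 100)
    means <- fit$model$means[order(fit$model$means[, 1]), ]
    se <- 1 / sqrt(1000)
    expect_true(all(abs(means[1, ] - c(0, 0)) < 3 * se))
    expect_true(all(abs(means[2, ] - c(10, 10)) < 3 * se))
    expect_equal(fit$model$priors, c(0.5, 0.5), tolerance = 0.02)
})

test_that("GMM fit agrees with an independent mixture fitter", {
    suppressPackageStartupMessages(library(mclust))
    set.seed(77)
    mix <- random_mixture(n_per = 400, centers = rbind(c(0, 0), c(8, 8)))
    fit <- fit_gmm(mix$x, rbind(c(1, 1), c(7, 7)), max_iter = 300, tol = 1e-10)
    mc <- Mclust(mix$x, G = 2, modelNames = "VVV", verbose = FALSE)
    ours <- fit$model$means[order(fit$model$means[, 1]), ]
    theirs <- t(mc$parameters$mean)[order(mc$parameters$mean[1, ]), ]
    expect_equal(ours, theirs, tolerance = 1e-3, ignore_attr = TRUE)
    # same maximized log-likelihood up to convergence tolerance
    expect_equal(-fit$model$nll, mc$loglik, tolerance = 1e-5)
})

test_that("GMM NLL is non-increasing across EM iterations", {
    set.seed(9)
    for (rep in 1:50) {
        x <- matrix(rnorm(60 * 2), 60, 2) +
            matrix(sample(c(0, 4), 120, TRUE), 60, 2)
        seeds <- kmeanspp_seed(x, 3)
        nlls <- vapply(1:6, function(it)
            fit_gmm(x, seeds, max_iter = it, tol = 0)$model$nll, numeric(1))
        expect_true(all(diff(nlls) <= 1e-8 * abs(nlls[-length(nlls)])))
    }
})

test_that("negative_log_likelihood matches naive density evaluation", {
    # single standard normal, point at the mean: 0.5 log(2 pi)
    m <- gbmseg:::new_cluster_model("gmm", matrix(0, 1, 1),
                                    array(1, c(1, 1, 1)), 1, 0)
    expect_equal(negative_log_likelihood(matrix(0, 1, 1), m), 0.5 * log(2 * pi))

    set.seed(14)
    x <- matrix(rnorm(30), 10, 3)
    means <- matrix(rnorm(6), 2, 3)
    covs <- array(0, c(2, 3, 3))
    for (c in 1:2) { a <- matrix(rnorm(9), 3); covs[c, , ] <- crossprod(a) + diag(3) }
    mod <- gbmseg:::new_cluster_model("gmm", means, covs, c(0.3, 0.7), 0)
    naive <- -sum(log(sapply(seq_len(10), function(n) {
        sum(sapply(1:2, function(c) {
            S <- covs[c, , ]
            d <- x[n, ] - means[c, ]
            mod$priors[c] * exp(-0.5 * t(d) %*% solve(S) %*% d) /
                sqrt((2 * pi)^3 * det(S))
        }))
    })))
    expect_equal(negative_log_likelihood(x, mod), naive, tolerance = 1e-10)

    # duplicating the rows doubles the NLL
    expect_equal(negative_log_likelihood(rbind(x, x), mod),
                 2 * negative_log_likelihood(x, mod))
})

test_that("objectives are invariant to feature and label permutations", {
    set.seed(41)
    x <- matrix(rnorm(40 * 3), 40, 3)
    seeds <- kmeanspp_seed(x, 3, seed = 2)
    f1 <- fit_kmeans(x, seeds)
    f2 <- fit_kmeans(x[, c(3, 1, 2)], seeds[, c(3, 1, 2)])
    expect_equal(f1$model$objective, f2$model$objective)
    f3 <- fit_kmeans(x, seeds[c(2, 3, 1), ])
    expect_equal(f1$model$objective, f3$model$objective, tolerance = 1e-8)
    g1 <- fit_fuzzy_kmeans(x, seeds)
    g2 <- fit_fuzzy_kmeans(x[, c(2, 1, 3)], seeds[, c(2, 1, 3)])
    expect_equal(g1$model$objective, g2$model$objective, tolerance = 1e-8)
})

test_that("fits are reproducible given the same seed", {
    set.seed(50)
    x <- matrix(rnorm(200), 50, 4)
    for (alg in c("kmeans", "fuzzy", "gmm")) {
        a <- run_multistart(x, C = 3, algorithm = alg, n_inits = 20, keep = 3,
                            seed = 77)
        b <- run_multistart(x, C = 3, algorithm = alg, n_inits = 20, keep = 3,
                            seed = 77)
        expect_identical(a$labelling$assignment, b$labelling$assignment)
        expect_identical(a$model$means, b$model$means)
    }
})

test_that("multistart with n_inits = keep = 1 collapses to a single fit", {
    set.seed(60)
    x <- matrix(rnorm(60), 30, 2)
    ms <- run_multistart(x, C = 2, algorithm = "kmeans", n_inits = 1, keep = 1,
                         seed = 3)
    set.seed(3)
    s <- kmeanspp_seed(x, 2)
    single <- fit_kmeans(x, s)
    expect_identical(ms$labelling$assignment, single$labelling$assignment)
    expect_equal(ms$model$objective, single$model$objective)
})
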