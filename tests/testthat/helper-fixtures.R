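# Shared fixtures, generated in code.

# Small phantom reused across tests (32^3 keeps every stage fast).
mini_phantom <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- generate_phantom(phantom_spec(shape = c(32L, 32L, 32L),
                                                    noise_seed = 99L))
        cache
    }
})

# A tiny in-memory study with constant channels on a box mask.
toy_study <- function(shape = c(8L, 8L, 8L), t1 = 10, t1c = 12, t2 = 20,
                      flair = 30) {
    mask <- array(FALSE, shape)
    mask[3:6, 3:6, 3:6] <- TRUE
    mk <- function(v) array(v, shape)
    multichannel_study(list(T1 = mk(t1), T1c = mk(t1c), T2 = mk(t2),
                            Flair = mk(flair)), mask)
}

# Random well-separated Gaussian mixture in D dimensions.
random_mixture <- function(n_per = 50, centers = rbind(c(0, 0), c(10, 10)),
                           sd = 1) {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c)
        sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2L,
              centers[c, ], "+")))
    list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# Exhaustive best 2-class k-means objective over all bipartitions (N <= 12).
brute_force_kmeans2 <- function(x) {
    n <- nrow(x)
    best <- Inf
    for (code in 1:(2^n - 2)) {
        grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
        obj <- 0
        for (g in list(grp, !grp)) {
            xg <- x[g, , drop = FALSE]
            mu <- colMeans(xg)
            obj <- obj + sum(sweep(xg, 2L, mu)^2)
        }
        if (obj < best) best <- obj
    }
    best
}
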