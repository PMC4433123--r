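test_that("lesion mask follows the median + sd threshold rule", {
    # constant channels: sd = 0, nothing strictly exceeds the median
    st <- toy_study()
    expect_equal(sum(compute_lesion_mask(st, perimeter_radius = 0)), 0)

    # hand-computable 1-D arrangement on the Flair channel
    shape <- c(12L, 3L, 3L)
    mask <- array(TRUE, shape)
    flair <- array(5.5, shape)
    flair[1:10, 1, 1] <- 1:10
    mk <- function(v) array(v, shape)
    st2 <- multichannel_study(list(T1 = mk(1), T1c = mk(1), T2 = mk(1),
                                   Flair = flair), mask)
    thr <- median(flair) + sd(flair)
    got <- compute_lesion_mask(st2, perimeter_radius = 0)
    expect_equal(got, flair > thr)
})

test_that("lesion mask fills holes and strips the brain perimeter", {
    shape <- c(16L, 16L, 16L)
    mask <- array(TRUE, shape)
    mk <- function(v) array(v, shape)
    flair <- mk(10)
    flair[6:11, 6:11, 6:11] <- 100   # bright blob ...
    flair[8:9, 8:9, 8:9] <- 10       # ... with a dark hole inside
    st <- multichannel_study(list(T1 = mk(1), T1c = mk(1), T2 = mk(1),
                                  Flair = flair), mask)
    lesion <- compute_lesion_mask(st, perimeter_radius = 2)
    expect_true(all(lesion[8:9, 8:9, 8:9]))      # hole filled
    expect_true(all(!lesion[1:2, , ]))           # perimeter shell removed
})

test_that("tissue map correction substitutes epsilon only inside the lesion", {
    ph <- mini_phantom()
    lesion <- array(FALSE, ph$study$shape)
    expect_identical(correct_tissue_maps(ph$maps, lesion, 1e-6)$maps, ph$maps$maps)

    lesion[16, 16, 16] <- TRUE
    cor1 <- correct_tissue_maps(ph$maps, lesion, 1e-6)
    expect_equal(cor1$maps$WM[16, 16, 16], 1e-6)
    expect_equal(cor1$maps$GM[16, 16, 16], 1e-6)
    lesion_off <- which(!lesion)
    expect_identical(cor1$maps$CSF[lesion_off], ph$maps$maps$CSF[lesion_off])
    expect_true(cor1$corrected)

    full <- array(TRUE, ph$study$shape)
    corf <- correct_tissue_maps(ph$maps, full, 1e-6)
    expect_true(all(corf$maps$WM == 1e-6))
    expect_error(correct_tissue_maps(ph$maps, lesion, 1), "epsilon")
    expect_error(correct_tissue_maps(ph$maps, lesion, -0.1), "epsilon")
})

test_that("attribute_classes reproduces the hand cumulative-sum example", {
    # 4 classes engineered so p(c|WM) = (0.6, 0.3, 0.08, 0.02)
    n <- 100
    assignment <- rep(1:4, c(60, 30, 8, 2))
    index_map <- cbind(seq_len(n), 1L, 1L)
    wm <- array(0.6, c(n, 1, 1))
    # uniform GM/CSF mass: constraints exist and mirror the WM ordering
    gm <- array(0.2, c(n, 1, 1)); csf <- array(0.2, c(n, 1, 1))
    maps <- tissue_probability_maps(list(WM = wm, GM = gm, CSF = csf))
    att <- attribute_classes(assignment, index_map, maps, tau = 0.8)
    expect_equal(att$p_ct[, "WM"], c(`1` = 0.6, `2` = 0.3, `3` = 0.08, `4` = 0.02),
                 ignore_attr = TRUE)
    expect_equal(att$cumsums$WM, c(0.6, 0.9, 0.98, 1.0))
    # literal rule: cumulative sums 0.9, 0.98, 1.0 all exceed 0.8
    expect_equal(att$z_sets$WM, c(2L, 3L, 4L))
    # exclusive variant starts strictly after the crossing class
    att2 <- attribute_classes(assignment, index_map, maps,
                              tau = 0.8, rule = "exclusive")
    expect_equal(att2$z_sets$WM, c(3L, 4L))

    # a tissue with zero total mass contributes a vacuous constraint
    maps0 <- tissue_probability_maps(list(WM = wm, GM = gm * 0, CSF = csf))
    expect_warning(att0 <- attribute_classes(assignment, index_map, maps0),
                   "vacuous")
    expect_equal(att0$z_sets$GM, 1:4)
})

test_that("attribution table columns are normalized and Z shrinks with tau", {
    ph <- mini_phantom()
    fm <- flatten_to_features(list(ph$study$channels$T1), ph$study$brain_mask)
    assignment <- ph$tissues$labels[fm$index_map]
    lesion <- compute_lesion_mask(ph$study)
    cmaps <- correct_tissue_maps(ph$maps, lesion)
    att <- attribute_classes(assignment, fm, cmaps, tau = 0.8)
    expect_equal(colSums(att$p_ct), c(WM = 1, GM = 1, CSF = 1))
    expect_true(all(sapply(att$sorted_probs, function(p) all(diff(p) <= 1e-12))))
    expect_true(all(sapply(att$cumsums, function(s) abs(s[length(s)] - 1) < 1e-9)))
    # monotonicity in tau (for both rules)
    for (rule in c("inclusive", "exclusive")) {
        zs <- lapply(c(0.5, 0.7, 0.9), function(tau)
            attribute_classes(assignment, fm, cmaps, tau = tau, rule = rule)$z)
        expect_true(all(zs[[2]] %in% zs[[1]]))
        expect_true(all(zs[[3]] %in% zs[[2]]))
    }
})

test_that("ground-truth classes attribute correctly on the phantom", {
    ph <- mini_phantom()
    fm <- flatten_to_features(list(ph$study$channels$T1), ph$study$brain_mask)
    assignment <- ph$tissues$labels[fm$index_map]  # 1=CSF 2=GM 3=WM 4-7 tumour
    lesion <- compute_lesion_mask(ph$study)
    cmaps <- correct_tissue_maps(ph$maps, lesion)
    att <- attribute_classes(assignment, fm, cmaps, tau = 0.8, rule = "exclusive")
    expect_true(all(4:7 %in% att$z))
    expect_false(any(1:3 %in% att$z))
})

test_that("single-class segmentations are flagged as degenerate", {
    ph <- mini_phantom()
    fm <- flatten_to_features(list(ph$study$channels$T1), ph$study$brain_mask)
    ones <- rep(1L, nrow(fm$values))
    expect_warning(attribute_classes(ones, fm, ph$maps), "single class")
})

test_that("perimeter components are erased by the strict majority rule", {
    shape <- c(14L, 14L, 14L)
    brain <- array(TRUE, shape)
    lab <- array(0L, shape)
    lab[7:8, 7:8, 7:8] <- 1L           # interior component
    lab[1:2, 1:6, 1] <- 2L             # fully in the perimeter shell
    lv <- label_volume(lab)
    out <- remove_perimeter_classes(lv, brain, dilation_radius = 2, erosion_radius = 2)
    expect_true(all(out$labels[7:8, 7:8, 7:8] == 1L))
    expect_true(all(out$labels[lab == 2L] == 0L))

    # exactly 50% inside is kept (rule is strict >)
    shell <- brain & !binary_erode(brain, 2)
    perim <- binary_dilate(shell, 2)
    run <- which(!perim[, 7, 7])       # interior run along i at j=k=7
    lab3 <- array(0L, shape)
    inside_n <- 4L
    first_out <- run[1]
    lab3[(first_out - inside_n):(first_out + inside_n - 1L), 7, 7] <- 3L
    stopifnot(sum(lab3 == 3L & perim) == inside_n)  # 50/50 by construction
    out3 <- remove_perimeter_classes(label_volume(lab3), brain)
    expect_equal(sum(out3$labels == 3L), 2L * inside_n)
})

test_that("low-rate classes are removed in a single pass with strict <", {
    shape <- c(10L, 10L, 10L)
    lab <- array(0L, shape)
    lab[1:99] <- 1L; lab[100] <- 2L
    out <- remove_low_rate_classes(label_volume(lab), 0.01)
    expect_equal(sort(unique(as.vector(out$labels[out$labels > 0]))), c(1L, 2L))

    lab2 <- array(0L, shape)
    lab2[1:197] <- 1L; lab2[198:199] <- 2L; lab2[200] <- 3L
    # fractions 98.5% / 1% / 0.5%: only the 0.5% class goes
    out2 <- remove_low_rate_classes(label_volume(lab2), 0.01)
    expect_equal(sort(unique(as.vector(out2$labels[out2$labels > 0]))), c(1L, 2L))
    expect_equal(sum(out2$labels == 2L), 2L)

    lab3 <- array(0L, shape); lab3[5] <- 4L
    out3 <- remove_low_rate_classes(label_volume(lab3), 0.01)
    expect_equal(sum(out3$labels == 4L), 1L)
    expect_error(remove_low_rate_classes(label_volume(array(0L, shape))), "positive")
})

test_that("class densities are normalized and match the analytic normal curve", {
    set.seed(73)
    x <- matrix(rnorm(5000), ncol = 1)
    dens <- estimate_class_densities(x, rep(1L, 5000))
    g <- dens$grid[, 1]
    h <- g[2] - g[1]
    area <- h * (sum(dens$dens[[1]][, 1]) - (dens$dens[[1]][1, 1] +
                                                 dens$dens[[1]][256, 1]) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
    expect_lt(max(abs(dens$dens[[1]][, 1] - dnorm(g))), 0.05)

    # identical member sets give identical densities
    xx <- rbind(x, x)
    ass <- rep(c(1L, 2L), each = 5000)
    d2 <- estimate_class_densities(xx, ass)
    expect_equal(d2$dens[[1]], d2$dens[[2]])

    # degenerate class still integrates to 1
    xc <- matrix(c(rep(5, 10), rnorm(10)), ncol = 1)
    dc <- estimate_class_densities(xc, rep(c(1L, 2L), each = 10))
    a1 <- h1 <- dc$grid[2, 1] - dc$grid[1, 1]
    area1 <- h1 * (sum(dc$dens[[1]][, 1]) - (dc$dens[[1]][1, 1] +
                                                 dc$dens[[1]][256, 1]) / 2)
    expect_equal(area1, 1, tolerance = 1e-3)
    expect_error(estimate_class_densities(xc, c(1L, rep(2L, 19))), "fewer than 2")
})

test_that("Jensen-Shannon divergence has its analytic properties", {
    g <- seq(-5, 5, length.out = 128)
    p <- dnorm(g); q <- dnorm(g, mean = 1)
    expect_equal(js_divergence(p, p), 0)
    expect_equal(js_divergence(p, q), js_divergence(q, p))
    disj <- c(rep(1, 64), rep(0, 64)); disj2 <- rev(disj)
    expect_equal(js_divergence(disj, disj2), 1)
    set.seed(3)
    for (i in 1:10) {
        a <- runif(128); b <- runif(128)
        d <- js_divergence(a, b)
        expect_gte(d, 0); expect_lte(d, 1)
    }
    expect_error(js_divergence(p, q[-1]), "grids")
})

test_that("UPGMA merging honours threshold and class cap", {
    set.seed(91)
    # two identical-density classes merge into one
    x <- matrix(rnorm(400), ncol = 1)
    ass <- rep(c(1L, 2L), 200)
    dens <- estimate_class_densities(x, ass)
    map <- merge_similar_classes(dens, max_classes = 4, merge_threshold = 0.1)
    expect_equal(unname(map), c(1L, 1L))

    # six mutually distant classes forced down to exactly 4
    x6 <- matrix(rnorm(1200, mean = rep(seq(0, 100, 20), each = 200), sd = 0.5),
                 ncol = 1)
    a6 <- rep(1:6, each = 200)
    d6 <- estimate_class_densities(x6, a6)
    map6 <- merge_similar_classes(d6, max_classes = 4, merge_threshold = 0.1)
    expect_equal(max(map6), 4L)
    expect_length(unique(map6), 4L)

    # three distant classes above threshold stay distinct
    x3 <- matrix(rnorm(600, mean = rep(c(0, 50, 100), each = 200), sd = 0.5),
                 ncol = 1)
    d3 <- estimate_class_densities(x3, rep(1:3, each = 200))
    map3 <- merge_similar_classes(d3, max_classes = 4, merge_threshold = 0.1)
    expect_equal(unname(map3), 1:3)
    # merge map is a surjection onto 1..K
    expect_setequal(unique(map6), seq_len(max(map6)))
})

test_that("UPGMA merge order matches hclust average linkage", {
    set.seed(95)
    x <- matrix(rnorm(1500, mean = rep(c(0, 3, 6, 20, 40), each = 300), sd = 1),
                ncol = 1)
    ass <- rep(1:5, each = 300)
    dens <- estimate_class_densities(x, ass)
    dm <- gbmseg:::js_distance_matrix(dens)
    for (k in c(2, 3, 4)) {
        map <- merge_similar_classes(dens, max_classes = k, merge_threshold = 0)
        hc <- cutree(hclust(as.dist(dm), method = "average"), k = k)
        # same partition up to group relabelling
        expect_equal(length(unique(map)), length(unique(hc)))
        expect_true(all(table(map, hc) %in% c(0, table(map))))
    }
})

test_that("BRATS code assignment follows the contrast priority order", {
    ph <- mini_phantom()
    # ground-truth tumour tissues as merged classes 1..4
    lab <- array(0L, ph$study$shape)
    lab[ph$tissues$labels == 4L] <- 1L  # necrosis
    lab[ph$tissues$labels == 5L] <- 2L  # enhancing
    lab[ph$tissues$labels == 6L] <- 3L  # non-enhancing
    lab[ph$tissues$labels == 7L] <- 4L  # edema
    out <- assign_brats_labels(label_volume(lab), ph$study)
    map <- attr(out, "mapping")
    expect_equal(map[["2"]], 4L)  # enhancing class -> code 4
    expect_equal(map[["4"]], 2L)  # edema class -> code 2
    expect_equal(map[["1"]], 1L)  # necrosis class -> code 1
    expect_equal(map[["3"]], 3L)  # remaining -> code 3
    # label volume agrees with the phantom truth
    expect_equal(out$labels, ph$truth$labels)

    # single class, brightest in T1d -> code 4
    lab1 <- array(0L, ph$study$shape)
    lab1[ph$tissues$labels == 5L] <- 1L
    out1 <- assign_brats_labels(label_volume(lab1), ph$study)
    expect_equal(unname(attr(out1, "mapping")), 4L)
    expect_error(assign_brats_labels(label_volume(array(0L, ph$study$shape)),
                                     ph$study), "no classes")
})
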