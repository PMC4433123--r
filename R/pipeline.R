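# Full segmentation pipeline: features -> PCA -> multistart clustering ->
# tumour class isolation -> BRATS coding, with optional evaluation against
# a reference labelling and file outputs.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package defaults; any
#' entry can be overridden via `...`. Inputs are given either as in-memory
#' objects (`study`, `maps`, `reference`) or as NIfTI paths (`t1`, `t1c`,
#' `t2`, `flair`, `mask`, `wm`, `gm`, `csf`, `reference`).
#'
#' @param ... configuration overrides.
#' @export
pipeline_config <- function(...) {
    cfg <- list(algorithm = "gmm",
                n_classes = 14L,      # 7 assumed tissues x 2 Gaussians
                n_inits = 100L, keep = 10L,
                beta = 1.0, tau = 0.8, epsilon = 1e-6,
                max_classes = 4L, merge_threshold = 0.1,
                min_fraction = 0.01, zt_rule = "exclusive",
                radius = 2L, var_threshold = 0.99,
                m = 2, max_iter = 200L, icm_sweeps = 5L, tol = 1e-6,
                perimeter_erosion = 2L, perimeter_dilation = 2L,
                seed = 1L, out_dir = NULL,
                study = NULL, maps = NULL, reference = NULL,
                t1 = NULL, t1c = NULL, t2 = NULL, flair = NULL, mask = NULL,
                wm = NULL, gm = NULL, csf = NULL)
    over <- list(...)
    if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
        over <- over[[1]]
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
        stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    class(cfg) <- "gbmseg_config"
    cfg
}

load_pipeline_inputs <- function(cfg) {
    if (is.null(cfg$study)) {
        paths <- list(T1 = cfg$t1, T1c = cfg$t1c, T2 = cfg$t2, Flair = cfg$flair)
        if (any(vapply(paths, is.null, logical(1))) || is.null(cfg$mask))
            stopf("provide either a `study` object or all of t1/t1c/t2/flair/mask")
        cfg$study <- assemble_study(paths, cfg$mask)
    }
    if (is.null(cfg$maps)) {
        if (is.null(cfg$wm) || is.null(cfg$gm) || is.null(cfg$csf))
            stopf("provide either a `maps` object or all of wm/gm/csf")
        cfg$maps <- tissue_probability_maps(list(WM = read_volume(cfg$wm)$data,
                                                 GM = read_volume(cfg$gm)$data,
                                                 CSF = read_volume(cfg$csf)$data))
    }
    if (is.character(cfg$reference))
        cfg$reference <- label_volume(read_volume(cfg$reference)$data)
    if (is.array(cfg$reference)) cfg$reference <- label_volume(cfg$reference)
    cfg
}

with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full unsupervised segmentation pipeline
#'
#' Stages: feature stack, PCA reduction, multistart clustering, lesion-mask
#' correction of the tissue maps, tissue attribution, normal-class removal,
#' perimeter and low-rate outlier removal, density-based class merging, and
#' BRATS code assignment. Deterministic given `seed`.
#'
#' @param config a list from [pipeline_config()], a plain list of
#'   overrides, or a path to a YAML file of overrides.
#' @return list with `labels` (final BRATS `label_volume`), `report`
#'   (a [compartment_report()] when a reference is given), `attribution`,
#'   `model`, `pca_model`, `merge_map`, `brats_mapping` and `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!inherits(config, "gbmseg_config")) config <- pipeline_config(config)
    cfg <- load_pipeline_inputs(config)
    study <- cfg$study
    log <- character(0)
    note <- function(...) log <<- c(log, sprintf(...))
    note("algorithm=%s n_classes=%d n_inits=%d keep=%d seed=%d",
         cfg$algorithm, cfg$n_classes, cfg$n_inits, cfg$keep, cfg$seed)
    note("beta=%g tau=%g epsilon=%g max_classes=%d merge_threshold=%g min_fraction=%g",
         cfg$beta, cfg$tau, cfg$epsilon, cfg$max_classes, cfg$merge_threshold,
         cfg$min_fraction)
    note("radius=%d var_threshold=%g zt_rule=%s", cfg$radius, cfg$var_threshold,
         cfg$zt_rule)

    stack <- with_stage("features", build_feature_stack(study, radius = cfg$radius))
    red <- with_stage("pca",
                      reduce_dimensionality(stack, var_threshold = cfg$var_threshold))
    note("PCA retained K=%d components (cumulative %.4f)", red$model$K,
         sum(red$model$explained_fractions[seq_len(red$model$K)]))

    mrf <- NULL
    if (cfg$algorithm == "ghmrf")
        mrf <- make_mrf_spec(study$brain_mask, beta = cfg$beta)
    extra <- switch(cfg$algorithm,
                    fuzzy = list(m = cfg$m, max_iter = cfg$max_iter, tol = cfg$tol),
                    ghmrf = list(max_iter = cfg$max_iter, icm_sweeps = cfg$icm_sweeps,
                                 tol = cfg$tol),
                    list(max_iter = cfg$max_iter, tol = cfg$tol))
    fit <- with_stage("clustering",
                      do.call(run_multistart,
                              c(list(red$features, C = cfg$n_classes,
                                     algorithm = cfg$algorithm,
                                     n_inits = cfg$n_inits, keep = cfg$keep,
                                     seed = cfg$seed, mrf = mrf), extra)))
    note("multistart: candidate %d selected (criterion %.6g)", fit$best,
         fit$selection[fit$best])

    lesion <- with_stage("lesion_mask", compute_lesion_mask(study))
    note("lesion mask: %d voxels", sum(lesion))
    cmaps <- with_stage("map_correction",
                        correct_tissue_maps(cfg$maps, lesion, cfg$epsilon))
    att <- with_stage("attribution",
                      attribute_classes(fit$labelling, red$features, cmaps,
                                        tau = cfg$tau, rule = cfg$zt_rule))
    note("pathological classes Z: {%s}", paste(att$z, collapse = ", "))
    if (length(att$z) == 0)
        stopf("pipeline stage 'attribution' failed: no pathological classes survive tau = %g",
              cfg$tau)

    assignment <- fit$labelling$assignment
    tumour_assign <- ifelse(assignment %in% att$z, assignment, 0L)
    lv <- with_stage("isolation", {
        lv <- scatter_labels(tumour_assign, red$features)
        lv <- remove_perimeter_classes(lv, study$brain_mask,
                                       dilation_radius = cfg$perimeter_dilation,
                                       erosion_radius = cfg$perimeter_erosion)
        remove_low_rate_classes(lv, cfg$min_fraction)
    })
    surv_assign <- lv$labels[red$features$index_map]
    survivors <- sort(unique(surv_assign[surv_assign > 0L]))
    note("surviving classes after outlier removal: {%s}",
         paste(survivors, collapse = ", "))
    if (length(survivors) == 0)
        stopf("pipeline stage 'isolation' failed: no classes survive outlier removal")

    merge_map <- with_stage("merge", {
        dens <- estimate_class_densities(red$features, surv_assign,
                                         classes = survivors)
        merge_similar_classes(dens, max_classes = cfg$max_classes,
                              merge_threshold = cfg$merge_threshold)
    })
    note("merge: %d classes -> %d groups", length(survivors), max(merge_map))
    merged_assign <- surv_assign
    pos <- surv_assign > 0L
    merged_assign[pos] <- merge_map[as.character(surv_assign[pos])]
    merged_lv <- scatter_labels(merged_assign, red$features)

    final <- with_stage("brats_mapping", assign_brats_labels(merged_lv, study))
    note("BRATS mapping: %s",
         paste(sprintf("%s->%d", names(attr(final, "mapping")),
                       attr(final, "mapping")), collapse = " "))

    report <- NULL
    if (!is.null(cfg$reference))
        report <- with_stage("evaluation",
                             compartment_report(final, cfg$reference))

    result <- list(labels = final, report = report, attribution = att,
                   model = fit$model, pca_model = red$model,
                   merge_map = merge_map, brats_mapping = attr(final, "mapping"),
                   log = log)
    if (!is.null(cfg$out_dir))
        with_stage("outputs", write_pipeline_outputs(result, study, cfg))
    result
}

write_pipeline_outputs <- function(result, study, cfg) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(result$labels$labels, study$affine,
                 file.path(cfg$out_dir, "segmentation.nii.gz"))
    att <- result$attribution
    utils::write.csv(data.frame(class = rownames(att$p_ct), att$p_ct,
                                in_z = rownames(att$p_ct) %in% as.character(att$z)),
                     file.path(cfg$out_dir, "attribution.csv"), row.names = FALSE)
    model <- result$model
    sidecar <- list(model_kind = model$model_kind, C = model$C, D = model$D,
                    means = model$means, priors = model$priors,
                    covariances = lapply(seq_len(model$C),
                                         function(c) model$covariances[c, , ]),
                    objective = model$objective, nll = model$nll,
                    n_iter = model$n_iter)
    jsonlite::write_json(sidecar, file.path(cfg$out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- c(cfg[c("algorithm", "n_classes", "n_inits", "keep", "beta", "tau",
                        "epsilon", "max_classes", "merge_threshold", "min_fraction",
                        "zt_rule", "radius", "var_threshold", "seed")],
                  list(log = result$log))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(result$report))
        utils::write.csv(result$report$metrics,
                         file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
    invisible(cfg$out_dir)
}
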