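# Segmentation quality metrics over the BRATS evaluation compartments.

BRATS_COMPARTMENTS <- list(complete = c(1L, 2L, 3L, 4L),
                           core = c(1L, 3L, 4L),
                           enhancing = 4L)

#' Binarize a BRATS label volume into an evaluation compartment
#'
#' complete = labels {1,2,3,4}; core = {1,3,4}; enhancing = {4}.
#'
#' @param labels a `label_volume` (or integer array) with BRATS codes.
#' @param compartment "complete", "core" or "enhancing".
#' @return logical 3-D array.
#' @export
binarize_compartment <- function(labels, compartment) {
    if (inherits(labels, "label_volume")) labels <- labels$labels
    if (!compartment %in% names(BRATS_COMPARTMENTS))
        stopf("unknown compartment '%s'", compartment)
    array(labels %in% BRATS_COMPARTMENTS[[compartment]], dim(labels))
}

#' Confusion counts between two binary volumes
#'
#' @param predicted,reference logical 3-D arrays.
#' @param eval_mask optional logical array restricting the evaluated
#'   voxels (default: whole volume).
#' @return object of class `evaluation_counts`: TP, TN, FP, FN and the
#'   derived totals P, N, P_hat, N_hat.
#' @export
confusion_counts <- function(predicted, reference, eval_mask = NULL) {
    check_same_shape(predicted, reference, "predicted and reference")
    p <- as.logical(predicted)
    r <- as.logical(reference)
    if (!is.null(eval_mask)) {
        check_same_shape(predicted, eval_mask, "predicted and eval mask")
        keep <- as.logical(eval_mask)
        p <- p[keep]; r <- r[keep]
    }
    tp <- sum(p & r); tn <- sum(!p & !r); fp <- sum(p & !r); fn <- sum(!p & r)
    evaluation_counts(tp, tn, fp, fn)
}

#' Construct evaluation counts directly
#'
#' @param TP,TN,FP,FN non-negative integers.
#' @export
evaluation_counts <- function(TP, TN, FP, FN) {
    if (any(c(TP, TN, FP, FN) < 0)) stopf("counts must be non-negative")
    structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                   P = TP + FN, N = TN + FP, P_hat = TP + FP, N_hat = TN + FN),
              class = "evaluation_counts")
}

#' Dice overlap coefficient
#'
#' Default is the standard overlap Dice 2TP / (P + P_hat) (the BRATS
#' challenge metric). `variant = "printed"` computes
#' 2(TP+TN) / (P + N + P_hat + N_hat) for audit of the alternative
#' accuracy-style formula. Both empty sets give 1.
#'
#' @param counts an `evaluation_counts`.
#' @param variant "overlap" (default) or "printed".
#' @export
dice <- function(counts, variant = c("overlap", "printed")) {
    variant <- match.arg(variant)
    if (variant == "printed")
        return(2 * (counts$TP + counts$TN) /
                   (counts$P + counts$N + counts$P_hat + counts$N_hat))
    if (counts$P + counts$P_hat == 0) return(1)
    2 * counts$TP / (counts$P + counts$P_hat)
}

#' Positive predictive value TP / (TP + FP)
#'
#' Defined as 1 when nothing is predicted positive and nothing is positive
#' in the reference; 0 when positives exist but none are predicted.
#' @param counts an `evaluation_counts`.
#' @export
ppv <- function(counts) {
    if (counts$P_hat == 0) return(if (counts$P == 0) 1 else 0)
    counts$TP / counts$P_hat
}

#' Sensitivity TP / (TP + FN)
#'
#' Defined as 1 when the reference has no positives and none are predicted.
#' @param counts an `evaluation_counts`.
#' @export
sensitivity <- function(counts) {
    if (counts$P == 0) return(if (counts$P_hat == 0) 1 else 0)
    counts$TP / counts$P
}

#' Cohen's kappa
#'
#' (P_A - P_E) / (1 - P_E) with accuracy P_A = (TP+TN)/(P+N) and chance
#' agreement P_E = (P/(P+N)) (P_hat/(P_hat+N_hat)) +
#' (N/(P+N)) (N_hat/(P_hat+N_hat)). The degenerate case P_E = 1 returns 0.
#'
#' @param counts an `evaluation_counts`.
#' @export
kappa <- function(counts) {
    tot <- counts$P + counts$N
    pa <- (counts$TP + counts$TN) / tot
    pe <- (counts$P / tot) * (counts$P_hat / tot) +
        (counts$N / tot) * (counts$N_hat / tot)
    if (pe >= 1) return(0)
    (pa - pe) / (1 - pe)
}

#' Per-compartment evaluation report
#'
#' Dice, PPV and sensitivity for the complete, core and enhancing
#' compartments, plus the (binary, complete-tumour) Cohen's kappa.
#'
#' @param predicted,reference `label_volume`s with BRATS codes.
#' @param eval_mask optional evaluation mask (default: whole volume).
#' @return object of class `compartment_report`: a data frame `metrics`
#'   (rows = compartments) and scalar `kappa`.
#' @export
compartment_report <- function(predicted, reference, eval_mask = NULL) {
    rows <- lapply(names(BRATS_COMPARTMENTS), function(comp) {
        cc <- confusion_counts(binarize_compartment(predicted, comp),
                               binarize_compartment(reference, comp), eval_mask)
        data.frame(compartment = comp, dice = dice(cc), ppv = ppv(cc),
                   sensitivity = sensitivity(cc))
    })
    complete_counts <- confusion_counts(binarize_compartment(predicted, "complete"),
                                        binarize_compartment(reference, "complete"),
                                        eval_mask)
    structure(list(metrics = do.call(rbind, rows), kappa = kappa(complete_counts)),
              class = "compartment_report")
}

#' @export
print.compartment_report <- function(x, ...) {
    print(x$metrics, row.names = FALSE)
    cat(sprintf("complete-tumour kappa: %.4f\n", x$kappa))
    invisible(x)
}
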