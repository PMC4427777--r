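## Overlap metrics between a reference (manually delineated, Vm) and a
## segmented (Va) voxel set: Dice = 2|Vm n Va| / (|Vm| + |Va|),
## precision = |Vm n Va| / |Va|, recall = |Vm n Va| / |Vm|; plus the paired
## t-test used to compare per-case metric sequences across methods.

.overlapCounts <- function(ref, seg) {
    stopifnot(is(ref, "BinaryMask"), is(seg, "BinaryMask"))
    .stopGeom(ref, seg, "reference and segmentation")
    c(nRef = as.numeric(sum(ref@data)), nSeg = as.numeric(sum(seg@data)),
      nIntersect = as.numeric(sum(ref@data & seg@data)))
}

#' Dice similarity index
#'
#' `2|Vm n Va| / (|Vm| + |Va|)`: 0 for disjoint sets, 1 for identical sets;
#' symmetric in its arguments. Undefined (an error) when both masks are
#' empty.
#'
#' @param ref,seg [BinaryMask-class]s on matching geometry.
#' @return Scalar in \[0, 1\].
#' @export
diceCoefficient <- function(ref, seg) {
    n <- .overlapCounts(ref, seg)
    if (n["nRef"] + n["nSeg"] == 0)
        stop("Dice is undefined for two empty masks", call. = FALSE)
    unname(2 * n["nIntersect"] / (n["nRef"] + n["nSeg"]))
}

#' Precision (positive predictive value)
#'
#' True positives over everything labelled positive: `|Vm n Va| / |Va|`.
#'
#' @inheritParams diceCoefficient
#' @return Scalar in \[0, 1\].
#' @export
precisionScore <- function(ref, seg) {
    n <- .overlapCounts(ref, seg)
    if (n["nSeg"] == 0)
        stop("precision is undefined for an empty segmentation", call. = FALSE)
    unname(n["nIntersect"] / n["nSeg"])
}

#' Recall (sensitivity)
#'
#' True positives over everything actually positive: `|Vm n Va| / |Vm|`.
#'
#' @inheritParams diceCoefficient
#' @return Scalar in \[0, 1\].
#' @export
recallScore <- function(ref, seg) {
    n <- .overlapCounts(ref, seg)
    if (n["nRef"] == 0)
        stop("recall is undefined for an empty reference", call. = FALSE)
    unname(n["nIntersect"] / n["nRef"])
}

#' Full overlap evaluation
#'
#' Single pass producing the three voxel counts and Dice, precision and
#' recall. Note the algebraic identity Dice = 2PR/(P+R) (harmonic mean of
#' precision and recall) holds exactly.
#'
#' @inheritParams diceCoefficient
#' @return An [EvalReport-class].
#' @export
evaluateOverlap <- function(ref, seg) {
    n <- .overlapCounts(ref, seg)
    if (n["nRef"] == 0 || n["nSeg"] == 0)
        stop("evaluation requires nonempty reference and segmentation",
             call. = FALSE)
    new("EvalReport", nRef = unname(n["nRef"]), nSeg = unname(n["nSeg"]),
        nIntersect = unname(n["nIntersect"]),
        dice = unname(2 * n["nIntersect"] / (n["nRef"] + n["nSeg"])),
        precision = unname(n["nIntersect"] / n["nSeg"]),
        recall = unname(n["nIntersect"] / n["nRef"]))
}

#' Convert an EvalReport to a one-row data.frame
#'
#' @param report an [EvalReport-class].
#' @return data.frame with columns n_ref, n_seg, n_intersect, dice,
#'   precision, recall.
#' @export
reportAsData <- function(report) {
    stopifnot(is(report, "EvalReport"))
    data.frame(n_ref = report@nRef, n_seg = report@nSeg,
               n_intersect = report@nIntersect, dice = report@dice,
               precision = report@precision, recall = report@recall)
}

#' Two-sided paired t-test on per-case metrics
#'
#' Thin wrapper around [stats::t.test()] with `paired = TRUE`: t =
#' mean(d) / (sd(d)/sqrt(n)) on differences d = a - b, with n - 1 degrees of
#' freedom. Significance is never auto-thresholded; the caller interprets
#' the p value.
#'
#' @param a,b equal-length numeric vectors (n >= 2) of per-case scores.
#' @return A [PairedTestResult-class].
#' @export
pairedTTest <- function(a, b) {
    if (length(a) != length(b) || length(a) < 2L)
        stop("need equal-length sequences with at least 2 pairs", call. = FALSE)
    d <- a - b
    if (sd(d) == 0 || !is.finite(sd(d)))
        stop("degenerate test: differences have zero variance", call. = FALSE)
    tt <- t.test(a, b, paired = TRUE, alternative = "two.sided")
    new("PairedTestResult", meanDiff = unname(tt$estimate),
        statistic = unname(tt$statistic), pValue = tt$p.value,
        n = length(a))
}

setMethod("show", "EvalReport", function(object) {
    cat(sprintf(
        "EvalReport: |Vm|=%d |Va|=%d |Vm n Va|=%d\n  dice %.4f  precision %.4f  recall %.4f\n",
        object@nRef, object@nSeg, object@nIntersect, object@dice,
        object@precision, object@recall))
})

setMethod("show", "PairedTestResult", function(object) {
    cat(sprintf("Paired t-test: mean diff %.4g, t = %.4g, p = %.4g (n = %d)\n",
                object@meanDiff, object@statistic, object@pValue, object@n))
})
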