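#' @describeIn CoexExperiment the sample-to-group factor (levels ordered
#'   group A, group B).
#' @export
setMethod("sampleGroups", "CoexExperiment", function(x) colData(x)$group)

#' @describeIn CoexExperiment the two group labels, group A first.
#' @export
setMethod("groupNames", "CoexExperiment", function(x)
    levels(colData(x)$group))

#' @describeIn CoexExperiment named integer vector of group sizes (K, L).
#' @export
setMethod("groupSizes", "CoexExperiment", function(x) {
    tab <- table(colData(x)$group)
    stats::setNames(as.integer(tab), names(tab))
})

#' @describeIn CoexExperiment swap the roles of group A and group B; every
#'   z statistic computed on the swapped object is the exact negative of the
#'   original.
#' @export
setMethod("swapGroups", "CoexExperiment", function(x) {
    grp <- colData(x)$group
    colData(x)$group <- factor(grp, levels = rev(levels(grp)))
    x
})

setMethod("show", "CoexExperiment", function(object) {
    sizes <- groupSizes(object)
    cat(sprintf("CoexExperiment: %d molecules x %d samples\n",
                nrow(object), ncol(object)))
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s (n=%d)", names(sizes), sizes),
                      collapse = " vs ")))
})

#' @describeIn InteractionNetwork-class source identifiers in network order.
#' @export
setMethod("networkSources", "InteractionNetwork", function(x) x@source)

#' @describeIn InteractionNetwork-class target identifiers in network order.
#' @export
setMethod("networkTargets", "InteractionNetwork", function(x) x@target)

#' @describeIn InteractionNetwork-class the pairs as a two-column data.frame.
#' @export
setMethod("networkPairs", "InteractionNetwork", function(x)
    data.frame(source = x@source, target = x@target))

#' @describeIn InteractionNetwork-class number of pairs.
#' @param x an `InteractionNetwork`.
#' @export
setMethod("length", "InteractionNetwork", function(x) length(x@source))

setMethod("show", "InteractionNetwork", function(object) {
    n <- length(object)
    cat(sprintf("InteractionNetwork: %d directed pair%s, %d source molecule%s\n",
                n, if (n == 1L) "" else "s",
                length(unique(object@source)),
                if (length(unique(object@source)) == 1L) "" else "s"))
    if (n) {
        k <- min(3L, n)
        cat(paste(sprintf("  %s -> %s", object@source[seq_len(k)],
                          object@target[seq_len(k)]), collapse = "\n"), "\n")
        if (n > k) cat(sprintf("  ... and %d more\n", n - k))
    }
})

setMethod("show", "PermutationPlan", function(object) {
    cat(sprintf(
        "PermutationPlan: B = %d relabelings, seed = %d, alpha = %g, R = %d hypotheses\n",
        object@nPermutations, object@seed, object@alpha, object@nHypotheses))
})

setMethod("show", "PairTestResults", function(object) {
    md <- metadata(object)
    cat(sprintf(
        "PairTestResults: %d pairs | %s correlation, %s %s p-values | %s (K=%d) vs %s (L=%d)\n",
        nrow(object), md$correlationKind, md$sidedness, md$pvalueKind,
        md$groupA, md$K, md$groupB, md$L))
    callNextMethod()
})

setMethod("show", "SourceAggregates", function(object) {
    md <- metadata(object)
    cat(sprintf(
        "SourceAggregates: %d rows | N = %d interactions, S = %d significant at alpha = %g\n",
        nrow(object), md$N, md$S, md$alpha))
    callNextMethod()
})
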