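#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<-
NULL

#' CoexExperiment: expression data with a two-group sample design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' molecules-by-samples expression matrix (assumed already normalised and
#' log-scaled) together with a factor assigning every sample to exactly one of
#' two condition labels.  The first factor level plays the role of group A
#' ("Normal" in the typical tumour/normal contrast) and the second the role of
#' group B; all differential co-expression statistics in the package are signed
#' as group A minus group B.
#'
#' Validity requires finite values, unique molecule and sample identifiers,
#' exactly two group levels, and at least four samples per group -- the Fisher
#' z asymptotic variances contain a factor 1/(M - 3), so groups of size three
#' or fewer are rejected outright rather than producing NaN statistics.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`; the grouping lives
#'   in `colData(x)$group`.
#'
#' @seealso [CoexExperiment()] for construction, [sampleGroups()],
#'   [groupNames()], [groupSizes()], [swapGroups()].
#' @export
setClass("CoexExperiment", contains = "SummarizedExperiment")

setValidity("CoexExperiment", function(object) {
    msg <- character(0)
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        m <- assay(object, "exprs")
        if (!is.numeric(m))
            msg <- c(msg, "assay 'exprs' must be numeric")
        else if (any(!is.finite(m)))
            msg <- c(msg, "assay 'exprs' contains missing or non-finite values")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "molecule identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    grp <- colData(object)$group
    if (is.null(grp)) {
        msg <- c(msg, "colData(object)$group is required")
    } else {
        if (!is.factor(grp) || nlevels(grp) != 2L)
            msg <- c(msg, "group must be a factor with exactly two levels")
        else {
            sizes <- table(grp)
            if (any(sizes <= 3L))
                msg <- c(msg, sprintf(
                    "each group needs more than 3 samples (got %s); the z-test variance 1/(M-3) is undefined otherwise",
                    paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
        }
        if (anyNA(grp))
            msg <- c(msg, "every sample must be assigned to a group (no NA)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CoexExperiment
#'
#' @param exprs numeric matrix, molecules in rows (unique rownames) and samples
#'   in columns (unique colnames).  Values are taken as-is; they are expected
#'   to be normalised/log-scaled upstream.
#' @param groups the sample-to-group assignment: either a factor/character
#'   vector of length `ncol(exprs)` (optionally named by sample), or a named
#'   vector covering all samples.
#' @param groupA,groupB optional group labels fixing which level is group A
#'   (reference, e.g. "Normal") and which is group B.  Defaults to the order of
#'   first appearance in `groups`.
#'
#' @return a [CoexExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' ce <- CoexExperiment(m, rep(c("Normal", "Tumor"), each = 5))
#' groupSizes(ce)
#' @export
CoexExperiment <- function(exprs, groups, groupA = NULL, groupB = NULL) {
    if (!is.matrix(exprs))
        exprs <- as.matrix(exprs)
    if (!is.null(names(groups)) && !is.null(colnames(exprs))) {
        missing <- setdiff(colnames(exprs), names(groups))
        if (length(missing))
            stop("samples without a group assignment: ",
                 paste(missing, collapse = ", "))
        groups <- groups[colnames(exprs)]
    }
    if (length(groups) != ncol(exprs))
        stop("'groups' must assign every sample of the matrix")
    groups <- as.character(groups)
    lev <- unique(groups)
    if (length(lev) != 2L)
        stop("exactly two distinct group labels are required, got: ",
             paste(lev, collapse = ", "))
    if (!is.null(groupA)) {
        if (!groupA %in% lev)
            stop("groupA label '", groupA, "' not present in 'groups'")
        lev <- c(groupA, setdiff(lev, groupA))
    }
    if (!is.null(groupB)) {
        if (!groupB %in% lev || identical(groupB, lev[1L]))
            stop("groupB label '", groupB, "' invalid")
        lev <- c(lev[1L], groupB)
    }
    se <- SummarizedExperiment(
        assays = list(exprs = exprs),
        colData = S4Vectors::DataFrame(
            group = factor(groups, levels = lev),
            row.names = colnames(exprs)))
    new("CoexExperiment", se)
}

#' InteractionNetwork: directed (source, target) pairs to be tested
#'
#' An ordered list of directed molecule pairs; the source is the regulator
#' role (e.g. an isomiR) and the target the regulated molecule (e.g. an mRNA).
#' Self-pairs and duplicated (source, target) pairs are invalid.  When no
#' predefined network is available, [exhaustiveNetwork()] enumerates all
#' unordered molecule pairs.
#'
#' @slot source character vector of source identifiers.
#' @slot target character vector of target identifiers, same length.
#' @export
setClass("InteractionNetwork",
         slots = c(source = "character", target = "character"))

setValidity("InteractionNetwork", function(object) {
    msg <- character(0)
    if (length(object@source) != length(object@target))
        msg <- c(msg, "source and target must have equal length")
    else {
        if (any(object@source == object@target))
            msg <- c(msg, "self-pairs (source == target) are not allowed")
        key <- paste(object@source, object@target, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (source, target) pairs are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname InteractionNetwork-class
#' @param source,target character vectors of molecule identifiers, or a
#'   two-column data.frame passed as `source` with `target` missing.
#' @return an `InteractionNetwork`.
#' @examples
#' net <- InteractionNetwork(c("miR1", "miR1"), c("geneA", "geneB"))
#' length(net)
#' @export
InteractionNetwork <- function(source, target) {
    if (missing(target)) {
        df <- as.data.frame(source)
        if (ncol(df) < 2L)
            stop("a two-column (source, target) table is required")
        target <- as.character(df[[2L]])
        source <- as.character(df[[1L]])
    }
    new("InteractionNetwork", source = as.character(source),
        target = as.character(target))
}

#' All unordered molecule pairs as a network (exhaustive mode)
#'
#' @param ids character vector of molecule identifiers (or a
#'   [CoexExperiment-class], in which case its rownames are used).
#' @return an [InteractionNetwork-class] with `choose(n, 2)` pairs, each
#'   unordered pair appearing once with the earlier identifier as source.
#' @examples
#' length(exhaustiveNetwork(letters[1:5]))  # 10
#' @export
exhaustiveNetwork <- function(ids) {
    if (is(ids, "CoexExperiment"))
        ids <- rownames(ids)
    ids <- as.character(ids)
    if (length(ids) < 2L)
        stop("need at least two molecules for exhaustive pairing")
    idx <- utils::combn(length(ids), 2L)
    InteractionNetwork(ids[idx[1L, ]], ids[idx[2L, ]])
}

#' PermutationPlan: how label permutations are drawn
#'
#' Bundles the number of relabelings B, the RNG seed, the significance level
#' alpha and the number of simultaneously tested hypotheses R.  When B is left
#' unspecified it defaults to [minPermutations()] = ceiling(R / alpha), the
#' smallest number of permutations able to resolve a BH-adjusted p-value at
#' level alpha across R hypotheses.
#'
#' @slot nPermutations integer, B >= 1.
#' @slot seed integer seed driving the single permutation stream.
#' @slot alpha numeric in (0, 1).
#' @slot nHypotheses integer, R >= 1.
#' @export
setClass("PermutationPlan",
         slots = c(nPermutations = "integer", seed = "integer",
                   alpha = "numeric", nHypotheses = "integer"))

setValidity("PermutationPlan", function(object) {
    msg <- character(0)
    if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
        object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be a single number in (0, 1)")
    if (object@nHypotheses < 1L)
        msg <- c(msg, "nHypotheses must be >= 1")
    if (object@nPermutations < 1L)
        msg <- c(msg, "nPermutations must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname PermutationPlan-class
#' @param nHypotheses number of simultaneously tested hypotheses R.
#' @param alpha significance level used for the default permutation count.
#' @param nPermutations number of relabelings B, or `NULL`/`"auto"` for the
#'   default `ceiling(nHypotheses / alpha)`.
#' @param seed integer seed.
#' @return a `PermutationPlan`.
#' @examples
#' PermutationPlan(nHypotheses = 10, alpha = 0.05)   # B = 200
#' @export
PermutationPlan <- function(nHypotheses, alpha = 0.05, nPermutations = NULL,
                            seed = 1L) {
    if (is.null(nPermutations) || identical(nPermutations, "auto"))
        nPermutations <- minPermutations(nHypotheses, alpha)
    new("PermutationPlan",
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed),
        alpha = as.numeric(alpha),
        nHypotheses = as.integer(nHypotheses))
}

#' Per-pair differential correlation test results
#'
#' A [S4Vectors::DataFrame] subclass with one row per tested network pair and
#' columns `source`, `target`, `r_<groupA>`, `r_<groupB>`, `statistic`,
#' `pvalue`, `adjusted_pvalue`.  Run-level information (correlation kind,
#' p-value kind, sidedness, group labels and sizes) is stored in
#' `metadata()`.
#' @export
setClass("PairTestResults", contains = "DFrame")

#' Per-source aggregation results
#'
#' A [S4Vectors::DataFrame] subclass with one row per (source, score kind)
#' combination carrying the hypergeometric overrepresentation test and the
#' requested aggregation scores with their permutation p-values.
#' @export
setClass("SourceAggregates", contains = "DFrame")
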