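#' Fisher variance-stabilising transformation of a correlation
#'
#' Computes `z(r) = arctanh(r)`.  For bivariate-normal data the transformed
#' sample correlation is asymptotically normal with mean `arctanh(rho)` and a
#' variance that does not depend on `rho` (Pearson) or depends on it only
#' through the bounded factor `1 + rho^2/2` (Spearman); see
#' [asymptoticVariance()].
#'
#' Correlations with `|r| >= 1 - 1e-12` are clamped to `+/-(1 - 1e-12)` with a
#' warning so that perfectly collinear inputs yield a large finite statistic
#' instead of an infinity.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return `arctanh` of the (clamped) correlations; an odd, strictly
#'   increasing function of `r`.
#' @examples
#' fisherTransform(c(0, 0.5, -0.5))
#' @export
fisherTransform <- function(r) {
    if (!is.numeric(r) || any(!is.finite(r)))
        stop("correlations must be finite numbers")
    if (any(abs(r) > 1))
        stop("correlations must lie in [-1, 1]")
    if (any(abs(r) >= .CLAMP)) {
        warning("correlation(s) with |r| >= 1 - 1e-12 clamped before arctanh")
        r <- pmin(pmax(r, -.CLAMP), .CLAMP)
    }
    atanh(r)
}

#' Asymptotic variance of the Fisher-transformed correlation
#'
#' For a sample of size `M` the transformed Pearson correlation has asymptotic
#' variance `1 / (M - 3)`.  The transformed Spearman correlation has
#' asymptotic variance `(1 + rho^2 / 2) / (M - 3)`, which depends on the
#' unknown population value; since `1 + rho^2/2 <= 1.5`, the worst-case bound
#' `1.5 / (M - 3)` yields a conservative (upper-bounding) test.
#'
#' @param M sample size of the group; must exceed 3.
#' @param kind `"pearson"` or `"spearman"`.
#' @param mode for Spearman: `"worst_case"` (default; the bound `1.5/(M-3)`)
#'   or `"plugin"` (uses `r` as a plug-in estimate of rho).  Ignored for
#'   Pearson.
#' @param r plug-in correlation estimate, required when
#'   `kind = "spearman", mode = "plugin"`.
#' @return the asymptotic variance (vectorised over `M` and `r`).
#' @examples
#' asymptoticVariance(103, "pearson")                      # 0.01
#' asymptoticVariance(103, "spearman")                     # 0.015
#' asymptoticVariance(103, "spearman", "plugin", r = 0)    # 0.01
#' @export
asymptoticVariance <- function(M, kind = c("pearson", "spearman"),
                               mode = c("worst_case", "plugin"), r = NULL) {
    kind <- match.arg(kind)
    mode <- match.arg(mode)
    if (any(M <= 3))
        stop("group size M must exceed 3 (variance has a 1/(M-3) factor)")
    if (kind == "pearson")
        return(1 / (M - 3))
    if (mode == "worst_case")
        return(1.5 / (M - 3))
    if (is.null(r))
        stop("plug-in Spearman variance needs the correlation 'r'")
    (1 + r^2 / 2) / (M - 3)
}

#' The z statistic for equality of two correlations
#'
#' Tests `rho_A = rho_B` from independent groups of sizes `K` and `L` via
#' `(arctanh(r_A) - arctanh(r_B)) / sqrt(sigma2_A + sigma2_B)`.  Under the
#' null the statistic is asymptotically standard normal.  For Spearman
#' correlations the default denominator uses the worst-case variances
#' `1.5/(M - 3)`, so the statistic is exactly the conservatively rescaled one
#' whose normal tail upper-bounds the plug-in p-value; `spearmanMode =
#' "plugin"` gives the plug-in-variance statistic instead (useful to verify
#' the conservativeness bound).
#'
#' The statistic is antisymmetric: swapping the groups negates it exactly.
#'
#' @param rA,rB correlations observed in group A and group B.
#' @param K,L group sizes (each > 3).
#' @param kind `"pearson"` or `"spearman"`.
#' @param spearmanMode `"worst_case"` (default) or `"plugin"`.
#' @return the z statistic (vectorised).
#' @examples
#' ztestStatistic(0.5, -0.5, 103, 103, "pearson")    # 7.7682
#' ztestStatistic(0.5, -0.5, 103, 103, "spearman")   # 6.3427
#' @export
ztestStatistic <- function(rA, rB, K, L, kind = c("pearson", "spearman"),
                           spearmanMode = c("worst_case", "plugin")) {
    kind <- match.arg(kind)
    spearmanMode <- match.arg(spearmanMode)
    if (kind == "pearson" || spearmanMode == "worst_case") {
        den <- sqrt(asymptoticVariance(K, kind, "worst_case") +
                    asymptoticVariance(L, kind, "worst_case"))
    } else {
        den <- sqrt(asymptoticVariance(K, kind, "plugin", r = rA) +
                    asymptoticVariance(L, kind, "plugin", r = rB))
    }
    (fisherTransform(rA) - fisherTransform(rB)) / den
}

#' Analytic p-value of the z statistic
#'
#' Normal-tail probability of the (asymptotically standard normal) statistic:
#' two-sided `2 * Phi(-|z|)` or one-sided `Phi(-z)` for the alternative
#' "correlation larger in group A".  For Spearman input statistics the
#' worst-case rescaling is already embedded in the statistic, so the returned
#' value upper-bounds the plug-in p-value.
#'
#' @param z numeric vector of z statistics.
#' @param sidedness `"two_sided"` (default) or `"one_sided_greater"`.
#' @return p-values in `[0, 1]`.
#' @examples
#' analyticPvalue(1.959964)                 # ~0.05
#' analyticPvalue(2, "one_sided_greater")
#' @export
analyticPvalue <- function(z, sidedness = c("two_sided", "one_sided_greater")) {
    sidedness <- match.arg(sidedness)
    if (any(!is.finite(z)))
        stop("z statistics must be finite")
    if (sidedness == "two_sided")
        2 * stats::pnorm(-abs(z))
    else
        stats::pnorm(-z)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate correction: sort ascending, take
#' `adjusted_i = min_{j >= i} (p_j * m / j)` clipped at 1, return in the input
#' order.  Adjustment is always applied across exactly the set of hypotheses
#' tested in one run, never pooled across runs or modes.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order, each `>=` its input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))   # 0.03 0.03 0.03
#' @export
bhAdjust <- function(pvalues) {
    if (!is.numeric(pvalues) || anyNA(pvalues) ||
        any(pvalues < 0 | pvalues > 1))
        stop("p-values must all lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Per-pair correlations within each group
#'
#' Computes, for every (source, target) pair of the network, the correlation
#' of the two molecules within each of the two sample groups.  Spearman
#' correlations are computed as Pearson correlations of within-group
#' midranks.  A molecule with zero variance inside a group is a hard error
#' naming the molecule and the group.
#'
#' @param x a [CoexExperiment-class].
#' @param network an [InteractionNetwork-class]; `NULL` for all unordered
#'   molecule pairs.
#' @param kind `"pearson"` or `"spearman"`.
#' @return a [S4Vectors::DataFrame] with columns `source`, `target`,
#'   `r_<groupA>`, `r_<groupB>`, in network order.
#' @examples
#' ce <- CoexExperiment(
#'   matrix(rnorm(80), 2, 40, dimnames = list(c("a", "b"), paste0("s", 1:40))),
#'   rep(c("N", "T"), each = 20))
#' groupCorrelations(ce, InteractionNetwork("a", "b"), "spearman")
#' @export
groupCorrelations <- function(x, network = NULL,
                              kind = c("pearson", "spearman")) {
    kind <- match.arg(kind)
    stopifnot(is(x, "CoexExperiment"))
    if (is.null(network))
        network <- exhaustiveNetwork(x)
    idx <- .networkIndices(x, network)
    gc <- .groupColumns(x)
    m <- assay(x, "exprs")
    rA <- .pairCorrelations(m, gc$A, idx$src, idx$tgt, kind, gc$labelA)
    rB <- .pairCorrelations(m, gc$B, idx$src, idx$tgt, kind, gc$labelB)
    df <- DataFrame(source = networkSources(network),
                    target = networkTargets(network),
                    rA = rA, rB = rB)
    colnames(df)[3:4] <- paste0("r_", c(gc$labelA, gc$labelB))
    df
}

#' Differential correlation z-test over a network
#'
#' For every (source, target) pair of the network, computes the within-group
#' correlations, the z statistic for their equality and a p-value (analytic
#' normal tail or label-permutation), then applies Benjamini-Hochberg
#' adjustment across exactly the tested pairs.  Results are returned in
#' network order.
#'
#' @param x a [CoexExperiment-class].
#' @param network an [InteractionNetwork-class]; `NULL` selects exhaustive
#'   mode (all unordered molecule pairs of `x`).
#' @param kind correlation kind, `"pearson"` (default) or `"spearman"`.
#'   Spearman is computed as Pearson on within-group midranks and is tested
#'   with the conservative worst-case variance.
#' @param pvalueKind `"analytic"` (default) or `"permutation"`.
#' @param sidedness `"two_sided"` (default) or `"one_sided_greater"`.
#' @param plan a [PermutationPlan-class] used when
#'   `pvalueKind = "permutation"`; defaults to
#'   `PermutationPlan(nHypotheses = length(network), alpha = alpha)`.
#' @param alpha significance level recorded with the run (and used for the
#'   default permutation count).
#' @return a [PairTestResults-class] with columns `source`, `target`,
#'   `r_<groupA>`, `r_<groupB>`, `statistic`, `pvalue`, `adjusted_pvalue`.
#' @examples
#' ce <- CoexExperiment(
#'   matrix(rnorm(200), 5, 40,
#'          dimnames = list(paste0("g", 1:5), paste0("s", 1:40))),
#'   rep(c("Normal", "Tumor"), each = 20))
#' runZtest(ce, exhaustiveNetwork(ce))
#' @export
runZtest <- function(x, network = NULL,
                     kind = c("pearson", "spearman"),
                     pvalueKind = c("analytic", "permutation"),
                     sidedness = c("two_sided", "one_sided_greater"),
                     plan = NULL, alpha = 0.05) {
    kind <- match.arg(kind)
    pvalueKind <- match.arg(pvalueKind)
    sidedness <- match.arg(sidedness)
    stopifnot(is(x, "CoexExperiment"))
    if (is.null(network))
        network <- exhaustiveNetwork(x)
    idx <- .networkIndices(x, network)
    gc <- .groupColumns(x)
    K <- length(gc$A); L <- length(gc$B)
    m <- assay(x, "exprs")
    denom <- .zDenominator(K, L, kind)
    obs <- .pairZ(m, gc$A, gc$B, idx$src, idx$tgt, kind, denom,
                  gc$labelA, gc$labelB)
    if (any(abs(obs$rA) >= .CLAMP) || any(abs(obs$rB) >= .CLAMP))
        warning("correlation(s) with |r| >= 1 - 1e-12 clamped before arctanh")
    if (pvalueKind == "analytic") {
        pv <- analyticPvalue(obs$z, sidedness)
    } else {
        if (is.null(plan))
            plan <- PermutationPlan(nHypotheses = length(network),
                                    alpha = alpha)
        pv <- .permutationPvaluesFromZ(
            m, gc, idx, kind, denom, obs$z, plan,
            sidedness = sidedness, pooled = FALSE)
    }
    df <- DataFrame(
        source = networkSources(network),
        target = networkTargets(network),
        rA = obs$rA, rB = obs$rB,
        statistic = obs$z,
        pvalue = pv,
        adjusted_pvalue = bhAdjust(pv))
    colnames(df)[3:4] <- paste0("r_", c(gc$labelA, gc$labelB))
    metadata(df) <- list(correlationKind = kind, pvalueKind = pvalueKind,
                         sidedness = sidedness, groupA = gc$labelA,
                         groupB = gc$labelB, K = K, L = L, alpha = alpha)
    new("PairTestResults", df)
}
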