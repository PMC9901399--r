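#' Minimum permutation count for BH-resolvable p-values
#'
#' When R hypotheses are tested simultaneously and BH-adjusted at level
#' alpha, the smallest adjusted p-value that can still be rejected is about
#' alpha / R, so at least `ceiling(R / alpha)` relabelings are needed for the
#' permutation p-value granularity to resolve it.  This is the default
#' number of permutations.
#'
#' @param R number of simultaneously tested hypotheses (>= 1).
#' @param alpha significance level in (0, 1).
#' @return `ceiling(R / alpha)` as an integer.
#' @examples
#' minPermutations(1000, 0.05)   # 20000
#' @export
minPermutations <- function(R, alpha) {
    if (!is.numeric(R) || any(R < 1))
        stop("R must be >= 1")
    if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
        any(alpha <= 0 | alpha >= 1))
        stop("alpha must lie strictly between 0 and 1")
    as.integer(ceiling(R / alpha))
}

#' Randomly relabel the samples, preserving group sizes
#'
#' Draws a uniformly random reassignment of the K + L samples to the two
#' groups with the original sizes K and L kept fixed.  Uses (and advances)
#' the caller's RNG stream.
#'
#' @param x a [CoexExperiment-class].
#' @return a `CoexExperiment` identical to `x` except for a permuted group
#'   factor (same labels, same sizes).
#' @examples
#' ce <- CoexExperiment(
#'   matrix(rnorm(80), 2, 40,
#'          dimnames = list(c("a", "b"), paste0("s", 1:40))),
#'   rep(c("N", "T"), each = 20))
#' set.seed(1)
#' groupSizes(permuteLabels(ce))   # unchanged sizes
#' @export
permuteLabels <- function(x) {
    stopifnot(is(x, "CoexExperiment"))
    grp <- sampleGroups(x)
    lev <- levels(grp)
    K <- sum(grp == lev[1L])
    n <- length(grp)
    newA <- sample.int(n, K)
    out <- rep(lev[2L], n)
    out[newA] <- lev[1L]
    colData(x)$group <- factor(out, levels = lev)
    x
}

# B x R matrix of z statistics under shared random relabelings.  One seeded
# stream drives all draws; each relabeling is applied to the whole matrix so
# every pair sees the same permutation set.
.permutationZMatrix <- function(m, gc, idx, kind, denom, plan) {
    B <- plan@nPermutations
    n <- length(gc$A) + length(gc$B)
    K <- length(gc$A)
    allCols <- c(gc$A, gc$B)
    R <- length(idx$src)
    Z <- matrix(NA_real_, nrow = B, ncol = R)
    .withSeed(plan@seed, {
        for (b in seq_len(B)) {
            pick <- sample.int(n, K)
            colsA <- allCols[pick]
            colsB <- allCols[-pick]
            Z[b, ] <- .pairZ(m, colsA, colsB, idx$src, idx$tgt, kind,
                             denom)$z
        }
    })
    Z
}

# permutation p-values given observed z and the permuted matrix
.permPvalues <- function(z0, Z, sidedness, pooled, smoothed) {
    B <- nrow(Z)
    R <- length(z0)
    if (sidedness == "two_sided") {
        z0c <- abs(z0); Zc <- abs(Z)
    } else {
        z0c <- z0; Zc <- Z
    }
    if (!pooled) {
        cnt <- colSums(Zc >= rep(z0c, each = B))
        total <- B
    } else {
        v <- sort(as.vector(Zc))
        # exceedances with ties counted: #{v >= t} = length(v) - #{v < t}
        cnt <- length(v) - findInterval(z0c, v, left.open = TRUE)
        total <- B * R
    }
    if (smoothed) (1 + cnt) / (total + 1) else cnt / total
}

.permutationPvaluesFromZ <- function(m, gc, idx, kind, denom, z0, plan,
                                     sidedness = "two_sided",
                                     pooled = FALSE, smoothed = TRUE) {
    Z <- .permutationZMatrix(m, gc, idx, kind, denom, plan)
    .permPvalues(z0, Z, sidedness, pooled, smoothed)
}

.permSetup <- function(x, network, kind) {
    stopifnot(is(x, "CoexExperiment"), is(network, "InteractionNetwork"))
    idx <- .networkIndices(x, network)
    gc <- .groupColumns(x)
    denom <- .zDenominator(length(gc$A), length(gc$B), kind)
    m <- assay(x, "exprs")
    z0 <- .pairZ(m, gc$A, gc$B, idx$src, idx$tgt, kind, denom,
                 gc$labelA, gc$labelB)$z
    list(m = m, gc = gc, idx = idx, denom = denom, z0 = z0)
}

#' Per-pair label-permutation p-values
#'
#' For each network pair i, relabels the samples B times (group sizes
#' preserved, one shared relabeling set for all pairs), recomputes the z
#' statistic, and returns `p_i = (1 + #\{b : |z_i^(b)| >= |z_i^(0)|\}) /
#' (B + 1)`.  Each pair's observed statistic is compared only against its own
#' permutation distribution.  The add-one smoothing keeps p strictly positive
#' (minimum attainable `1/(B+1)`) so BH adjustment behaves; `smoothed =
#' FALSE` restores the raw proportion.
#'
#' @param x a [CoexExperiment-class].
#' @param network an [InteractionNetwork-class].
#' @param kind `"pearson"` or `"spearman"`.
#' @param plan a [PermutationPlan-class]; defaults to B =
#'   `minPermutations(length(network), alpha)` with `alpha = 0.05`, seed 1.
#' @param sidedness `"two_sided"` (exceedance of `|z|`) or
#'   `"one_sided_greater"` (signed comparison).
#' @param smoothed logical; add-one smoothing (default `TRUE`).
#' @return numeric vector of p-values in network order.
#' @examples
#' ce <- CoexExperiment(
#'   matrix(rnorm(400), 2, 200,
#'          dimnames = list(c("a", "b"), paste0("s", 1:200))),
#'   rep(c("N", "T"), each = 100))
#' net <- InteractionNetwork("a", "b")
#' perPairPermutationPvalues(ce, net, plan = PermutationPlan(1, nPermutations = 99))
#' @export
perPairPermutationPvalues <- function(x, network,
                                      kind = c("pearson", "spearman"),
                                      plan = NULL,
                                      sidedness = c("two_sided",
                                                    "one_sided_greater"),
                                      smoothed = TRUE) {
    kind <- match.arg(kind)
    sidedness <- match.arg(sidedness)
    if (is.null(plan))
        plan <- PermutationPlan(nHypotheses = length(network))
    s <- .permSetup(x, network, kind)
    .permutationPvaluesFromZ(s$m, s$gc, s$idx, kind, s$denom, s$z0, plan,
                             sidedness, pooled = FALSE, smoothed = smoothed)
}

#' Pooled label-permutation p-values (cross-pair comparator)
#'
#' The alternative scheme in which every observed statistic is compared
#' against the permuted statistics of *all* pairs pooled together:
#' `p_i = (1 + #\{(j, b) : |z_j^(b)| >= |z_i^(0)|\}) / (R * B + 1)`.  Under
#' exchangeable pairs this agrees with the per-pair scheme, but when the
#' pairs are heterogeneous (most changing strongly, a few weakly) the pooled
#' null is inflated by the strong pairs and the weakly-changed pair's p-value
#' is biased upwards.  Provided as the comparator for the permutation-method
#' study; the per-pair scheme is the one recommended for analysis.
#'
#' @inheritParams perPairPermutationPvalues
#' @return numeric vector of p-values in network order.
#' @export
pooledPermutationPvalues <- function(x, network,
                                     kind = c("pearson", "spearman"),
                                     plan = NULL,
                                     sidedness = c("two_sided",
                                                   "one_sided_greater"),
                                     smoothed = TRUE) {
    kind <- match.arg(kind)
    sidedness <- match.arg(sidedness)
    if (is.null(plan))
        plan <- PermutationPlan(nHypotheses = length(network))
    s <- .permSetup(x, network, kind)
    .permutationPvaluesFromZ(s$m, s$gc, s$idx, kind, s$denom, s$z0, plan,
                             sidedness, pooled = TRUE, smoothed = smoothed)
}
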