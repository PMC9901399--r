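#' Hypergeometric overrepresentation test for a source molecule
#'
#' Tests whether the `s_G` significantly changed interactions of a source
#' molecule G are overrepresented among all `S` significant changes, given
#' that G has `n_G` interactions out of `N` in the network.  Under uniform
#' allocation `s_G` is hypergeometric `H(N, S, n_G)`; the returned value is
#' the upper tail including the observed count, `P(X >= s_G)`.
#'
#' @param sG observed number of significant interactions of the source.
#' @param nG number of network interactions of the source.
#' @param S total number of significant interactions in the network.
#' @param N total number of interactions in the network.
#' @return `P(X >= sG)` (vectorised over `sG`, `nG`).
#' @examples
#' hypergeomTest(2, 2, 5, 10)   # choose(5,2)/choose(10,2) = 10/45
#' hypergeomTest(0, 3, 5, 10)   # 1
#' @export
hypergeomTest <- function(sG, nG, S, N) {
    bad <- sG < 0 | sG > pmin(nG, S) | nG > N | S > N | nG < 0
    if (any(bad))
        stop("inconsistent counts: need 0 <= sG <= min(nG, S), nG <= N, S <= N")
    stats::phyper(sG - 1, S, N - S, nG, lower.tail = FALSE)
}

#' Aggregate a source molecule's per-target z statistics
#'
#' Summarises the z statistics of all tested (source, target) pairs of one
#' source molecule into a single score: their mean, median, or a quantile
#' (linear-interpolation convention, `stats::quantile` type 7).  A score far
#' from zero indicates a consistent trend of correlation change across the
#' source's targets even when no single pair survives multiple-testing
#' adjustment.
#'
#' @param z numeric vector of z statistics (nonempty).
#' @param scoreKind `"mean"`, `"median"` or `"quantile"`.
#' @param q quantile level in `[0, 1]` when `scoreKind = "quantile"`.
#' @return the scalar score.
#' @examples
#' aggregateScore(c(1, 2, 100), "median")          # 2
#' aggregateScore(c(0, 1, 2, 3), "quantile", 0.25) # 0.75
#' @export
aggregateScore <- function(z, scoreKind = c("mean", "median", "quantile"),
                           q = 0.25) {
    scoreKind <- match.arg(scoreKind)
    if (length(z) == 0L)
        stop("cannot aggregate an empty set of z statistics")
    switch(scoreKind,
           mean = mean(z),
           median = stats::median(z),
           quantile = unname(stats::quantile(z, probs = q, type = 7)))
}

#' Permutation p-value of one source's aggregation score
#'
#' Aggregates the z statistics of the source's network targets on the
#' observed labeling and under B shared relabelings, and returns
#' `p = (1 + #\{b : |score^(b)| >= |score^(0)|\}) / (B + 1)` -- a test of the
#' hypothesis that the aggregated score is zero, i.e. that the source has the
#' same correlations with its targets under both conditions.
#'
#' @param x a [CoexExperiment-class].
#' @param network an [InteractionNetwork-class].
#' @param sourceId the source molecule whose targets are aggregated.
#' @param kind correlation kind.
#' @param scoreKind `"mean"`, `"median"` or `"quantile"`.
#' @param plan a [PermutationPlan-class]; defaults to B =
#'   `minPermutations(1, 0.05)` = 20 (pass an explicit plan for real use).
#' @param q quantile level for `scoreKind = "quantile"`.
#' @return the permutation p-value (scalar, in `(0, 1]`).
#' @export
scorePermutationPvalue <- function(x, network, sourceId,
                                   kind = c("pearson", "spearman"),
                                   scoreKind = c("mean", "median", "quantile"),
                                   plan = NULL, q = 0.25) {
    kind <- match.arg(kind)
    scoreKind <- match.arg(scoreKind)
    keep <- networkSources(network) == sourceId
    if (!any(keep))
        stop("unknown source molecule: ", sourceId)
    sub <- InteractionNetwork(networkSources(network)[keep],
                              networkTargets(network)[keep])
    if (is.null(plan))
        plan <- PermutationPlan(nHypotheses = 1L)
    s <- .permSetup(x, sub, kind)
    Z <- .permutationZMatrix(s$m, s$gc, s$idx, kind, s$denom, plan)
    score0 <- aggregateScore(s$z0, scoreKind, q)
    scoreB <- apply(Z, 1L, aggregateScore, scoreKind = scoreKind, q = q)
    (1 + sum(abs(scoreB) >= abs(score0))) / (plan@nPermutations + 1)
}

#' Source-level aggregation of differential correlation results
#'
#' Runs the pairwise z-test once (analytic two-sided p-values), derives for
#' each source molecule G the interaction count `n_G` and the number of
#' significant changes `s_G` (BH-adjusted p < alpha), tests
#' overrepresentation with the hypergeometric upper tail, and -- for each
#' requested score kind -- aggregates the source's z statistics and attaches
#' a label-permutation p-value for the score.  BH adjustment is additionally
#' applied across sources, separately for the hypergeometric and for each
#' score statistic.
#'
#' Pair-level and score-level permutations share one seeded relabeling
#' stream, so a source with a single target reproduces the per-pair
#' permutation p-value exactly.
#'
#' @param x a [CoexExperiment-class].
#' @param network an [InteractionNetwork-class]; `NULL` for exhaustive mode
#'   (every molecule is a source whose targets are all other molecules).
#' @param kind correlation kind.
#' @param alpha significance level defining "significantly changed".
#' @param scoreKinds character vector among `"mean"`, `"median"`,
#'   `"quantile"`; may be empty to skip score permutation tests.
#' @param plan a [PermutationPlan-class] for the score permutations; defaults
#'   to B = `minPermutations(#sources, alpha)`.
#' @param q quantile level used by `"quantile"`.
#' @return a [SourceAggregates-class] with one row per (source, score kind),
#'   or one row per source when `scoreKinds` is empty; columns `source`,
#'   `n_G`, `s_G`, `hypergeom_pvalue`, `hypergeom_adjusted`, `score_kind`,
#'   `score_value`, `score_pvalue`, `score_adjusted`.  The underlying
#'   [PairTestResults-class] is attached as `metadata(result)$pairResults`.
#' @examples
#' ce <- CoexExperiment(
#'   matrix(rnorm(400), 10, 40,
#'          dimnames = list(paste0("g", 1:10), paste0("s", 1:40))),
#'   rep(c("N", "T"), each = 20))
#' net <- InteractionNetwork(rep("g1", 9), paste0("g", 2:10))
#' runAggregation(ce, net, plan = PermutationPlan(1, nPermutations = 99))
#' @export
runAggregation <- function(x, network = NULL,
                           kind = c("pearson", "spearman"),
                           alpha = 0.05, scoreKinds = "mean",
                           plan = NULL, q = 0.25) {
    kind <- match.arg(kind)
    if (is.null(network)) {
        ids <- rownames(x)
        src <- rep(ids, each = length(ids) - 1L)
        tgt <- unlist(lapply(seq_along(ids),
                             function(i) ids[-i]), use.names = FALSE)
        network <- InteractionNetwork(src, tgt)
    }
    if (length(scoreKinds))
        scoreKinds <- match.arg(scoreKinds, c("mean", "median", "quantile"),
                                several.ok = TRUE)
    pairRes <- runZtest(x, network, kind = kind, pvalueKind = "analytic",
                        sidedness = "two_sided", alpha = alpha)
    srcIds <- networkSources(network)
    sources <- unique(srcIds)
    nG <- as.integer(table(factor(srcIds, levels = sources)))
    sig <- pairRes$adjusted_pvalue < alpha
    sG <- as.integer(tapply(sig, factor(srcIds, levels = sources), sum))
    N <- length(network)
    S <- sum(sig)
    hyp <- hypergeomTest(sG, nG, S, N)
    hypAdj <- bhAdjust(hyp)

    if (length(scoreKinds)) {
        if (is.null(plan))
            plan <- PermutationPlan(nHypotheses = length(sources),
                                    alpha = alpha)
        s <- .permSetup(x, network, kind)
        Z <- .permutationZMatrix(s$m, s$gc, s$idx, kind, s$denom, plan)
        fsrc <- factor(srcIds, levels = sources)
        rows <- vector("list", length(scoreKinds))
        for (j in seq_along(scoreKinds)) {
            sk <- scoreKinds[j]
            score0 <- as.numeric(tapply(s$z0, fsrc, aggregateScore,
                                        scoreKind = sk, q = q))
            # B x #sources matrix of permuted scores
            scoreB <- vapply(seq_along(sources), function(g) {
                cols <- which(fsrc == sources[g])
                apply(Z[, cols, drop = FALSE], 1L, aggregateScore,
                      scoreKind = sk, q = q)
            }, numeric(plan@nPermutations))
            if (is.null(dim(scoreB)))
                scoreB <- matrix(scoreB, nrow = plan@nPermutations)
            cnt <- colSums(abs(scoreB) >= rep(abs(score0),
                                              each = plan@nPermutations))
            pv <- (1 + cnt) / (plan@nPermutations + 1)
            rows[[j]] <- DataFrame(
                source = sources, n_G = nG, s_G = sG,
                hypergeom_pvalue = hyp, hypergeom_adjusted = hypAdj,
                score_kind = if (sk == "quantile")
                    sprintf("quantile(%g)", q) else sk,
                score_value = score0,
                score_pvalue = pv,
                score_adjusted = bhAdjust(pv))
        }
        df <- do.call(rbind, rows)
    } else {
        df <- DataFrame(
            source = sources, n_G = nG, s_G = sG,
            hypergeom_pvalue = hyp, hypergeom_adjusted = hypAdj,
            score_kind = NA_character_, score_value = NA_real_,
            score_pvalue = NA_real_, score_adjusted = NA_real_)
    }
    metadata(df) <- list(alpha = alpha, N = N, S = S,
                         correlationKind = kind,
                         pairResults = pairRes,
                         plan = if (length(scoreKinds)) plan else NULL)
    new("SourceAggregates", df)
}
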