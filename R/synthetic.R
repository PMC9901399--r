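#' Scenario for the hub-gene aggregation power study
#'
#' Describes a multivariate-normal model of `m` genes sampled `n` times per
#' group with zero means and unit variances, in which gene 1 (the hub)
#' correlates `+rho` with genes `2..k` in group A ("Normal") and `-rho` with
#' the same genes in group B ("Tumor"); all remaining genes are independent.
#'
#' The correlations are realised through a single-factor construction:
#' genes `2..k` are `+/-rho * gene1 + sqrt(1 - rho^2) * noise`.  This
#' reproduces exactly the stated hub-to-gene correlations (and gives genes
#' `2..k` a common within-block correlation `rho^2`, identical in both groups
#' so irrelevant to the hub's tested pairs) while keeping the covariance
#' positive definite for every `k` and `|rho| < 1`; a matrix with the
#' `+/-rho` entries and zeros elsewhere would be indefinite whenever
#' `(k - 1) * rho^2 > 1`.
#'
#' @slot m number of genes.
#' @slot n per-group sample size.
#' @slot k the hub's correlations involve genes 2..k (k - 1 changed pairs;
#'   `k = 1` gives an exact null).
#' @slot rho correlation magnitude in (0, 1).
#' @slot seed integer seed.
#' @export
setClass("AggregationScenario",
         slots = c(m = "integer", n = "integer", k = "integer",
                   rho = "numeric", seed = "integer"))

setValidity("AggregationScenario", function(object) {
    msg <- character(0)
    if (object$k < 1L || object$k > object$m - 1L)
        msg <- c(msg, "need 1 <= k <= m - 1")
    if (object@rho < 0 || object@rho >= 1)
        msg <- c(msg, "rho must lie in [0, 1); rho = 0 gives an exact null")
    if (object@n <= 3L)
        msg <- c(msg, "per-group sample size n must exceed 3")
    if (length(msg)) msg else TRUE
})

setMethod("$", "AggregationScenario", function(x, name) slot(x, name))

#' @rdname AggregationScenario-class
#' @param m,n,k,rho,seed see the class slots.
#' @return an `AggregationScenario`.
#' @examples
#' AggregationScenario(m = 1000, n = 20, k = 100, rho = 0.5)
#' @export
AggregationScenario <- function(m = 1000L, n = 20L, k = 100L, rho = 0.5,
                                seed = 1L) {
    new("AggregationScenario", m = as.integer(m), n = as.integer(n),
        k = as.integer(k), rho = as.numeric(rho), seed = as.integer(seed))
}

#' Scenario for the permutation-method comparison study
#'
#' Describes `2 m` genes forming `m` independent pairs.  Group A ("Normal",
#' size K) is sampled with identity covariance; group B ("Tumor", size L)
#' is block-diagonal with `k` strong blocks (within-pair correlation
#' `rhoStrong`, clamped to `1 - 1e-6` for sampling validity when set to 1)
#' followed by `m - k` weak blocks (within-pair correlation `rhoWeak`).  The
#' last pair is the flagged weakly-changed pair on which the two permutation
#' p-value schemes are compared.
#'
#' @slot m number of gene pairs.
#' @slot k number of strongly-changed pairs (0 <= k <= m).
#' @slot K,L group sizes.
#' @slot rhoWeak,rhoStrong within-pair correlations of group B blocks.
#' @slot seed integer seed.
#' @export
setClass("PermScenario",
         slots = c(m = "integer", k = "integer", K = "integer",
                   L = "integer", rhoWeak = "numeric",
                   rhoStrong = "numeric", seed = "integer"))

setValidity("PermScenario", function(object) {
    msg <- character(0)
    if (object@k < 0L || object@k > object@m)
        msg <- c(msg, "need 0 <= k <= m")
    if (object@K <= 3L || object@L <= 3L)
        msg <- c(msg, "group sizes must exceed 3")
    if (abs(object@rhoWeak) > 1 || abs(object@rhoStrong) > 1)
        msg <- c(msg, "block correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("$", "PermScenario", function(x, name) slot(x, name))

#' @rdname PermScenario-class
#' @param m,k,K,L,rhoWeak,rhoStrong,seed see the class slots.
#' @return a `PermScenario`.
#' @examples
#' PermScenario(m = 10, k = 9, K = 100, L = 50)
#' @export
PermScenario <- function(m = 10L, k = 9L, K = 100L, L = 100L,
                         rhoWeak = 0.5, rhoStrong = 1.0, seed = 1L) {
    new("PermScenario", m = as.integer(m), k = as.integer(k),
        K = as.integer(K), L = as.integer(L), rhoWeak = as.numeric(rhoWeak),
        rhoStrong = as.numeric(rhoStrong), seed = as.integer(seed))
}

# draw n samples of a zero-mean bivariate normal with unit variances and
# correlation rho, via the 2x2 Cholesky factor
.rbvn <- function(n, rho) {
    a <- stats::rnorm(n)
    b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n)
    rbind(a, b)
}

# hub-factor draw: gene 1 ~ N(0,1); genes 2..k = sgn*rho*g1 + noise;
# genes (k+1)..m iid
.rHubGroup <- function(m, n, k, rho, sign) {
    out <- matrix(stats::rnorm(m * n), nrow = m, ncol = n)
    if (k >= 2L) {
        hub <- out[1L, ]
        out[2:k, ] <- sign * rho * rep(hub, each = k - 1L) +
            sqrt(1 - rho^2) * out[2:k, , drop = FALSE]
    }
    out
}

#' Generate the hub-gene aggregation dataset
#'
#' Samples the two groups of an [AggregationScenario-class] (gene 1
#' correlated `+rho` with genes 2..k in "Normal", `-rho` in "Tumor") and
#' builds the star network of gene 1 against all other `m - 1` genes.
#'
#' @param scenario an [AggregationScenario-class].
#' @return a list with elements `experiment` ([CoexExperiment-class], groups
#'   "Normal"/"Tumor" of size `n` each) and `network`
#'   ([InteractionNetwork-class], `m - 1` pairs with gene 1 as source).
#' @examples
#' ds <- generateAggregationDataset(AggregationScenario(m = 50, n = 10, k = 5))
#' groupSizes(ds$experiment)
#' @export
generateAggregationDataset <- function(scenario) {
    stopifnot(is(scenario, "AggregationScenario"))
    m <- scenario$m; n <- scenario$n; k <- scenario$k; rho <- scenario$rho
    dat <- .withSeed(scenario$seed, {
        cbind(.rHubGroup(m, n, k, rho, +1), .rHubGroup(m, n, k, rho, -1))
    })
    genes <- sprintf("gene%d", seq_len(m))
    samples <- sprintf("sample%d", seq_len(2L * n))
    dimnames(dat) <- list(genes, samples)
    ce <- CoexExperiment(dat, rep(c("Normal", "Tumor"), each = n),
                         groupA = "Normal")
    net <- InteractionNetwork(rep(genes[1L], m - 1L), genes[-1L])
    list(experiment = ce, network = net)
}

#' Generate the paired-blocks permutation dataset
#'
#' Samples the two groups of a [PermScenario-class]: group A with identity
#' covariance over `2 m` genes, group B block-diagonal with `k` strong blocks
#' (correlation `rhoStrong`, clamped to `1 - 1e-6` when 1) and `m - k` weak
#' blocks (correlation `rhoWeak`).  The network lists the `m` within-block
#' pairs; the index of the flagged weakly-changed pair (the last one) is
#' returned as `weakPair`.
#'
#' @param scenario a [PermScenario-class].
#' @return a list with `experiment`, `network`, and `weakPair` (integer
#'   index into the network; `NA` when `k = m`).
#' @examples
#' ds <- generatePermDataset(PermScenario(m = 10, k = 9, K = 100, L = 50))
#' ds$weakPair   # 10
#' @export
generatePermDataset <- function(scenario) {
    stopifnot(is(scenario, "PermScenario"))
    m <- scenario$m; k <- scenario$k
    K <- scenario$K; L <- scenario$L
    rhoS <- min(scenario$rhoStrong, 1 - 1e-6)
    rhoW <- scenario$rhoWeak
    dat <- .withSeed(scenario$seed, {
        a <- matrix(stats::rnorm(2L * m * K), nrow = 2L * m, ncol = K)
        b <- matrix(NA_real_, nrow = 2L * m, ncol = L)
        for (j in seq_len(m)) {
            rows <- c(2L * j - 1L, 2L * j)
            b[rows, ] <- .rbvn(L, if (j <= k) rhoS else rhoW)
        }
        cbind(a, b)
    })
    genes <- sprintf("gene%d", seq_len(2L * m))
    samples <- sprintf("sample%d", seq_len(K + L))
    dimnames(dat) <- list(genes, samples)
    ce <- CoexExperiment(dat, rep(c("Normal", "Tumor"), c(K, L)),
                         groupA = "Normal")
    net <- InteractionNetwork(genes[2L * seq_len(m) - 1L],
                              genes[2L * seq_len(m)])
    list(experiment = ce, network = net,
         weakPair = if (k < m) m else NA_integer_)
}

#' Power study of the hub's mean aggregation score
#'
#' For every grid cell (n, k, rho), repeatedly generates the hub-gene
#' aggregation dataset, computes the permutation p-value of the hub's mean
#' aggregation score, and reports the mean and standard deviation of the
#' p-value across replicates.  Shows how the sample size needed to detect a
#' fixed fraction of changed correlations shrinks as the correlation
#' magnitude grows.
#'
#' @param nValues,kValues,rhoValues grids of per-group sample sizes, changed
#'   pair counts, and correlation magnitudes.
#' @param m number of genes.
#' @param replicates replicate datasets per cell.
#' @param B permutations per p-value.
#' @param seed base seed; replicate r of cell i uses a distinct derived seed.
#' @return a data.frame with columns `n`, `k`, `rho`, `mean_pvalue`,
#'   `sd_pvalue`, `replicates`.
#' @export
aggregationPowerStudy <- function(nValues = c(10L, 20L, 40L, 80L),
                                  kValues = 100L,
                                  rhoValues = c(0.3, 0.5, 0.7),
                                  m = 1000L, replicates = 10L, B = 1000L,
                                  seed = 1L) {
    grid <- expand.grid(n = nValues, k = kValues, rho = rhoValues,
                        KEEP.OUT.ATTRS = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i) {
        pv <- vapply(seq_len(replicates), function(r) {
            sc <- AggregationScenario(
                m = m, n = grid$n[i], k = grid$k[i], rho = grid$rho[i],
                seed = seed + 7919L * i + r)
            ds <- generateAggregationDataset(sc)
            scorePermutationPvalue(
                ds$experiment, ds$network, sourceId = "gene1",
                kind = "pearson", scoreKind = "mean",
                plan = PermutationPlan(nHypotheses = 1L, nPermutations = B,
                                       seed = seed + 104729L * i + r))
        }, numeric(1L))
        data.frame(n = grid$n[i], k = grid$k[i], rho = grid$rho[i],
                   mean_pvalue = mean(pv), sd_pvalue = stats::sd(pv),
                   replicates = replicates)
    })
    do.call(rbind, res)
}

#' Comparison of the per-pair and pooled permutation p-value schemes
#'
#' Generates the paired-blocks dataset (K fixed, L varying) and computes both
#' permutation p-values on the flagged weakly-changed pair.  When most pairs
#' change strongly (`k` close to `m`) the pooled scheme's null distribution
#' is inflated by the strong pairs and the weak pair's pooled p-value is
#' biased upwards, while the per-pair scheme remains calibrated.
#'
#' @param LValues grid of group B sizes.
#' @param K group A size.
#' @param m,k number of pairs and of strongly-changed pairs.
#' @param replicates replicate datasets per L.
#' @param B permutations per p-value.
#' @param seed base seed.
#' @return a data.frame with columns `L`, `k`, `method` (`"per_pair"` /
#'   `"pooled"`), `mean_pvalue`, `sd_pvalue`, `replicates`.
#' @export
permutationComparisonStudy <- function(LValues = seq(10L, 100L, by = 10L),
                                       K = 100L, m = 10L, k = 9L,
                                       replicates = 20L, B = 1000L,
                                       seed = 1L) {
    res <- lapply(seq_along(LValues), function(i) {
        L <- LValues[i]
        pp <- matrix(NA_real_, nrow = replicates, ncol = 2L)
        for (r in seq_len(replicates)) {
            sc <- PermScenario(m = m, k = k, K = K, L = L,
                               seed = seed + 7919L * i + r)
            ds <- generatePermDataset(sc)
            plan <- PermutationPlan(nHypotheses = m, nPermutations = B,
                                    seed = seed + 104729L * i + r)
            pp[r, 1L] <- perPairPermutationPvalues(
                ds$experiment, ds$network, kind = "pearson",
                plan = plan)[ds$weakPair]
            pp[r, 2L] <- pooledPermutationPvalues(
                ds$experiment, ds$network, kind = "pearson",
                plan = plan)[ds$weakPair]
        }
        data.frame(L = rep(L, 2L), k = k,
                   method = c("per_pair", "pooled"),
                   mean_pvalue = colMeans(pp),
                   sd_pvalue = apply(pp, 2L, stats::sd),
                   replicates = replicates)
    })
    do.call(rbind, res)
}
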