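# Internal numerical helpers shared by the test engine and the permutation
# machinery.  None of these are exported.

# evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    expr
}

.CLAMP <- 1 - 1e-12

# midrank (average-tie) ranks per row
.rowRanks <- function(m) {
    if (nrow(m) == 0L) return(m)
    t(apply(m, 1L, rank))
}

# Correlations of the (src, tgt) index pairs over the columns `cols` of x.
# Spearman is Pearson on within-slice midranks.  Zero within-slice variance
# for any molecule participating in a pair is a hard error naming the
# molecule and group (no silent r = 0).
.pairCorrelations <- function(x, cols, src, tgt, kind, groupLabel = "group") {
    xs <- x[, cols, drop = FALSE]
    if (kind == "spearman")
        xs <- .rowRanks(xs)
    xs <- xs - rowMeans(xs)
    ss <- sqrt(.rowSums(xs * xs, nrow(xs), ncol(xs)))
    need <- unique(c(src, tgt))
    bad <- need[ss[need] == 0]
    if (length(bad))
        stop("zero within-group variance in group '", groupLabel,
             "' for molecule(s): ",
             paste(rownames(x)[bad], collapse = ", "))
    xs <- xs / ss
    r <- .rowSums(xs[src, , drop = FALSE] * xs[tgt, , drop = FALSE],
                  length(src), ncol(xs))
    pmin(pmax(r, -1), 1)
}

# z statistics for all pairs under an arbitrary assignment of columns to the
# two groups; variance denominator depends only on (K, L, kind) so it is
# precomputed by the caller.  Clamping here is silent: over thousands of
# relabelings a warning per collinear draw is noise.
.pairZ <- function(x, colsA, colsB, src, tgt, kind, denom,
                   labelA = "A", labelB = "B") {
    rA <- .pairCorrelations(x, colsA, src, tgt, kind, labelA)
    rB <- .pairCorrelations(x, colsB, src, tgt, kind, labelB)
    dz <- atanh(pmin(pmax(rA, -.CLAMP), .CLAMP)) -
          atanh(pmin(pmax(rB, -.CLAMP), .CLAMP))
    list(z = dz / denom, rA = rA, rB = rB)
}

# variance denominator sqrt(sigma2(K) + sigma2(L)) of the z statistic
.zDenominator <- function(K, L, kind) {
    sqrt(asymptoticVariance(K, kind, mode = "worst_case") +
         asymptoticVariance(L, kind, mode = "worst_case"))
}

# map network identifiers onto row indices of the experiment
.networkIndices <- function(x, network) {
    if (length(network) == 0L)
        stop("the interaction network is empty; nothing to test")
    src <- match(networkSources(network), rownames(x))
    tgt <- match(networkTargets(network), rownames(x))
    missing <- c(networkSources(network)[is.na(src)],
                 networkTargets(network)[is.na(tgt)])
    if (length(missing))
        stop("network molecules absent from the expression matrix: ",
             paste(unique(missing), collapse = ", "))
    list(src = src, tgt = tgt)
}

.groupColumns <- function(x) {
    grp <- sampleGroups(x)
    lev <- levels(grp)
    list(A = which(grp == lev[1L]), B = which(grp == lev[2L]),
         labelA = lev[1L], labelB = lev[2L])
}
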