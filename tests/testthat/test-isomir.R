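test_that("isomiR identifiers parse and round-trip", {
    p <- parseIsomir(c("hsa-miR-192-5p|+1", "hsa-miR-93-5p|0",
                       "hsa-miR-101-3p|-2"))
    expect_identical(p$mirna, c("hsa-miR-192-5p", "hsa-miR-93-5p",
                                "hsa-miR-101-3p"))
    expect_identical(p$shift, c(1L, 0L, -2L))
    ids <- c("hsa-miR-192-5p|+1", "hsa-miR-93-5p|0", "hsa-let-7a-5p|-3")
    expect_identical(formatIsomir(parseIsomir(ids)), ids)
    expect_identical(formatIsomir("hsa-miR-1", 2), "hsa-miR-1|+2")
    expect_error(parseIsomir("hsa-miR-93-5p"), "malformed")
    expect_error(parseIsomir("hsa-miR-93-5p|x"), "malformed")
    expect_error(parseIsomir("hsa-miR-93-5p|0|+2"), "malformed")
})

test_that("RPM normalisation scales by library size times 1e6", {
    counts <- matrix(c(5, 0, 3, 7), 2, 2,
                     dimnames = list(c("a", "b"), c("s1", "s2")))
    rpm <- rpmNormalize(counts, librarySizes = c(10, 100))
    expect_equal(rpm["a", "s1"], 5e5)
    expect_equal(rpm["b", "s1"], 0)
    expect_equal(rpm[, "s2"], c(a = 3e4, b = 7e4))
    # conservation: when the library size is the column total, shares sum to 1e6
    rpm2 <- rpmNormalize(counts)
    expect_equal(colSums(rpm2), c(s1 = 1e6, s2 = 1e6))
    expect_error(rpmNormalize(counts, librarySizes = c(0, 10)), "library size")
    expect_error(rpmNormalize(-counts), "nonnegative")
})

test_that("the cumulative-share filter returns the minimal covering prefix", {
    m <- matrix(c(90, 6, 4), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
    expect_identical(highlyExpressedSet(m, 0.95), c("A", "B"))
    expect_identical(highlyExpressedSet(m, 0.90), "A")
    expect_identical(highlyExpressedSet(m[1, , drop = FALSE], 0.1), "A")
    withZero <- rbind(m, D = 0)
    expect_identical(highlyExpressedSet(withZero, 1.0), c("A", "B", "C"))
    # pooled across samples, ties broken by identifier
    tied <- matrix(c(5, 5, 0, 0, 5, 5), 3, 2,
                   dimnames = list(c("Z", "M", "A"), c("s1", "s2")))
    expect_identical(highlyExpressedSet(tied, 0.5), c("M", "Z")[1])
    expect_error(highlyExpressedSet(m, 0), "fraction")
})

test_that("the cumulative-share filter is monotone in the fraction", {
    set.seed(301)
    m <- matrix(rpois(40 * 5, lambda = rexp(40, 1 / 50)), 40, 5,
                dimnames = list(sprintf("iso%02d", 1:40), sprintf("s%d", 1:5)))
    fr <- c(0.2, 0.5, 0.8, 0.95, 1.0)
    sets <- lapply(fr, highlyExpressedSet, x = m)
    for (i in seq_len(length(fr) - 1L))
        expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
})

test_that("AGO2 weighting multiplies per sample and respects the pseudocount", {
    expect_equal(ago2Weight(c(1, 2), c(3, 4), log2transform = FALSE),
                 c(3, 8))
    expect_equal(ago2Weight(c(1, 2), c(3, 4)), log2(c(4, 9)))
    expect_equal(ago2Weight(c(5, 9), c(0, 0)), c(0, 0))   # pseudocount 1
    m <- matrix(1:6, 2, 3)
    expect_equal(ago2Weight(m, c(1, 10, 100), log2transform = FALSE),
                 m * rep(c(1, 10, 100), each = 2))
    expect_error(ago2Weight(c(1, 2), c(1, 2, 3)), "per sample")
})

test_that("constant AGO2 weighting is a no-op for rank correlations", {
    set.seed(311)
    rpm <- abs(rnorm(30)) * 100
    target <- rnorm(30)
    w <- ago2Weight(rpm, rep(7, 30), log2transform = FALSE)
    expect_equal(cor(w, target, method = "spearman"),
                 cor(rpm, target, method = "spearman"), tolerance = 1e-12)
})

test_that("anticorrelation networks use a strict threshold", {
    ds <- makePairedExperiment(3, 10, 10, rhoA = 0, rhoB = 0, seed = 321)
    res <- runZtest(ds$experiment, ds$network, kind = "spearman")
    # overwrite the correlation columns with exact boundary cases
    res$r_Normal <- c(-0.3, -0.31, -0.29)
    net <- buildCorrelationNetwork(res, "Normal")
    expect_identical(length(net), 1L)
    expect_identical(networkSources(net), res$source[2])
    expect_error(buildCorrelationNetwork(res, "NoSuchGroup"), "unknown group")
    empty <- res[0, ]
    S4Vectors::metadata(empty) <- S4Vectors::metadata(res)
    expect_identical(length(buildCorrelationNetwork(empty, "Normal")), 0L)
})

test_that("target-change classification follows the jump definition", {
    ds <- makePairedExperiment(4, 10, 10, rhoA = 0, rhoB = 0, seed = 331)
    res <- runZtest(ds$experiment, ds$network, kind = "spearman")
    res$r_Normal <- c(-0.5, -0.1, -0.5, -0.45)
    res$r_Tumor <- c(-0.1, -0.5, -0.1, -0.35)
    res$adjusted_pvalue <- c(0.01, 0.01, 0.2, 0.01)
    ch <- classifyTargetChanges(res)
    expect_identical(as.character(ch$status),
                     c("lost", "gained", "unchanged", "unchanged"))
    # statuses partition the pairs
    expect_identical(nrow(ch), 4L)
    expect_identical(sum(table(ch$status)), 4L)
    expect_error(classifyTargetChanges(res[, setdiff(colnames(res),
                                                     "adjusted_pvalue")]),
                 "adjusted p-values")
})

test_that("per-source change summaries count and normalise correctly", {
    ds <- makePairedExperiment(4, 10, 10, rhoA = 0, rhoB = 0, seed = 341)
    res <- runZtest(ds$experiment, ds$network, kind = "spearman")
    res$source <- rep(c("isoA", "isoB"), each = 2)
    res$r_Normal <- c(-0.5, -0.6, -0.1, -0.4)
    res$r_Tumor <- c(-0.1, -0.2, -0.5, -0.4)
    res$adjusted_pvalue <- c(0.01, 0.01, 0.01, 0.5)
    sm <- summariseTargetChanges(classifyTargetChanges(res))
    a <- sm[sm$source == "isoA", ]
    expect_identical(c(a$lost, a$gained, a$n_targets_groupA), c(2L, 0L, 2L))
    expect_equal(a$lost_norm, 1.0)
    b <- sm[sm$source == "isoB", ]
    expect_identical(c(b$lost, b$gained, b$n_targets_groupA), c(0L, 1L, 1L))
})

test_that("the isomiR pipeline runs end to end on synthetic fixtures", {
    # counts -> RPM -> 95% filter -> AGO2 weighting -> z-test -> jump classes
    set.seed(351)
    nS <- 30L                                    # samples per group
    samples <- sprintf("s%d", seq_len(2L * nS))
    isos <- formatIsomir(rep(c("hsa-miR-1-5p", "hsa-miR-2-3p"), each = 3),
                         rep(c(-1L, 0L, 1L), 2))
    # two dominant isomiRs, four rare ones; overdispersed counts (lognormal
    # per-sample rates) so biological variation dominates the shared AGO2 and
    # library-size factors and the isomiRs stay mutually independent
    lam <- c(50, 2000, 30, 20, 1500, 25)
    rates <- lam * matrix(exp(rnorm(6L * 2L * nS, sd = 0.6)), nrow = 6L)
    counts <- matrix(rpois(6L * 2L * nS, rates), nrow = 6L,
                     dimnames = list(isos, samples))
    ago2 <- runif(2L * nS, 80, 120)
    libSizes <- round(runif(2L * nS, 9e4, 1.1e5))
    rpm <- rpmNormalize(counts, librarySizes = libSizes)
    keep <- highlyExpressedSet(rpm, 0.95)
    expect_true(all(c("hsa-miR-1-5p|0", "hsa-miR-2-3p|0") %in% keep))
    expect_lt(length(keep), 6L)
    weighted <- ago2Weight(rpm[keep, , drop = FALSE], ago2)
    # targets anticorrelated with iso1 in Normal only; iso2 targets null
    iso1 <- weighted[1, ]
    # GENE1 is repressed by iso1 in Normal; the coupling is lost (slightly
    # reversed) in Tumor.  GENE2 is never a target.
    tgt1 <- ifelse(seq_along(iso1) <= nS, -0.9, 0.2) * scale(iso1)[, 1] +
        rnorm(2L * nS, sd = 0.5)
    tgt2 <- rnorm(2L * nS)
    exprs <- rbind(weighted, GENE1 = tgt1, GENE2 = tgt2)
    ce <- CoexExperiment(exprs, rep(c("Normal", "Tumor"), each = nS))
    net <- InteractionNetwork(rep(keep[1:2], each = 2),
                              rep(c("GENE1", "GENE2"), 2))
    res <- runZtest(ce, net, kind = "spearman")
    ch <- classifyTargetChanges(res, alpha = 0.05, threshold = -0.3)
    expect_identical(as.character(ch$status[ch$target == "GENE1"][1]), "lost")
    sm <- summariseTargetChanges(ch)
    expect_identical(sum(sm$lost), 1L)
})
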