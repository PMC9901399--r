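test_that("fisherTransform matches the closed form and is odd", {
    expect_identical(fisherTransform(0), 0)
    expect_equal(fisherTransform(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
    expect_equal(fisherTransform(-0.5), -fisherTransform(0.5))
    r <- seq(-0.95, 0.95, by = 0.05)
    expect_equal(fisherTransform(r), -fisherTransform(-r))
    expect_true(all(diff(fisherTransform(r)) > 0))
})

test_that("fisherTransform clamps collinear input with a warning and rejects bad input", {
    expect_warning(z1 <- fisherTransform(1), "clamped")
    expect_true(is.finite(z1))
    expect_warning(zm <- fisherTransform(-1), "clamped")
    expect_equal(zm, -z1)
    expect_error(fisherTransform(NA_real_), "finite")
    expect_error(fisherTransform(1.2), "\\[-1, 1\\]")
})

test_that("asymptoticVariance matches the 1/(M-3) forms", {
    expect_equal(asymptoticVariance(103, "pearson"), 0.01, tolerance = 1e-12)
    expect_equal(asymptoticVariance(103, "spearman", "worst_case"), 0.015,
                 tolerance = 1e-12)
    expect_equal(asymptoticVariance(103, "spearman", "plugin", r = 0), 0.01,
                 tolerance = 1e-12)
    expect_equal(asymptoticVariance(10, "spearman", "plugin", r = 0.6),
                 (1 + 0.18) / 7, tolerance = 1e-12)
    expect_error(asymptoticVariance(3, "pearson"), "exceed 3")
})

test_that("ztestStatistic matches closed-form oracles and is antisymmetric", {
    expect_identical(ztestStatistic(0.4, 0.4, 10, 50), 0)
    expect_equal(ztestStatistic(0.5, -0.5, 103, 103, "pearson"),
                 2 * atanh(0.5) / sqrt(0.02), tolerance = 1e-12)
    expect_equal(ztestStatistic(0.5, -0.5, 103, 103, "spearman"),
                 2 * atanh(0.5) / sqrt(0.03), tolerance = 1e-12)
    set.seed(11)
    rA <- runif(50, -0.9, 0.9); rB <- runif(50, -0.9, 0.9)
    for (kind in c("pearson", "spearman"))
        expect_equal(ztestStatistic(rA, rB, 14, 23, kind),
                     -ztestStatistic(rB, rA, 23, 14, kind),
                     tolerance = 1e-12)
})

test_that("analyticPvalue matches an independent erfc-based normal tail", {
    expect_identical(analyticPvalue(0), 1)
    expect_equal(analyticPvalue(1.959964), 0.05, tolerance = 1e-6)
    # independent CDF: Phi(-|z|) = erfc(|z| / sqrt(2)) / 2
    z <- c(0.5, 1.5, 3, 7.7682)
    expect_equal(analyticPvalue(z), pracma::erfc(abs(z) / sqrt(2)),
                 tolerance = 1e-9)
    expect_equal(analyticPvalue(7.7682), 7.98e-15, tolerance = 1e-2)
    expect_equal(analyticPvalue(z, "one_sided_greater"),
                 pracma::erfc(z / sqrt(2)) / 2, tolerance = 1e-9)
    expect_equal(analyticPvalue(-2, "one_sided_greater"),
                 1 - pracma::erfc(2 / sqrt(2)) / 2, tolerance = 1e-9)
    expect_error(analyticPvalue(Inf), "finite")
})

test_that("bhAdjust matches an independent step-up oracle", {
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(c(0.5, 1.0)), c(1.0, 1.0))
    set.seed(5)
    for (i in 1:10) {
        p <- runif(25)^2
        adj <- bhAdjust(p)
        expect_equal(adj, bhOracle(p), tolerance = 1e-12)
        expect_true(all(adj >= p))
        expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("groupCorrelations equals a naive per-pair cor() loop", {
    set.seed(21)
    for (kind in c("pearson", "spearman")) {
        ce <- makeExperiment(nGenes = 50L, nPerGroup = 20L, seed = 100 +
                             match(kind, c("pearson", "spearman")))
        net <- exhaustiveNetwork(ce)
        got <- groupCorrelations(ce, net, kind)
        m <- SummarizedExperiment::assay(ce, "exprs")
        grp <- sampleGroups(ce)
        pairs <- networkPairs(net)
        for (i in sample(nrow(pairs), 60)) {
            a <- m[pairs$source[i], ]; b <- m[pairs$target[i], ]
            expect_equal(got$r_Normal[i],
                         cor(a[grp == "Normal"], b[grp == "Normal"],
                             method = kind), tolerance = 1e-12)
            expect_equal(got$r_Tumor[i],
                         cor(a[grp == "Tumor"], b[grp == "Tumor"],
                             method = kind), tolerance = 1e-12)
        }
    }
})

test_that("degenerate pairs give exact correlations of +/-1", {
    m <- rbind(x = c(1, 2, 3, 4, 10, 20, 30, 40),
               y = c(4, 3, 2, 1, 40, 30, 20, 10),
               w = c(1, 2, 3, 4, 1, 2, 3, 4)^2)
    colnames(m) <- sprintf("s%d", 1:8)
    ce <- CoexExperiment(m, rep(c("A", "B"), each = 4))
    net <- InteractionNetwork(c("x", "x"), c("y", "w"))
    for (kind in c("pearson", "spearman")) {
        r <- groupCorrelations(ce, net, kind)
        expect_equal(r$r_A[1], -1)
        expect_equal(r$r_B[1], -1)
    }
    # x vs x^2 on positive increasing values: perfect monotone, not linear
    m2 <- rbind(x = c(1:5, 1:5), y = c((1:5)^2, (1:5)^2))
    colnames(m2) <- sprintf("s%d", 1:10)
    ce2 <- CoexExperiment(m2, rep(c("A", "B"), each = 5))
    r5 <- groupCorrelations(ce2, InteractionNetwork("x", "y"), "pearson")
    expect_equal(r5$r_A[1], cor(1:5, (1:5)^2), tolerance = 1e-12)
    rs <- groupCorrelations(ce2, InteractionNetwork("x", "y"), "spearman")
    expect_equal(rs$r_A[1], 1)
})

test_that("constant rows raise an error naming molecule and group", {
    m <- rbind(g1 = c(1, 1, 1, 1, rnorm(4)), g2 = rnorm(8))
    colnames(m) <- sprintf("s%d", 1:8)
    ce <- CoexExperiment(m, rep(c("A", "B"), each = 4))
    expect_error(groupCorrelations(ce, InteractionNetwork("g1", "g2")),
                 "g1.*group 'A'|group 'A'.*g1")
})

test_that("runZtest composes correlations, statistic, p-values and BH", {
    ds <- makePairedExperiment(3, 20, 20, rhoA = c(0.8, 0, -0.5),
                               rhoB = c(0.8, 0, -0.5), seed = 31)
    res <- runZtest(ds$experiment, ds$network)
    expect_s4_class(res, "PairTestResults")
    expect_equal(nrow(res), 3L)
    # recompute by hand from the correlation columns
    zref <- ztestStatistic(res$r_Normal, res$r_Tumor, 20, 20, "pearson")
    expect_equal(res$statistic, zref, tolerance = 1e-12)
    expect_equal(res$pvalue, analyticPvalue(zref), tolerance = 1e-12)
    expect_equal(res$adjusted_pvalue, bhOracle(res$pvalue), tolerance = 1e-12)
    expect_true(all(res$adjusted_pvalue >= res$pvalue))
    expect_error(runZtest(ds$experiment,
                          InteractionNetwork(character(0), character(0))),
                 "empty")
})

test_that("identical per-group data give z = 0 and p = 1", {
    set.seed(7)
    half <- matrix(rnorm(10), 2, 5)
    m <- cbind(half, half)
    dimnames(m) <- list(c("a", "b"), sprintf("s%d", 1:10))
    ce <- CoexExperiment(m, rep(c("A", "B"), each = 5))
    res <- runZtest(ce, InteractionNetwork("a", "b"))
    expect_equal(res$statistic, 0)
    expect_equal(res$pvalue, 1)
    expect_equal(res$adjusted_pvalue, 1)
})

test_that("swapping group labels negates z exactly and keeps two-sided p", {
    ce <- makeExperiment(nGenes = 12L, nPerGroup = 10L, seed = 41)
    net <- exhaustiveNetwork(ce)
    for (kind in c("pearson", "spearman")) {
        a <- runZtest(ce, net, kind = kind)
        b <- runZtest(swapGroups(ce), net, kind = kind)
        expect_identical(a$statistic, -b$statistic)
        expect_identical(a$pvalue, b$pvalue)
    }
})

test_that("the worst-case Spearman p upper-bounds the plug-in p", {
    set.seed(51)
    rA <- runif(1000, -0.999, 0.999)
    rB <- runif(1000, -0.999, 0.999)
    K <- sample(5:200, 1000, replace = TRUE)
    L <- sample(5:200, 1000, replace = TRUE)
    zWorst <- ztestStatistic(rA, rB, K, L, "spearman")
    zPlug <- ztestStatistic(rA, rB, K, L, "spearman",
                            spearmanMode = "plugin")
    expect_true(all(analyticPvalue(zWorst) >= analyticPvalue(zPlug) - 1e-15))
    # strict whenever either correlation is away from the |r| = 1 boundary
    strict <- abs(rA) < 0.999 & abs(rB) < 0.999 & abs(zWorst) > 1e-8
    expect_true(all(analyticPvalue(zWorst)[strict] >
                    analyticPvalue(zPlug)[strict]))
})

test_that("mean |z| grows with the simulated correlation difference", {
    deltas <- c(0, 0.3, 0.6, 0.9)
    meanAbs <- vapply(seq_along(deltas), function(i) {
        d <- deltas[i]
        ds <- makePairedExperiment(150, 50, 50, rhoA = d / 2, rhoB = -d / 2,
                                   seed = 60 + i)
        mean(abs(runZtest(ds$experiment, ds$network)$statistic))
    }, numeric(1))
    expect_true(all(diff(meanAbs) > 0))
})
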