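# Fixture builders shared across the test files.  Everything is generated in
# code; no data files.

# small experiment with iid normal expression
makeExperiment <- function(nGenes = 5L, nPerGroup = 20L, seed = 1L,
                           labels = c("Normal", "Tumor")) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * 2L * nPerGroup), nrow = nGenes,
                dimnames = list(sprintf("g%d", seq_len(nGenes)),
                                sprintf("s%d", seq_len(2L * nPerGroup))))
    CoexExperiment(m, rep(labels, each = nPerGroup))
}

# experiment of `nPairs` independent gene pairs; pair i has correlation
# rhoA[i] in group A and rhoB[i] in group B
makePairedExperiment <- function(nPairs, K, L, rhoA, rhoB, seed = 1L) {
    rhoA <- rep_len(rhoA, nPairs)
    rhoB <- rep_len(rhoB, nPairs)
    set.seed(seed)
    drawPair <- function(n, rho) {
        a <- rnorm(n)
        rbind(a, rho * a + sqrt(1 - rho^2) * rnorm(n))
    }
    m <- matrix(NA_real_, nrow = 2L * nPairs, ncol = K + L)
    for (i in seq_len(nPairs)) {
        rows <- c(2L * i - 1L, 2L * i)
        m[rows, seq_len(K)] <- drawPair(K, rhoA[i])
        m[rows, K + seq_len(L)] <- drawPair(L, rhoB[i])
    }
    dimnames(m) <- list(sprintf("g%d", seq_len(2L * nPairs)),
                        sprintf("s%d", seq_len(K + L)))
    list(experiment = CoexExperiment(m, rep(c("Normal", "Tumor"), c(K, L))),
         network = InteractionNetwork(
             sprintf("g%d", 2L * seq_len(nPairs) - 1L),
             sprintf("g%d", 2L * seq_len(nPairs))))
}

# independent step-up BH oracle (naive loop, no p.adjust)
bhOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    sorted <- p[ord]
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
    out <- numeric(m)
    out[ord] <- adj
    out
}

# hypergeometric upper tail P(X >= s) by direct enumeration with choose()
hypergeomOracle <- function(s, nG, S, N) {
    xs <- s:min(nG, S)
    sum(choose(S, xs) * choose(N - S, nG - xs)) / choose(N, nG)
}
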