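# Shared objects built once per test run: the default region model and a
# reference panel at the default simulation depth.
.model <- defaultRegionModel()
.panel <- simulatePanel(.model, n = 50, meanDepth = 1000, seed = 424242)
.ref <- buildReference(.panel)

grInterval <- function(start1, end1, chrom = "chr22") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
}

# Independent Wilcoxon oracle: null distribution of the rank-sum via
# dynamic programming over subset sums of the pooled midranks (scaled to
# integers), not via combn as the implementation's exact path uses.
oracleWilcoxonP <- function(x, y) {
    nx <- length(x)
    pooled <- c(x, y)
    rk2 <- as.integer(round(2 * rank(pooled)))  # midranks doubled: integers
    wObs <- sum(rk2[seq_len(nx)])
    # counts[k+1, s+1] = number of size-k subsets with doubled-rank sum s
    maxS <- sum(sort(rk2, decreasing = TRUE)[seq_len(nx)])
    counts <- matrix(0, nrow = nx + 1L, ncol = maxS + 1L)
    counts[1L, 1L] <- 1
    for (r in rk2) {
        for (k in nx:1) {
            idx <- seq_len(maxS + 1L - r)
            counts[k + 1L, idx + r] <-
                counts[k + 1L, idx + r] + counts[k, idx]
        }
    }
    dist <- counts[nx + 1L, ]
    tot <- sum(dist)
    pLess <- sum(dist[seq_len(wObs + 1L)]) / tot
    pMore <- sum(dist[seq(wObs + 1L, maxS + 1L)]) / tot
    min(1, 2 * min(pLess, pMore))
}

# Independent Fisher oracle: two-sided p by direct hypergeometric
# enumeration.
oracleFisherP <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    lo <- max(0L, k - n2); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n2, k)
    pObs <- stats::dhyper(a, m, n2, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
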