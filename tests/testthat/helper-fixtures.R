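# Shared fixtures and independent oracles for the test suite. The standard
# benchmark pipeline run is expensive (~1 min), so it is computed once per
# session and cached.

.fixtureCache <- new.env(parent = emptyenv())

# standard benchmark: 168 samples, 3000 genes, 8 planted modules (100-400),
# loading 0.8, noise sd 0.6, 2 planted outlier samples, beta from the
# scale-free criterion
benchmarkRun <- function() {
    if (is.null(.fixtureCache$bench)) {
        cfg <- syntheticConfig(seed = 1)
        el <- system.time(
            res <- suppressWarnings(
                runPipeline(cfg, outDir = file.path(tempdir(), "benchrun"))))
        res$elapsed <- el[["elapsed"]]
        .fixtureCache$bench <- res
    }
    .fixtureCache$bench
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent oracle: literal step-up construction of BH q-values
bruteForceBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
        pi <- p[o[i]]
        cand <- vapply(seq_len(n), function(j) {
            pj <- sort(p)[j]
            if (pj >= pi) min(1, n * pj / j) else Inf
        }, numeric(1))
        q[o[i]] <- min(cand)
    }
    q
}

# independent oracle: exhaustive-sum upper-tail hypergeometric probability
bruteForceHyper <- function(N, K, n, k) {
    jmax <- min(K, n)
    if (k > jmax) return(0)
    js <- k:jmax
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small two-genotype single-region dataset from raw vectors
twoGroupDataset <- function(g1, g2, nGenes = 1, region = "PFC") {
    x <- rbind(matrix(c(g1, g2), nGenes, length(g1) + length(g2), byrow = TRUE))
    rownames(x) <- paste0("g", seq_len(nGenes))
    colnames(x) <- paste0("s", seq_len(ncol(x)))
    RegionExpressionSet(x, genotype = rep(c("selected", "control"),
                                          c(length(g1), length(g2))),
                        region = rep(region, ncol(x)))
}

# hand-made ground truth (module labels + cell-type tags) without expression
syntheticTruth <- function(moduleSizes, cellTypes, nBackground, seed = 1) {
    set.seed(seed)
    nGenes <- sum(moduleSizes) + nBackground
    ids <- sprintf("g%05d", seq_len(nGenes))
    mod <- rep(c(names(moduleSizes), "background"),
               c(moduleSizes, nBackground))
    ct <- rep(c(cellTypes, NA_character_), c(moduleSizes, nBackground))
    list(geneModule = setNames(mod, ids), cellType = setNames(ct, ids))
}
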