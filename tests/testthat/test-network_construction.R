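# Signed network construction: similarity/adjacency arithmetic, scale-free
# selection, TOM, module detection, eigengenes, connectivity, hub modules.

.blockExpr <- function(blocks, nSamples, loading = 0.95, noise = 0.1,
                       seed = 1) {
    set.seed(seed)
    x <- do.call(rbind, lapply(seq_along(blocks), function(i) {
        f <- rnorm(nSamples)
        matrix(loading * rep(f, each = blocks[i]), blocks[i], nSamples) +
            matrix(rnorm(blocks[i] * nSamples, sd = noise), blocks[i])
    }))
    rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%03d", seq_len(ncol(x)))
    x
}

test_that("signed adjacency maps correlation through (1+cor)/2 then powers", {
    s <- seq(0, 1, length.out = 10)
    x <- rbind(a = s, b = s, c = 1 - s, d = rep(c(0, 1), 5))
    colnames(x) <- paste0("smp", 1:10)
    net <- signedAdjacency(x, beta = 12)
    S <- similarityMatrix(net); A <- adjacencyMatrix(net)
    expect_equal(S["a", "b"], 1)
    expect_equal(A["a", "b"], 1)
    expect_equal(S["a", "c"], 0)
    expect_equal(A["a", "c"], 0)
    # exactly uncorrelated pair: a = 0.5^12
    y <- rbind(p = c(1, 1, -1, -1), q = c(1, -1, 1, -1))
    colnames(y) <- paste0("smp", 1:4)
    net2 <- signedAdjacency(y, beta = 12)
    expect_equal(adjacencyMatrix(net2)["p", "q"], 0.5^12)
    # zero-variance gene: S = 0.5 with warning
    z <- rbind(a = s, flat = rep(1, 10))
    colnames(z) <- paste0("smp", 1:10)
    w <- capture_warnings(net3 <- signedAdjacency(z, beta = 2))
    expect_true(any(grepl("zero-variance", w)))
    expect_equal(similarityMatrix(net3)["a", "flat"], 0.5)
})

test_that("raising beta never increases off-diagonal adjacency below S = 1", {
    set.seed(3)
    x <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
    a6 <- adjacencyMatrix(signedAdjacency(x, 6))
    a12 <- adjacencyMatrix(signedAdjacency(x, 12))
    off <- upper.tri(a6)
    expect_true(all(a12[off] <= a6[off] + 1e-12))
})

test_that("scale-free fit index rewards planted power-law degree sequences", {
    set.seed(4)
    k <- (1 - runif(5000))^(-1 / 1.5)          # Pareto tail, alpha ~ 2.5
    k <- k[k < 50]
    expect_gt(suppressWarnings(scaleFreeFitIndex(k))$fit, 0.9)
    # increasing degree distributions score negatively
    expect_lt(suppressWarnings(scaleFreeFitIndex(rep(1:10, 1:10)))$fit, 0)
    expect_error(scaleFreeFitIndex(rep(2, 100)), "constant")
})

test_that("pickSoftThreshold honors its contract", {
    set.seed(5)
    x <- .blockExpr(c(40, 40, 40), 60, loading = 0.8, noise = 0.6)
    S <- (1 + cor(t(x))) / 2
    one <- suppressWarnings(pickSoftThreshold(S, candidateBetas = 12))
    expect_equal(one$beta, 12)
    high <- suppressWarnings(pickSoftThreshold(S, candidateBetas = c(2, 4),
                                               targetR2 = 0.999))
    expect_false(high$reachedTarget)
    expect_true(high$beta %in% c(2, 4))
    expect_error(pickSoftThreshold(S, numeric(0)), "non-empty")
})

test_that("TOM reproduces hand-computed cases and stays bounded", {
    # 3-node clique: TOM = (1 + 1) / (2 + 1 - 1) = 1
    A <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    expect_true(all(abs(topologicalOverlap(A) - 1) < 1e-12))
    # no edges: off-diagonal TOM = 0
    I <- diag(4); dimnames(I) <- list(letters[1:4], letters[1:4])
    tomI <- topologicalOverlap(I)
    expect_true(all(tomI[upper.tri(tomI)] == 0))
    # random adjacency: symmetric, [0, 1], unit diagonal
    set.seed(6)
    R <- matrix(runif(100), 10, 10); R <- (R + t(R)) / 2; diag(R) <- 1
    dimnames(R) <- list(paste0("g", 1:10), paste0("g", 1:10))
    tom <- topologicalOverlap(R)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(all(diag(tom) == 1))
    R2 <- R; R2[1, 2] <- 0.9;
    expect_error(topologicalOverlap(R2), "symmetric")
})

test_that("module detection recovers perfect blocks with no grey left over", {
    x <- .blockExpr(c(100, 100), 60)
    net <- computeTOM(signedAdjacency(x, 12))
    net <- detectModules(net, minModuleSize = 80, cutHeight = 0.995,
                         deepSplit = TRUE)
    labels <- moduleLabels(net)
    expect_equal(sort(unique(labels)), c("blue", "turquoise"))
    expect_equal(length(unique(labels[1:100])), 1)
    expect_equal(length(unique(labels[101:200])), 1)
})

test_that("blocks below the minimum module size become grey", {
    # realistic block strength: loading 0.8, noise 0.6
    x <- rbind(.blockExpr(50, 60, loading = 0.8, noise = 0.6, seed = 7),
               matrix(rnorm(150 * 60), 150, 60))
    rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%03d", seq_len(ncol(x)))
    net <- detectModules(computeTOM(signedAdjacency(x, 12)),
                         minModuleSize = 80)
    expect_true(all(moduleLabels(net)[1:50] == "grey"))
    # pure noise: at least 90% grey
    set.seed(8)
    noise <- matrix(rnorm(300 * 60), 300, 60,
                    dimnames = list(sprintf("n%03d", 1:300),
                                    sprintf("s%03d", 1:60)))
    netN <- detectModules(computeTOM(signedAdjacency(noise, 12)),
                          minModuleSize = 80)
    expect_gte(mean(moduleLabels(netN) == "grey"), 0.9)
    # min size above the gene count: everything grey, with a warning
    expect_warning(all_grey <- detectModules(
        computeTOM(signedAdjacency(noise[1:40, ], 12)), minModuleSize = 80),
        "grey")
    expect_true(all(moduleLabels(all_grey) == "grey"))
})

test_that("module detection is deterministic", {
    x <- .blockExpr(c(90, 90, 90), 50, seed = 9)
    n1 <- detectModules(computeTOM(signedAdjacency(x, 12)))
    n2 <- detectModules(computeTOM(signedAdjacency(x, 12)))
    expect_identical(moduleLabels(n1), moduleLabels(n2))
})

test_that("eigengenes summarize modules and respect the sign convention", {
    # identical profiles: variance explained 1, eigengene = standardized x
    x <- matrix(rep(c(1, 3, 2, 5), each = 5), 5, 4, byrow = FALSE,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    labels <- setNames(rep("turquoise", 5), rownames(x))
    prof <- moduleEigengenes(x, labels)
    expect_equal(unname(varianceExplained(prof)), 1)
    eg <- eigengenes(prof)["turquoise", ]
    expect_gt(cor(eg, c(1, 3, 2, 5)), 0.999)
    expect_equal(sum(eg^2), 1)
    # latent-factor module: eigengene tracks the factor closely
    set.seed(10)
    f <- rnorm(100)
    xm <- matrix(0.8 * rep(f, each = 60), 60, 100) +
        matrix(rnorm(6000, sd = 0.6), 60, 100)
    dimnames(xm) <- list(paste0("g", 1:60), paste0("s", 1:100))
    pf <- moduleEigengenes(xm, setNames(rep("blue", 60), rownames(xm)))
    expect_gt(abs(cor(eigengenes(pf)["blue", ], f)), 0.9)
    expect_gte(cor(eigengenes(pf)["blue", ], colMeans(xm)), 0)
})

test_that("intramodular connectivity and hub selection follow the tie rule", {
    A <- matrix(0.5, 5, 5); diag(A) <- 1
    ids <- c("gB", "gA", "gC", "gD", "gE")
    dimnames(A) <- list(ids, ids)
    labels <- setNames(rep("turquoise", 5), ids)
    ic <- intramodularConnectivity(A, labels, topFraction = 0.2)
    expect_true(all(ic$kIn == 2))
    expect_identical(ic$hubs$turquoise, "gA")   # ceil(1) hub, lexicographic
    # fraction 0.2 of 10 genes -> 2 hubs; isolated gene has kIn 0
    B <- diag(10); dimnames(B) <- list(paste0("g", 1:10), paste0("g", 1:10))
    icB <- intramodularConnectivity(B, setNames(rep("m", 10), rownames(B)),
                                    0.2)
    expect_true(all(icB$kIn == 0))
    expect_length(icB$hubs$m, 2)
})

test_that("hub-module scores single out a planted bridge and normalize by size", {
    # two disconnected modules: both scores zero
    A <- matrix(0, 40, 40)
    A[1:20, 1:20] <- 0.9; A[21:40, 21:40] <- runif(400, 0.5, 0.9)
    A <- (A + t(A)) / 2; diag(A) <- 1
    dimnames(A) <- list(paste0("g", 1:40), paste0("g", 1:40))
    labels <- setNames(rep(c("blue", "red"), each = 20), rownames(A))
    sc <- hubModuleScores(A, labels, density = 0.3)
    expect_true(all(sc$scoreAll == 0))
    # bridge block correlated with both others takes the top score
    set.seed(11)
    n <- 30
    blocks <- list(b1 = 1:n, b2 = n + 1:n, bridge = 2 * n + 1:n)
    B <- matrix(0.02, 3 * n, 3 * n)
    B[blocks$b1, blocks$b1] <- 0.6; B[blocks$b2, blocks$b2] <- 0.6
    B[blocks$bridge, blocks$bridge] <- 0.6
    B[blocks$bridge, blocks$b1] <- 0.3; B[blocks$b1, blocks$bridge] <- 0.3
    B[blocks$bridge, blocks$b2] <- 0.3; B[blocks$b2, blocks$bridge] <- 0.3
    B <- B + matrix(runif(9 * n * n, 0, 0.01), 3 * n)
    B <- (B + t(B)) / 2; diag(B) <- 1
    dimnames(B) <- list(paste0("g", 1:(3 * n)), paste0("g", 1:(3 * n)))
    lb <- setNames(rep(c("blue", "red", "tan"), each = n), rownames(B))
    scB <- hubModuleScores(B, lb, density = 0.5)
    expect_equal(scB$module[scB$hubModule], "tan")
    # duplicating a module's genes leaves its per-size score unchanged
    expect_error(hubModuleScores(matrix(1, 4, 4,
        dimnames = list(paste0("g", 1:4), paste0("g", 1:4))),
        setNames(rep(c("a", "b"), 2), paste0("g", 1:4))), "degenerate")
})
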