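# Moderated t: hyperparameter estimation, limits, calibration; chi-square
# excess-DEG test; BH step-up; K-means of t profiles.

test_that("identical group means give t = 0 and p = 1", {
    ds <- twoGroupDataset(c(1, 2, 3), c(3, 2, 1))
    tab <- moderatedTTest(ds, "PFC", priorDf = 0)
    expect_equal(tab$moderatedT, 0)
    expect_equal(tab$rawP, 1)
})

test_that("prior df forced to 0 reproduces the closed-form pooled t", {
    ds <- twoGroupDataset(c(1, 2, 3), c(4, 5, 6))
    tab <- moderatedTTest(ds, "PFC", priorDf = 0)
    expect_equal(tab$moderatedT, -3.674, tolerance = 1e-3)
    expect_equal(tab$df, 4)
    expect_equal(tab$rawP, 0.0213, tolerance = 1e-3)
    expect_equal(tab$delta, -3)
    expect_equal(tab$foldChange, -8)
})

test_that("hyperparameter fit matches the independent empirical-Bayes oracle", {
    set.seed(7)
    n <- 2000
    s2true <- 0.25 / rchisq(n, df = 8) * 8   # genes share a variance prior
    x <- matrix(rnorm(n * 12, sd = rep(sqrt(s2true), 12)), n, 12)
    rownames(x) <- paste0("g", 1:n); colnames(x) <- paste0("s", 1:12)
    ds <- RegionExpressionSet(x, genotype = rep(c("selected", "control"),
                                                each = 6),
                              region = rep("PFC", 12))
    tab <- moderatedTTest(ds, "PFC")
    v1 <- apply(x[, 1:6], 1, var); v2 <- apply(x[, 7:12], 1, var)
    s2 <- (v1 + v2) / 2
    sq <- limma::squeezeVar(s2, df = 10)
    expect_equal(attr(tab, "d0"), sq$df.prior, tolerance = 1e-6)
    expect_equal(attr(tab, "s02"), sq$var.prior, tolerance = 1e-6)
})

test_that("shared true variance drives d0 large with near-identical ranking", {
    set.seed(8)
    x <- matrix(rnorm(5000 * 12, sd = 0.5), 5000, 12)
    rownames(x) <- paste0("g", 1:5000); colnames(x) <- paste0("s", 1:12)
    ds <- RegionExpressionSet(x, genotype = rep(c("selected", "control"),
                                                each = 6),
                              region = rep("PFC", 12))
    tab <- moderatedTTest(ds, "PFC")
    expect_gt(attr(tab, "d0"), 100)
    # with near-complete shrinkage the moderated statistic ranks by |delta|,
    # so agreement with the ordinary t is high but not exact
    expect_gt(cor(rank(abs(tab$moderatedT)), rank(abs(tab$ordinaryT))),
              0.95)
})

test_that("a group smaller than 2 is rejected", {
    ds <- twoGroupDataset(c(1), c(4, 5, 6))
    expect_error(moderatedTTest(ds, "PFC"), "at least 2")
})

test_that("excess-DEG chi-square matches hand arithmetic", {
    exact <- degsVsChance(500, 10000, 0.05)
    expect_equal(exact$statistic, 0)
    expect_equal(exact$p, 1)
    big <- degsVsChance(1000, 10000, 0.05)
    expect_equal(big$statistic, 526.32, tolerance = 1e-2)
    expect_lt(big$p, 1e-100)
    none <- degsVsChance(0, 1000, 0.05)
    expect_equal(none$statistic, 52.63, tolerance = 1e-2)
    expect_error(degsVsChance(5, 0), "positive")
    expect_error(degsVsChance(11, 10), "exceed")
})

test_that("BH q-values follow the step-up construction exactly", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.37), 0.37)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    set.seed(9)
    for (n in c(7, 63, 500)) {
        p <- runif(n)
        expect_equal(bhFDR(p), bruteForceBH(p))
    }
    expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("K-means on t profiles separates planted blobs and keeps duplicates together", {
    set.seed(10)
    tm <- rbind(matrix(rnorm(50 * 7, mean = 5), 50, 7),
                matrix(rnorm(50 * 7, mean = -5), 50, 7))
    rownames(tm) <- paste0("g", 1:100)
    cl <- clusterTValues(tm, pMatrix = NULL, k = 2, seed = 0)
    expect_equal(length(unique(cl$labels[1:50])), 1)
    expect_equal(length(unique(cl$labels[51:100])), 1)
    expect_false(cl$labels[1] == cl$labels[100])
    one <- clusterTValues(tm, pMatrix = NULL, k = 1, seed = 0)
    expect_equal(length(unique(one$labels)), 1)
    dup <- tm; dup[2, ] <- dup[1, ]
    cl2 <- clusterTValues(dup, pMatrix = NULL, k = 2, seed = 0)
    expect_equal(unname(cl2$labels[1]), unname(cl2$labels[2]))
    expect_error(clusterTValues(tm[1:3, ], pMatrix = NULL, k = 5), "fewer rows")
})

test_that("the p < 0.001 filter restricts clustering to top significant genes", {
    tm <- matrix(rnorm(40 * 3), 40, 3,
                 dimnames = list(paste0("g", 1:40), c("A", "B", "C")))
    pm <- matrix(0.5, 40, 3, dimnames = dimnames(tm))
    pm[1:10, 1] <- 1e-5
    cl <- clusterTValues(tm, pm, k = 2, pCut = 0.001, seed = 1)
    expect_setequal(cl$genes, paste0("g", 1:10))
})

test_that("fold-change convention: |FC| = 2^|delta|, null genes near +-1", {
    set.seed(11)
    x <- matrix(rnorm(200 * 24, sd = 0.3), 200, 24)
    rownames(x) <- paste0("g", 1:200); colnames(x) <- paste0("s", 1:24)
    ds <- RegionExpressionSet(x, genotype = rep(c("selected", "control"),
                                                each = 12),
                              region = rep("PFC", 24))
    tab <- moderatedTTest(ds, "PFC")
    expect_equal(abs(tab$foldChange), 2^abs(tab$delta))
    expect_equal(sign(tab$foldChange), sign(tab$delta))
    # |FC| = 2^|delta| >= 1 by construction; null genes sit just above 1
    expect_gte(min(abs(tab$foldChange)), 1)
    expect_lt(median(abs(tab$foldChange)), 1.15)
})

test_that("masked values adjust per-gene df in the moderated test", {
    set.seed(12)
    x <- matrix(rnorm(50 * 24), 50, 24)
    rownames(x) <- paste0("g", 1:50); colnames(x) <- paste0("s", 1:24)
    x[1, 1:4] <- NA
    ds <- RegionExpressionSet(x, genotype = rep(c("selected", "control"),
                                                each = 12),
                              region = rep("PFC", 24))
    tab <- moderatedTTest(ds, "PFC", priorDf = 0)
    expect_equal(tab$df[1], 8 + 12 - 2)
    expect_equal(tab$df[2], 22)
})
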