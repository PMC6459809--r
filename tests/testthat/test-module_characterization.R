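# Enrichment machinery: hypergeometric oracle equivalence, DEG
# over-representation, cell-type assignment, eigengene ANOVA.

test_that("hypergeometric p matches the exhaustive-sum oracle", {
    universe <- sprintf("g%03d", 1:100)
    module <- universe[1:10]
    query <- universe[6:25]
    ht <- hyperGeoTest(module, query, universe)
    expect_equal(ht$k, 5)
    expect_equal(ht$p, bruteForceHyper(100, 20, 10, 5), tolerance = 1e-12)
    # query = universe -> k = n, p = 1; empty query -> k = 0, p = 1
    full <- hyperGeoTest(module, universe, universe)
    expect_equal(full$k, 10); expect_equal(full$p, 1)
    none <- hyperGeoTest(module, character(0), universe)
    expect_equal(none$k, 0); expect_equal(none$p, 1)
    expect_error(hyperGeoTest(c(module, "zzz"), query, universe), "zzz")
})

test_that("no DEGs anywhere means no module is flagged", {
    truth <- syntheticTruth(c(m1 = 30, m2 = 30), c(NA, NA), 40)
    labels <- truth$geneModule
    labels[labels == "background"] <- "grey"
    universe <- names(labels)
    degs <- list(PFC.up = character(0), PFC.down = character(0))
    sr <- selectionResponsiveModules(labels, degs, universe)
    expect_false(any(sr$flags))
    expect_error(selectionResponsiveModules(labels, degs, character(0)),
                 "empty universe")
})

test_that("a module whose genes carry a planted effect is flagged", {
    truth <- syntheticTruth(c(m1 = 50, m2 = 50), c(NA, NA), 100, seed = 2)
    labels <- truth$geneModule
    labels[labels == "background"] <- "grey"
    universe <- names(labels)
    m1 <- names(labels)[labels == "m1"]
    # DEG list = the planted module plus background at the null rate
    set.seed(2)
    degUp <- c(m1, sample(setdiff(universe, m1), 8))
    sr <- selectionResponsiveModules(labels,
                                     list(BLA.up = degUp,
                                          BLA.down = character(0)),
                                     universe)
    expect_true(sr$flags[["m1"]])
    expect_false(sr$flags[["m2"]])
})

test_that("BH correction spans the whole module x set family at once", {
    truth <- syntheticTruth(c(a = 20, b = 20, c = 20), rep(NA, 3), 40,
                            seed = 3)
    labels <- truth$geneModule
    labels[labels == "background"] <- "grey"
    universe <- names(labels)
    set.seed(3)
    sets <- list(s1 = sample(universe, 25), s2 = sample(universe, 25))
    tab <- geneSetEnrichment(labels, sets, universe)
    expect_equal(tab$q, p.adjust(tab$p, "BH"))
    expect_equal(nrow(tab), 3 * 2)
})

test_that("null calibration: random labels rarely flag", {
    set.seed(4)
    flagged <- 0; total <- 0
    for (rep in 1:20) {
        ids <- sprintf("r%04d", 1:400)
        labels <- setNames(sample(rep(c("a", "b", "c", "d"), each = 100)), ids)
        degs <- list(up = sample(ids, 40), down = sample(ids, 40))
        sr <- selectionResponsiveModules(labels, degs, ids)
        flagged <- flagged + sum(sr$flags); total <- total + length(sr$flags)
    }
    expect_lte(flagged / total, 0.05)
})

test_that("marker enrichment assigns cell types without cross-assignment", {
    truth <- syntheticTruth(c(m1 = 60, m2 = 60), c("neuron", "astrocyte"),
                            200, seed = 5)
    labels <- truth$geneModule
    labels[labels == "background"] <- "grey"
    universe <- names(labels)
    set.seed(5)
    markers <- generateMarkerSets(truth, contamination = 0.2, nDecoys = 2)
    ct <- cellTypeAssignment(labels, markers, universe)
    expect_identical(ct$assignments$m1, "markers_neuron")
    expect_identical(ct$assignments$m2, "markers_astrocyte")
    expect_true(all(ct$flags[c("m1", "m2")]))
    # marker set identical to the module -> assigned with minimal p
    pure <- list(markers_x = names(labels)[labels == "m1"])
    ctp <- cellTypeAssignment(labels, pure, universe)
    expect_true("markers_x" %in% ctp$assignments$m1)
    # disjoint marker set -> unassigned
    disj <- list(markers_y = names(labels)[labels == "grey"][1:30])
    expect_length(cellTypeAssignment(labels, disj, universe)$assignments$m1, 0)
    # out-of-universe markers dropped with a warning
    expect_warning(cellTypeAssignment(labels,
                                      list(m = c(pure$markers_x, "nope")),
                                      universe),
                   "dropped")
})

test_that("eigengene region ANOVA flags planted region structure only", {
    region <- rep(c("A", "B", "C"), each = 10)
    eg <- rbind(flat = rep(0.1, 30),
                toy = rep(c(1, 2, 3), 10),
                shifted = c(rnorm(10, 2), rnorm(20)))
    prof <- methods::new("ModuleProfiles", eigengenes = eg,
                         varExplained = setNames(rep(1, 3), rownames(eg)),
                         labels = character())
    set.seed(6)
    av <- eigengeneRegionAnova(prof, region)
    expect_equal(av$F[av$module == "flat"], 0)
    expect_equal(av$p[av$module == "flat"], 1)
    expect_true(av$regionDependent[av$module == "shifted"])
    # balanced two-region toy with identical group profiles: F = 0, p = 1
    prof2 <- methods::new("ModuleProfiles",
                          eigengenes = matrix(c(1, 2, 3, 1, 2, 3), 1,
                                              dimnames = list("m", NULL)),
                          varExplained = c(m = 1), labels = character())
    av2 <- eigengeneRegionAnova(prof2, rep(c("A", "B"), each = 3))
    expect_equal(av2$F, 0, tolerance = 1e-12)
    expect_equal(av2$p, 1, tolerance = 1e-12)
    expect_error(eigengeneRegionAnova(prof, rep("A", 30)), "2 regions")
})

test_that("a planted region shift of 2 sd is detected in most replicates", {
    # study-scale eigengene: 7 regions x 24 samples, one region moved 2 sd
    set.seed(7)
    hits <- 0
    for (r in 1:40) {
        y <- rnorm(168)
        y[1:24] <- y[1:24] + 2
        prof <- methods::new("ModuleProfiles",
                             eigengenes = matrix(y, 1,
                                                 dimnames = list("m", NULL)),
                             varExplained = c(m = 1), labels = character())
        av <- eigengeneRegionAnova(prof, rep(studyRegions(), each = 24))
        hits <- hits + (av$p < 0.05)
    }
    expect_gte(hits / 40, 0.95)
})

test_that("gene-set enrichment handles degenerate collections", {
    truth <- syntheticTruth(c(m1 = 30), NA_character_, 70, seed = 8)
    labels <- truth$geneModule
    labels[labels == "background"] <- "grey"
    universe <- names(labels)
    whole <- geneSetEnrichment(labels, list(all = universe), universe)
    expect_equal(whole$p, 1)
    empty <- geneSetEnrichment(labels, list(), universe)
    expect_equal(nrow(empty), 0)
    # a set overlapping the module at 50% comes out significant
    set.seed(8)
    m1 <- names(labels)[labels == "m1"]
    lps <- c(m1[1:15], sample(setdiff(universe, m1), 15))
    sig <- geneSetEnrichment(labels, list(lps_like = lps), universe)
    expect_true(sig$significant)
    expect_equal(sig$p, bruteForceHyper(100, 30, 30, 15), tolerance = 1e-12)
})
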