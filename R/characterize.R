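# Module characterization: hypergeometric over-representation of DEG lists
# (selection-responsiveness), cell-type marker enrichment, eigengene region
# ANOVA, and generic gene-set enrichment. All enrichment p-values share one
# upper-tail hypergeometric core; BH correction is applied once per analysis
# family (all module x set tests jointly).

#' Upper-tail hypergeometric over-representation test
#'
#' With universe size N, query size K, module size n and overlap k, returns
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (the observed overlap is
#' included in the tail). Both gene sets must be subsets of the universe.
#'
#' @param moduleGenes character vector of module member ids.
#' @param queryGenes character vector of query set ids.
#' @param universe character vector, the reference gene population.
#' @return list with N, n, K, k and `p`.
#' @export
hyperGeoTest <- function(moduleGenes, queryGenes, universe) {
    moduleGenes <- unique(moduleGenes)
    queryGenes <- unique(queryGenes)
    bad <- setdiff(c(moduleGenes, queryGenes), universe)
    if (length(bad))
        stop("genes outside the universe: ",
             paste(utils::head(bad, 5), collapse = ", "),
             if (length(bad) > 5) " ..." else "")
    N <- length(unique(universe))
    n <- length(moduleGenes)
    K <- length(queryGenes)
    k <- length(intersect(moduleGenes, queryGenes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(N = N, n = n, K = K, k = k, p = p)
}

# shared machinery: test every module against every set, BH across the family
.enrichmentTable <- function(labels, sets, universe, includeGrey = FALSE) {
    mods <- sort(unique(labels))
    if (!includeGrey) mods <- setdiff(mods, "grey")
    rows <- list()
    for (m in mods) {
        member <- intersect(names(labels)[labels == m], universe)
        for (s in names(sets)) {
            qry <- intersect(unique(sets[[s]]), universe)
            ht <- hyperGeoTest(member, qry, universe)
            rows[[length(rows) + 1]] <- data.frame(
                module = m, set = s, N = ht$N, n = ht$n, K = ht$K, k = ht$k,
                p = ht$p)
        }
    }
    tab <- do.call(rbind, rows)
    tab$q <- if (nrow(tab)) bhFDR(tab$p) else numeric(0)
    rownames(tab) <- NULL
    tab
}

#' Selection-responsive modules via DEG over-representation
#'
#' Tests every module against every per-region, per-direction DEG list with
#' the hypergeometric test, corrects across all module x list tests jointly
#' (BH), and flags a module as selection-responsive when any q < `qCut`.
#'
#' @param labels named module labels per gene.
#' @param degs named list of DEG id vectors, e.g. from [degLists()]; list
#'   names should encode region and direction ("BLA.up").
#' @param universe reference population (conventionally the network genes).
#' @param qCut FDR threshold.
#' @param includeGrey include the unassigned genes as a pseudo-module.
#' @return list with `table` (all tests) and `flags` (named logical per
#'   module).
#' @export
selectionResponsiveModules <- function(labels, degs, universe, qCut = 0.05,
                                       includeGrey = FALSE) {
    if (!length(universe)) stop("empty universe")
    degs <- lapply(degs, intersect, y = universe)
    tab <- .enrichmentTable(labels, degs, universe, includeGrey)
    flags <- tapply(tab$q < qCut, tab$module, any)
    list(table = tab, flags = stats::setNames(as.logical(flags), names(flags)))
}

#' Cell-type assignment by marker enrichment
#'
#' Hypergeometric tests of every module against every marker collection with
#' joint BH correction; a module is assigned the cell type(s) with q < `qCut`
#' and flagged cell-type-specific when it has at least one assignment. Marker
#' genes absent from the universe are dropped (with a count warning).
#'
#' @param labels named module labels.
#' @param markers named list of marker gene sets (set names identify the cell
#'   type, e.g. "markers_neuron").
#' @param universe reference population.
#' @param qCut FDR threshold.
#' @return list with `table`, `assignments` (per-module character vector of
#'   assigned set names), and `flags` (cell-type-specific logical).
#' @export
cellTypeAssignment <- function(labels, markers, universe, qCut = 0.05) {
    dropped <- sum(vapply(markers, function(s) sum(!(unique(s) %in% universe)),
                          numeric(1)))
    if (dropped > 0)
        warning(dropped, " marker genes absent from the universe were dropped")
    markers <- lapply(markers, intersect, y = universe)
    tab <- .enrichmentTable(labels, markers, universe)
    sig <- tab[tab$q < qCut, , drop = FALSE]
    mods <- sort(unique(tab$module))
    assignments <- lapply(stats::setNames(mods, mods),
                          function(m) sig$set[sig$module == m])
    flags <- vapply(assignments, function(a) length(a) > 0, logical(1))
    list(table = tab, assignments = assignments, flags = flags)
}

#' One-way ANOVA of module eigengenes across brain regions
#'
#' Fixed-effects one-way ANOVA of each eigengene grouped by region; a module
#' is region-dependent at p < `alpha`. A constant eigengene yields F = 0,
#' p = 1 by convention.
#'
#' @param profiles a [ModuleProfiles-class] object.
#' @param region character vector of region labels, one per sample column.
#' @param alpha significance level for the region-dependence flag.
#' @return data.frame: module, F, p, regionDependent.
#' @export
eigengeneRegionAnova <- function(profiles, region, alpha = 0.05) {
    eg <- eigengenes(profiles)
    region <- as.factor(region)
    if (nlevels(region) < 2) stop("need at least 2 regions")
    res <- data.frame(module = rownames(eg), F = NA_real_, p = NA_real_)
    for (i in seq_len(nrow(eg))) {
        y <- eg[i, ]
        if (stats::sd(y) < .Machine$double.eps^0.5) {
            res$F[i] <- 0; res$p[i] <- 1
            next
        }
        a <- stats::anova(stats::lm(y ~ region))
        res$F[i] <- a$`F value`[1]
        res$p[i] <- a$`Pr(>F)`[1]
        if (!is.finite(res$p[i])) { res$F[i] <- 0; res$p[i] <- 1 }
    }
    res$regionDependent <- res$p < alpha
    res
}

#' Generic gene-set enrichment for modules
#'
#' The same hypergeometric + BH machinery over an arbitrary GMT-style
#' collection (functional categories, pathway response signatures, ...).
#'
#' @param labels named module labels.
#' @param collection named list of gene sets.
#' @param universe reference population.
#' @param qCut FDR threshold for the significance flag.
#' @return data.frame (module, set, N, n, K, k, p, q, significant); empty for
#'   an empty collection.
#' @export
geneSetEnrichment <- function(labels, collection, universe, qCut = 0.05) {
    if (!length(collection))
        return(data.frame(module = character(), set = character(),
                          N = integer(), n = integer(), K = integer(),
                          k = integer(), p = numeric(), q = numeric(),
                          significant = logical()))
    collection <- lapply(collection, intersect, y = universe)
    tab <- .enrichmentTable(labels, collection, universe)
    tab$significant <- tab$q < qCut
    tab
}
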