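# End-to-end pipeline: simulate -> preprocess -> differential expression ->
# network -> module characterization -> cross-species comparison -> circuit
# hypotheses, writing every interchange file along the way.

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a cross-species pair of datasets from `cfg`, preprocesses the
#' first (normalization, sample outliers, detection filter, Grubbs masking),
#' runs per-region moderated-t differential expression with the excess-DEG
#' chi-square and t-profile K-means, builds the signed coexpression network
#' (soft power chosen by the scale-free criterion unless given), detects and
#' characterizes modules (eigengenes, connectivity/hubs, hub-module scores,
#' DEG over-representation, cell-type assignment, region ANOVA, gene-set
#' enrichment), compares modules against the partner dataset's labeling
#' through the ortholog map, prioritizes modules by the four conservation
#' criteria, and emits ranked circuit hypotheses against the anatomical
#' connectivity table. All outputs are written under `outDir` as plain-text
#' TSV/GMT/JSON/GraphML files.
#'
#' @param cfg a [syntheticConfig()]; its seed drives all randomness.
#' @param outDir output directory (created if needed).
#' @param beta soft power; `NULL` selects it by [pickSoftThreshold()].
#' @param candidateBetas candidate powers for the scale-free scan.
#' @param minModuleSize,cutHeight,deepSplit module detection parameters.
#' @param deAlpha DEG threshold (raw p).
#' @param kClusters K-means cluster count for the t-value profiles.
#' @param markerContamination contamination of the generated marker sets.
#' @param dropFraction fraction of genes missing from the ortholog map.
#' @param pThreshold overlap meta-network edge threshold.
#' @param hubDensity edge density defining "connections" for the
#'   hub-module scores.
#' @param edgeExportDensity density of the exported Cytoscape edge list.
#' @param connectivity anatomical connectivity table; default fixture.
#' @return (invisibly) a list with every intermediate result.
#' @export
runPipeline <- function(cfg = syntheticConfig(), outDir = tempfile("coex"),
                        beta = NULL,
                        candidateBetas = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20),
                        minModuleSize = 80, cutHeight = 0.995,
                        deepSplit = TRUE, deAlpha = 0.05, kClusters = 6,
                        markerContamination = 0.2, dropFraction = 0.1,
                        pThreshold = 0.001, hubDensity = 0.25, edgeExportDensity = 0.01,
                        connectivity = defaultConnectivity()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(outDir, ...)

    ## 1. simulate (study dataset + cross-species twin + ortholog map)
    pair <- generateSpeciesPair(cfg, dropFraction = dropFraction)
    simA <- pair$a
    writeExpressionTSV(simA$dataset, p("expression.tsv"))
    writeMetadataTSV(simA$dataset, p("metadata.tsv"))
    writeExpressionTSV(detectionP(simA$dataset), p("detection.tsv"))
    writeTruthJSON(simA$truth, p("truth.json"))
    writeOrthologTSV(pair$orthologs, p("orthologs.tsv"))
    set.seed(cfg$seed + 7919L)
    markers <- generateMarkerSets(simA$truth,
                                  contamination = markerContamination)
    writeGMT(markers, p("markers.gmt"))
    responders <- rownames(simA$truth$effects)[
        rowSums(simA$truth$effects != 0) > 0]
    geneSets <- list(planted_response_signature = responders)
    writeGMT(geneSets, p("gene_sets.gmt"))

    ## 2. preprocess
    pp <- preprocessDataset(simA$dataset)
    ds <- pp$dataset
    writeLines(pp$flaggedSamples, p("flagged_samples.txt"))
    writeExpressionTSV(ds, p("expression_preprocessed.tsv"))

    ## 3. differential expression
    de <- runDifferentialExpression(ds, alpha = deAlpha)
    for (r in names(de$tables))
        write.table(de$tables[[r]], p(paste0("de_", r, ".tsv")), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    writeExpressionTSV(de$tMatrix, p("t_matrix.tsv"))
    write.table(de$degCounts, p("deg_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    tClusters <- tryCatch(
        clusterTValues(de$tMatrix, de$pMatrix, k = kClusters,
                       seed = cfg$seed),
        error = function(e) NULL)
    if (!is.null(tClusters))
        write.table(data.frame(gene = names(tClusters$labels),
                               cluster = tClusters$labels),
                    p("t_clusters.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)

    ## 4. network construction on the cross-region universe
    expr <- exprValues(ds)
    net <- buildNetwork(expr, beta = beta, candidateBetas = candidateBetas,
                        minModuleSize = minModuleSize, cutHeight = cutHeight,
                        deepSplit = deepSplit)
    labels <- moduleLabels(net)
    write.table(data.frame(gene = names(labels), module = labels),
                p("modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeDendrogramJSON(geneDendrogram(net), p("dendrogram.json"))
    A <- adjacencyMatrix(net)
    tau <- stats::quantile(A[upper.tri(A)], 1 - edgeExportDensity, names = FALSE)
    writeEdgeListTSV(A, p("edge_list.tsv"), threshold = tau)

    ## 5. module profiles and characterization
    profiles <- moduleEigengenes(expr, labels)
    writeExpressionTSV(eigengenes(profiles), p("eigengenes.tsv"))
    conn <- intramodularConnectivity(A, labels)
    write.table(data.frame(gene = names(conn$kIn), module = labels,
                           kIn = conn$kIn,
                           hub = unlist(lapply(names(conn$kIn), function(g)
                               labels[g] != "grey" &&
                               g %in% conn$hubs[[labels[g]]]))),
                p("kin.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    hubScores <- hubModuleScores(A, labels, density = hubDensity)
    write.table(hubScores, p("hub_module_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    universe <- names(labels)
    degs <- degLists(de, alpha = deAlpha)
    degs <- lapply(degs, intersect, y = universe)
    sr <- selectionResponsiveModules(labels, degs, universe)
    write.table(sr$table, p("module_deg_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ct <- cellTypeAssignment(labels, markers, universe)
    write.table(ct$table, p("cell_type_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    av <- eigengeneRegionAnova(profiles, sampleRegion(ds))
    write.table(av, p("eigengene_anova.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    gs <- geneSetEnrichment(labels, geneSets, universe)
    write.table(gs, p("gene_set_enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    mods <- setdiff(sort(unique(labels)), "grey")
    neuronSpecific <- vapply(mods, function(m)
        "markers_neuron" %in% ct$assignments[[m]], logical(1))
    flags <- data.frame(module = mods,
                        selectionResponsive = unname(sr$flags[mods]),
                        cellTypeSpecific = unname(ct$flags[mods]),
                        neuronSpecific = unname(neuronSpecific))
    write.table(flags, p("module_flags.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    ## 6. cross-species module conservation
    truthB <- pair$b$truth$geneModule
    labelsB <- ifelse(truthB == "background", "grey", truthB)
    names(labelsB) <- names(truthB)
    overlap <- moduleOverlapNetwork(labels, labelsB, map = pair$orthologs,
                                    pThreshold = pThreshold,
                                    networkNames = c("study", "partner"))
    write.table(overlapEdges(overlap), p("overlap_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bMods <- setdiff(sort(unique(labelsB)), "grey")
    specB <- pair$b$truth$config$moduleSpec
    bEffect <- vapply(specB, function(s) any(s$genotypeEffect != 0), logical(1))
    bTag <- !is.na(vapply(specB, `[[`, character(1), "cellType"))
    partnerFlags <- data.frame(
        module = vapply(specB, `[[`, character(1), "id"),
        diseaseRelated = bEffect, cellTypeSpecific = bTag)
    partnerFlags <- partnerFlags[partnerFlags$module %in% bMods, ]
    writeOverlapGraphML(overlap, p("overlap.graphml"), flagsA = flags,
                        flagsB = partnerFlags)
    prioritized <- prioritizeConservedModules(flags, overlap, partnerFlags)
    write.table(prioritized, p("prioritized_modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## 7. circuit hypotheses
    mrp <- moduleRegionProfiles(sr$table, profiles, sampleRegion(ds),
                                conn$hubs, degs)
    write.table(mrp, p("module_region_profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    hypotheses <- candidateConnections(mrp, connectivity, flags)
    write.table(hypotheses, p("hypotheses.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeRegionGraphML(hypotheses, cfg$regions, p("region_graph.graphml"))

    invisible(list(outDir = outDir, sim = simA, pair = pair, markers = markers,
                   preprocessed = ds, flaggedSamples = pp$flaggedSamples,
                   de = de, tClusters = tClusters, network = net,
                   profiles = profiles, connectivity = conn,
                   hubScores = hubScores, selectionResponsive = sr,
                   cellTypes = ct, anova = av, geneSetEnrichment = gs,
                   flags = flags, overlap = overlap,
                   partnerFlags = partnerFlags, prioritized = prioritized,
                   regionProfiles = mrp, hypotheses = hypotheses))
}
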