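# Readers and writers for the plain-text interchange formats: expression and
# metadata TSV, GMT gene-set collections, ortholog and connectivity tables,
# truth/dendrogram JSON, Cytoscape-importable edge lists and GraphML.

#' @importFrom utils read.delim write.table
NULL

#' Write an expression matrix as TSV (first column = gene id)
#' @param x matrix or [RegionExpressionSet-class].
#' @param path output file.
#' @export
writeExpressionTSV <- function(x, path) {
    if (methods::is(x, "RegionExpressionSet")) x <- exprValues(x)
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression TSV written by [writeExpressionTSV()]
#' @param path input file.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Write sample metadata (sample_id, genotype, region) as TSV
#' @param ds a [RegionExpressionSet-class].
#' @param path output file.
#' @export
writeMetadataTSV <- function(ds, path) {
    df <- data.frame(sample_id = colnames(ds),
                     genotype = sampleGenotype(ds),
                     region = sampleRegion(ds))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assemble a RegionExpressionSet from TSV files
#' @param exprPath expression TSV (genes x samples).
#' @param metaPath metadata TSV with sample_id, genotype, region.
#' @param detectionPath optional detection p-value TSV, same layout as the
#'   expression file.
#' @return a [RegionExpressionSet-class].
#' @export
readDataset <- function(exprPath, metaPath, detectionPath = NULL) {
    x <- readExpressionTSV(exprPath)
    meta <- read.delim(metaPath)
    meta <- meta[match(colnames(x), meta$sample_id), ]
    det <- if (!is.null(detectionPath)) readExpressionTSV(detectionPath) else NULL
    RegionExpressionSet(x, genotype = meta$genotype, region = meta$region,
                        detection = det)
}

#' Write a gene-set collection in GMT format
#' @param sets named list of gene id vectors.
#' @param path output file.
#' @param descriptions optional per-set description strings.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
}

#' Read a GMT gene-set collection
#' @param path input file.
#' @return named list of gene id vectors; descriptions kept in the
#'   "description" attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
    sets
}

#' Write / read a two-column ortholog table
#' @param map data.frame with columns source, target.
#' @param path file path.
#' @export
writeOrthologTSV <- function(map, path) {
    write.table(map[, c("source", "target")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
}

#' @rdname writeOrthologTSV
#' @export
readOrthologTSV <- function(path) {
    df <- read.delim(path, colClasses = "character")
    stopifnot(all(c("source", "target") %in% colnames(df)))
    df
}

#' Read a directed region-connectivity table
#' @param path TSV with columns source, target, annotation, citation.
#' @return data.frame.
#' @export
readConnectivityTSV <- function(path) {
    df <- read.delim(path, colClasses = "character")
    stopifnot(all(c("source", "target") %in% colnames(df)))
    if (is.null(df$annotation)) df$annotation <- ""
    if (is.null(df$citation)) df$citation <- ""
    df
}

#' Serialize ground truth to JSON
#' @param truth truth list from [generateDataset()].
#' @param path output file.
#' @export
writeTruthJSON <- function(truth, path) {
    out <- list(geneModule = as.list(truth$geneModule),
                cellType = as.list(truth$cellType),
                effects = truth$effects,
                sampleMap = truth$sampleMap,
                outlierSamples = truth$outlierSamples)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
}

#' Serialize an hclust dendrogram as a JSON merge list
#' @param hc an hclust object.
#' @param path output file.
#' @export
writeDendrogramJSON <- function(hc, path) {
    jsonlite::write_json(list(merge = hc$merge, height = hc$height,
                              order = hc$order, labels = hc$labels),
                         path, digits = NA)
}

#' Write a thresholded adjacency edge list (Cytoscape-importable TSV)
#' @param A adjacency matrix.
#' @param path output file.
#' @param threshold minimum edge weight retained.
#' @export
writeEdgeListTSV <- function(A, path, threshold) {
    idx <- which(upper.tri(A) & A >= threshold, arr.ind = TRUE)
    df <- data.frame(gene_a = rownames(A)[idx[, 1]],
                     gene_b = colnames(A)[idx[, 2]],
                     weight = A[idx])
    df <- df[order(-df$weight, df$gene_a, df$gene_b), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Export an overlap meta-network as GraphML
#'
#' Node attributes mirror the conventional meta-network encoding: species
#' (node shape class), cell-type flag (color class), and disease relatedness
#' (color intensity).
#'
#' @param overlap an [OverlapNetwork-class].
#' @param path output file.
#' @param flagsA,flagsB optional data.frames (module, cellTypeSpecific and
#'   selectionResponsive / diseaseRelated) annotating the two networks.
#' @export
writeOverlapGraphML <- function(overlap, path, flagsA = NULL, flagsB = NULL) {
    nodes <- overlapNodes(overlap)
    edges <- overlapEdges(overlap)
    nms <- unique(nodes$network)
    nodeId <- paste(nodes$network, nodes$module, sep = ":")
    annot <- function(net, mods, flags, col) {
        if (is.null(flags)) return(rep(FALSE, length(mods)))
        out <- flags[[col]][match(mods, flags$module)]
        ifelse(is.na(out), FALSE, out)
    }
    isA <- nodes$network == nms[1]
    cellType <- logical(nrow(nodes)); disease <- logical(nrow(nodes))
    cellType[isA] <- annot(nms[1], nodes$module[isA], flagsA, "cellTypeSpecific")
    cellType[!isA] <- annot(nms[2], nodes$module[!isA], flagsB, "cellTypeSpecific")
    disease[isA] <- annot(nms[1], nodes$module[isA], flagsA, "selectionResponsive")
    disease[!isA] <- annot(nms[2], nodes$module[!isA], flagsB, "diseaseRelated")
    vert <- data.frame(name = nodeId, network = nodes$network,
                       module = nodes$module, size = nodes$size,
                       conserved = nodes$conserved,
                       cellTypeSpecific = cellType, diseaseRelated = disease)
    el <- data.frame(from = paste(nms[1], edges$moduleA, sep = ":"),
                     to = paste(nms[2], edges$moduleB, sep = ":"),
                     weight = edges$weight, overlap = edges$overlap,
                     p = edges$p)
    g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = vert)
    igraph::write_graph(g, path, format = "graphml")
}

#' Export the region graph with hypothesis edges as GraphML
#' @param hypotheses data.frame from [candidateConnections()].
#' @param regions character vector of all region labels (graph vertices).
#' @param path output file.
#' @export
writeRegionGraphML <- function(hypotheses, regions, path) {
    hyp <- hypotheses[hypotheses$type == "direct_connection", , drop = FALSE]
    el <- data.frame(from = hyp$source, to = hyp$target,
                     module = hyp$module, score = hyp$score,
                     annotation = hyp$annotation)
    g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                       vertices = data.frame(name = regions))
    igraph::write_graph(g, path, format = "graphml")
}
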