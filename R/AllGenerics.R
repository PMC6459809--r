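# Generics and accessors for the package classes. Slot access from user code
# should go through these.

#' Expression values
#' @param x a RegionExpressionSet
#' @return numeric matrix genes x samples (masked entries are NA)
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "RegionExpressionSet", function(x) assay(x, "exprs"))

#' Detection p-values
#' @param x a RegionExpressionSet
#' @return matrix of detection p-values, or NULL when absent
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname detectionP
#' @export
setMethod("detectionP", "RegionExpressionSet", function(x) {
    if ("detection" %in% assayNames(x)) assay(x, "detection") else NULL
})

#' Sample genotype labels
#' @param x a RegionExpressionSet
#' @return character vector, one entry per sample
#' @export
setGeneric("sampleGenotype", function(x) standardGeneric("sampleGenotype"))

#' @rdname sampleGenotype
#' @export
setMethod("sampleGenotype", "RegionExpressionSet",
          function(x) as.character(colData(x)$genotype))

#' Sample brain-region labels
#' @param x a RegionExpressionSet
#' @return character vector, one entry per sample
#' @export
setGeneric("sampleRegion", function(x) standardGeneric("sampleRegion"))

#' @rdname sampleRegion
#' @export
setMethod("sampleRegion", "RegionExpressionSet",
          function(x) as.character(colData(x)$region))

#' Log of masked (outlier-removed) values
#' @param x a RegionExpressionSet
#' @return data.frame with columns gene, sample, reason
#' @export
setGeneric("maskLog", function(x) standardGeneric("maskLog"))

#' @rdname maskLog
#' @export
setMethod("maskLog", "RegionExpressionSet", function(x) {
    ml <- metadata(x)$maskLog
    if (is.null(ml))
        ml <- data.frame(gene = character(), sample = character(),
                         reason = character())
    ml
})

#' Module labels per gene
#' @param x a CoexpressionNetwork or ModuleProfiles
#' @return named character vector of module colors ("grey" = unassigned)
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "CoexpressionNetwork", function(x) x@labels)

#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleProfiles", function(x) x@labels)

#' Adjacency matrix of a coexpression network
#' @param x a CoexpressionNetwork
#' @return numeric matrix S^beta
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' Similarity matrix of a coexpression network
#' @param x a CoexpressionNetwork
#' @return numeric matrix S = (1 + cor)/2
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "CoexpressionNetwork", function(x) x@similarity)

#' Topological overlap matrix
#' @param x a CoexpressionNetwork
#' @return numeric TOM matrix
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname tomMatrix
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@TOM)

#' Gene dendrogram (average linkage on 1 - TOM)
#' @param x a CoexpressionNetwork
#' @return an hclust object, or NULL before detectModules() has run
#' @export
setGeneric("geneDendrogram", function(x) standardGeneric("geneDendrogram"))

#' @rdname geneDendrogram
#' @export
setMethod("geneDendrogram", "CoexpressionNetwork",
          function(x) x@dendrogram$hclust)

#' Module eigengene matrix
#' @param x a ModuleProfiles object
#' @return numeric matrix, modules x samples
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname eigengenes
#' @export
setMethod("eigengenes", "ModuleProfiles", function(x) x@eigengenes)

#' Proportion of variance explained by each eigengene
#' @param x a ModuleProfiles object
#' @return named numeric vector
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname varianceExplained
#' @export
setMethod("varianceExplained", "ModuleProfiles", function(x) x@varExplained)

#' Edges of an overlap meta-network
#' @param x an OverlapNetwork
#' @return data.frame of retained module-module edges
#' @export
setGeneric("overlapEdges", function(x) standardGeneric("overlapEdges"))

#' @rdname overlapEdges
#' @export
setMethod("overlapEdges", "OverlapNetwork", function(x) x@edges)

#' Nodes of an overlap meta-network
#' @param x an OverlapNetwork
#' @return data.frame of (network, module) nodes
#' @export
setGeneric("overlapNodes", function(x) standardGeneric("overlapNodes"))

#' @rdname overlapNodes
#' @export
setMethod("overlapNodes", "OverlapNetwork", function(x) x@nodes)

setMethod("show", "RegionExpressionSet", function(object) {
    cat("RegionExpressionSet:", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("  genotypes:", paste(unique(sampleGenotype(object)), collapse = ", "),
        "\n")
    cat("  regions:  ", paste(unique(sampleRegion(object)), collapse = ", "),
        "\n")
    cat("  detection p-values:",
        if ("detection" %in% assayNames(object)) "present" else "absent", "\n")
    nm <- nrow(maskLog(object))
    if (nm) cat("  masked values:", nm, "\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork:", length(object@genes), "genes")
    if (length(object@power)) cat(", beta =", object@power)
    cat("\n")
    if (length(object@labels)) {
        tb <- sort(table(object@labels), decreasing = TRUE)
        cat("  modules:", sum(names(tb) != "grey"), "(grey:",
            sum(object@labels == "grey"), "genes)\n")
    } else cat("  modules: not yet detected\n")
})

setMethod("show", "ModuleProfiles", function(object) {
    cat("ModuleProfiles:", nrow(object@eigengenes), "modules x",
        ncol(object@eigengenes), "samples\n")
    cat("  variance explained:",
        paste(sprintf("%s=%.2f", names(object@varExplained),
                      object@varExplained), collapse = ", "), "\n")
})

setMethod("show", "OverlapNetwork", function(object) {
    cat("OverlapNetwork:", nrow(object@nodes), "module nodes,",
        nrow(object@edges), "edges at p <", object@threshold, "\n")
    cat("  shared universe:", object@universeSize, "genes\n")
})
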