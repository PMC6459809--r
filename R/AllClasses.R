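#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' RegionExpressionSet: expression across genotypes and brain regions
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples expression matrix (assay `"exprs"`, log2-like scale after
#' normalization), an optional detection p-value matrix (assay `"detection"`,
#' same shape), and per-sample metadata with mandatory `genotype` and `region`
#' columns. Values removed by outlier filtering are `NA` in `"exprs"`; the
#' removal log (gene, sample, reason) is kept in `metadata(x)$maskLog` and all
#' downstream statistics treat `NA` as excluded.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("RegionExpressionSet", contains = "SummarizedExperiment")

setValidity("RegionExpressionSet", function(object) {
    msg <- NULL
    cd <- colData(object)
    if (!all(c("genotype", "region") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'genotype' and 'region'")
    if (!"exprs" %in% assayNames(object))
        msg <- c(msg, "an assay named 'exprs' is required")
    if ("detection" %in% assayNames(object)) {
        d <- assay(object, "detection")
        if (!all(dim(d) == dim(assay(object, "exprs"))))
            msg <- c(msg, "'detection' assay must match 'exprs' dimensions")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a RegionExpressionSet
#'
#' @param exprs numeric matrix, genes x samples, with rownames (gene ids) and
#'   colnames (sample ids).
#' @param genotype character/factor of length `ncol(exprs)`; two levels,
#'   conventionally `"selected"` (the bred line) and `"control"` (founder
#'   stock).
#' @param region character/factor of length `ncol(exprs)`; brain-region label
#'   per sample.
#' @param detection optional matrix of detection p-values, same shape as
#'   `exprs`.
#' @return A [RegionExpressionSet-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ds <- RegionExpressionSet(m, genotype = rep(c("selected", "control"), c(3, 2)),
#'                           region = rep("PFC", 5))
#' @export
RegionExpressionSet <- function(exprs, genotype, region, detection = NULL) {
    if (is.null(rownames(exprs)))
        rownames(exprs) <- paste0("gene", seq_len(nrow(exprs)))
    if (is.null(colnames(exprs)))
        colnames(exprs) <- paste0("sample", seq_len(ncol(exprs)))
    stopifnot(length(genotype) == ncol(exprs), length(region) == ncol(exprs))
    al <- list(exprs = exprs)
    if (!is.null(detection)) {
        dimnames(detection) <- dimnames(exprs)
        al$detection <- detection
    }
    se <- SummarizedExperiment(
        assays = al,
        colData = DataFrame(genotype = as.character(genotype),
                            region = as.character(region),
                            row.names = colnames(exprs)))
    obj <- methods::new("RegionExpressionSet", se)
    metadata(obj)$maskLog <- data.frame(gene = character(), sample = character(),
                                        reason = character())
    obj
}

#' CoexpressionNetwork: signed similarity, adjacency, TOM and modules
#'
#' Container for a signed weighted coexpression network. `similarity` is
#' S = (1 + cor)/2, `adjacency` is S^beta, `TOM` the topological overlap
#' matrix; all symmetric with unit diagonal. `dendrogram` stores the
#' average-linkage `hclust` tree on 1 - TOM, and `labels` the module colors
#' per gene ("grey" = unassigned). Slots are filled progressively by
#' [signedAdjacency()], [topologicalOverlap()] and [detectModules()].
#'
#' @slot genes character vector of gene ids.
#' @slot similarity numeric matrix S in `[0,1]`.
#' @slot power numeric, the soft-threshold exponent beta.
#' @slot adjacency numeric matrix `S^beta`.
#' @slot TOM numeric matrix of topological overlap values.
#' @slot dendrogram list; `$hclust` holds the tree once built.
#' @slot labels named character vector of module colors per gene.
#' @slot fitIndices data.frame of scale-free fit statistics per candidate beta.
#' @export
setClass("CoexpressionNetwork",
    representation(genes = "character", similarity = "matrix",
                   power = "numeric", adjacency = "matrix", TOM = "matrix",
                   dendrogram = "list", labels = "character",
                   fitIndices = "data.frame"),
    prototype(dendrogram = list(), labels = character(),
              fitIndices = data.frame()))

setValidity("CoexpressionNetwork", function(object) {
    msg <- NULL
    chk <- function(M, nm) {
        out <- NULL
        if (length(M)) {
            if (nrow(M) != length(object@genes))
                out <- c(out, sprintf("%s dimension disagrees with genes", nm))
            if (!isSymmetric(unname(M), tol = 1e-8))
                out <- c(out, sprintf("%s must be symmetric", nm))
            rng <- range(M, na.rm = TRUE)
            if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
                out <- c(out, sprintf("%s values must lie in [0,1]", nm))
        }
        out
    }
    msg <- c(msg, chk(object@similarity, "similarity"),
             chk(object@adjacency, "adjacency"), chk(object@TOM, "TOM"))
    if (length(object@labels) && length(object@labels) != length(object@genes))
        msg <- c(msg, "labels must cover every gene")
    if (is.null(msg)) TRUE else msg
})

#' ModuleProfiles: eigengenes and per-module summaries
#'
#' @slot eigengenes numeric matrix, modules x samples; each row is the module
#'   eigengene (first principal component of the standardized module
#'   submatrix), unit norm, oriented so that its correlation with the module
#'   mean expression profile is non-negative.
#' @slot varExplained named numeric; proportion of module variance captured by
#'   the eigengene.
#' @slot labels named character vector of module colors per gene.
#' @export
setClass("ModuleProfiles",
    representation(eigengenes = "matrix", varExplained = "numeric",
                   labels = "character"))

setValidity("ModuleProfiles", function(object) {
    msg <- NULL
    if (nrow(object@eigengenes) != length(object@varExplained))
        msg <- c(msg, "one varExplained entry per eigengene row required")
    if (is.null(msg)) TRUE else msg
})

#' OverlapNetwork: cross-network module-conservation meta-network
#'
#' Bipartite graph between the modules of two coexpression networks. Nodes are
#' (network, module) pairs; edges connect modules from *different* networks
#' whose gene overlap on the shared (ortholog-mapped) universe is significant
#' by the hypergeometric upper-tail test. Edge weight is -log10(p).
#'
#' @slot nodes data.frame: network, module, size.
#' @slot edges data.frame: moduleA, moduleB, overlap, p, weight.
#' @slot threshold numeric p-value threshold used to retain edges.
#' @slot universeSize integer size of the shared gene universe.
#' @export
setClass("OverlapNetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   threshold = "numeric", universeSize = "integer"))

setValidity("OverlapNetwork", function(object) {
    msg <- NULL
    if (nrow(object@edges) &&
        !all(c("moduleA", "moduleB", "overlap", "p", "weight") %in%
             colnames(object@edges)))
        msg <- c(msg, "edges must have moduleA, moduleB, overlap, p, weight")
    if (nrow(object@edges) && any(object@edges$p >= object@threshold))
        msg <- c(msg, "retained edges must satisfy p < threshold")
    if (is.null(msg)) TRUE else msg
})
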