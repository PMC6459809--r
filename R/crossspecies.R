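# Cross-species / cross-study module comparison: ortholog mapping restricted
# to one-to-one pairs, hypergeometric internetwork module overlap on the
# shared universe, a -log10(p) meta-network, and the four-criteria module
# prioritization.

#' Map gene ids through an ortholog table
#'
#' Restricts the table to one-to-one pairs (sources or targets occurring more
#' than once are dropped and counted as ambiguous), translates the input ids,
#' and reports what was lost.
#'
#' @param ids character vector of source-species gene ids.
#' @param map data.frame with columns `source` and `target`.
#' @return list with `mapped` (named character: source -> target for the ids
#'   that translate) and `report` (nInput, nMapped, nUnmapped, nAmbiguous).
#' @export
mapOrthologs <- function(ids, map) {
    if (!nrow(map)) stop("empty ortholog map")
    dupS <- map$source %in% map$source[duplicated(map$source)]
    dupT <- map$target %in% map$target[duplicated(map$target)]
    ambiguousIds <- intersect(ids, map$source[dupS | dupT])
    map <- map[!dupS & !dupT, , drop = FALSE]
    tr <- stats::setNames(map$target, map$source)
    hit <- ids[ids %in% names(tr)]
    list(mapped = tr[hit],
         report = list(nInput = length(ids), nMapped = length(hit),
                       nUnmapped = length(ids) - length(hit),
                       nAmbiguous = length(ambiguousIds)))
}

#' Internetwork module overlap meta-network
#'
#' Maps network A's labels into network B's id space, forms the shared
#' universe (genes present in both labelings after mapping), and tests every
#' non-grey module pair (a in A, b in B) for gene overlap with the upper-tail
#' hypergeometric test on that universe. Edges with p below `pThreshold` are
#' retained, weighted by -log10(p); a module is *conserved* when it keeps at
#' least one edge. No multiplicity correction is applied to the overlap p by
#' default (`correct = TRUE` switches the threshold to BH q-values).
#'
#' @param labelsA,labelsB named module-label vectors of the two networks.
#' @param map optional ortholog data.frame (source = A ids, target = B ids);
#'   `NULL` means the networks share an id space.
#' @param pThreshold edge retention threshold.
#' @param networkNames length-2 character used in node ids.
#' @param correct apply BH across module pairs before thresholding.
#' @return an [OverlapNetwork-class] object.
#' @export
moduleOverlapNetwork <- function(labelsA, labelsB, map = NULL,
                                 pThreshold = 0.001,
                                 networkNames = c("A", "B"),
                                 correct = FALSE) {
    if (!is.null(map)) {
        mo <- mapOrthologs(names(labelsA), map)
        labelsA <- stats::setNames(labelsA[names(mo$mapped)],
                                   unname(mo$mapped))
    }
    shared <- intersect(names(labelsA), names(labelsB))
    if (!length(shared)) stop("empty shared universe after mapping")
    la <- labelsA[shared]; lb <- labelsB[shared]
    modsA <- setdiff(sort(unique(la)), "grey")
    modsB <- setdiff(sort(unique(lb)), "grey")
    rows <- list()
    for (a in modsA) {
        ga <- shared[la == a]
        for (b in modsB) {
            gb <- shared[lb == b]
            ht <- hyperGeoTest(ga, gb, shared)
            rows[[length(rows) + 1]] <- data.frame(
                moduleA = a, moduleB = b, sizeA = ht$n, sizeB = ht$K,
                overlap = ht$k, p = ht$p)
        }
    }
    tab <- do.call(rbind, rows)
    crit <- if (correct) bhFDR(tab$p) else tab$p
    edges <- tab[crit < pThreshold, , drop = FALSE]
    edges$weight <- -log10(pmax(edges$p, .Machine$double.xmin))
    rownames(edges) <- NULL
    nodes <- rbind(
        data.frame(network = networkNames[1], module = modsA,
                   size = as.integer(table(la)[modsA])),
        data.frame(network = networkNames[2], module = modsB,
                   size = as.integer(table(lb)[modsB])))
    nodes$conserved <- ifelse(nodes$network == networkNames[1],
                              nodes$module %in% edges$moduleA,
                              nodes$module %in% edges$moduleB)
    methods::new("OverlapNetwork", nodes = nodes, edges = edges,
                 threshold = pThreshold, universeSize = length(shared))
}

#' Prioritize modules by the four conservation criteria
#'
#' Selects modules of network A that are (1) selection-responsive,
#' (2) conserved (at least one retained overlap edge), (3) cell-type-specific,
#' and (4) connected to a partner-network module that is both disease-related
#' (e.g. alcohol-related) and cell-type-specific. The returned table records
#' the evidence per criterion for every module.
#'
#' @param flags data.frame with columns `module`, `selectionResponsive`,
#'   `cellTypeSpecific` (network A annotation).
#' @param overlap an [OverlapNetwork-class] from [moduleOverlapNetwork()].
#' @param partnerFlags data.frame with columns `module`, `diseaseRelated`,
#'   `cellTypeSpecific` for network B.
#' @return data.frame with per-criterion logicals, the qualifying partner
#'   modules, and `selected` (all four criteria met).
#' @export
prioritizeConservedModules <- function(flags, overlap, partnerFlags) {
    need <- c("module", "selectionResponsive", "cellTypeSpecific")
    if (!all(need %in% colnames(flags)))
        stop("flags must provide: ", paste(setdiff(need, colnames(flags)),
                                           collapse = ", "))
    needP <- c("module", "diseaseRelated", "cellTypeSpecific")
    if (!all(needP %in% colnames(partnerFlags)))
        stop("partnerFlags must provide: ",
             paste(setdiff(needP, colnames(partnerFlags)), collapse = ", "))
    edges <- overlapEdges(overlap)
    goodPartners <- partnerFlags$module[partnerFlags$diseaseRelated &
                                        partnerFlags$cellTypeSpecific]
    out <- flags[, "module", drop = FALSE]
    out$selectionResponsive <- flags$selectionResponsive
    out$conserved <- out$module %in% edges$moduleA
    out$cellTypeSpecific <- flags$cellTypeSpecific
    out$partners <- vapply(out$module, function(m) {
        p <- intersect(edges$moduleB[edges$moduleA == m], goodPartners)
        paste(p, collapse = ";")
    }, character(1))
    out$connectedToDiseasePartner <- nzchar(out$partners)
    out$selected <- out$selectionResponsive & out$conserved &
        out$cellTypeSpecific & out$connectedToDiseasePartner
    rownames(out) <- NULL
    out
}
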