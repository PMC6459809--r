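# Circuit-hypothesis generation: turn module-level, multi-region regulation
# patterns into ranked hypotheses about neural connections, using a
# user-editable anatomical connectivity table. Modules coregulated in two
# connected regions suggest either the direct projection or a common upstream
# driver; both readings are emitted, separately labeled.

#' Default anatomical connectivity table for the seven study regions
#'
#' Directed region-to-region projections among PFC, AcbC, AcbSh, BNST, BLA,
#' CeA and VTA, with a neurotransmitter annotation and a citation tag. The
#' table ships as an editable TSV fixture
#' (`system.file("extdata", "region_connectivity.tsv", package =
#' "CoexCircuits")`); it is data, not code, and users should substitute their
#' own curation where it matters.
#'
#' @return data.frame with columns source, target, annotation, citation.
#' @export
defaultConnectivity <- function() {
    readConnectivityTSV(system.file("extdata", "region_connectivity.tsv",
                                    package = "CoexCircuits"))
}

#' Module-by-region regulation profiles
#'
#' Derives, per module and region, a regulation call from the per-direction
#' DEG-enrichment q-values ("up" or "down" when exactly that direction has
#' q < `qCut`; "mixed" when both do; otherwise "none"), the rank of the
#' region's mean eigengene expression (1 = highest), and the marker genes
#' that are simultaneously hubs and DEGs.
#'
#' @param enrichTable enrichment table from [selectionResponsiveModules()]
#'   whose set names look like "<region>.up" / "<region>.down".
#' @param profiles a [ModuleProfiles-class] object.
#' @param region character vector of region labels per sample column.
#' @param hubs per-module hub lists from [intramodularConnectivity()].
#' @param degs named per-region, per-direction DEG lists ([degLists()]).
#' @param qCut significance threshold on enrichment q.
#' @return data.frame: module, region, call, qUp, qDown, exprRank,
#'   markerGenes.
#' @export
moduleRegionProfiles <- function(enrichTable, profiles, region, hubs, degs,
                                 qCut = 0.05) {
    eg <- eigengenes(profiles)
    parts <- strsplit(enrichTable$set, ".", fixed = TRUE)
    enrichTable$region <- vapply(parts, `[`, character(1), 1)
    enrichTable$direction <- vapply(parts, `[`, character(1), 2)
    regions <- unique(region)
    mods <- rownames(eg)
    allDeg <- unique(unlist(degs))
    rows <- list()
    for (m in mods) {
        rmean <- tapply(eg[m, ], region, mean)[regions]
        rrank <- rank(-rmean, ties.method = "min")
        hubDeg <- intersect(hubs[[m]], allDeg)
        for (r in regions) {
            qUp <- enrichTable$q[enrichTable$module == m &
                                 enrichTable$region == r &
                                 enrichTable$direction == "up"]
            qDown <- enrichTable$q[enrichTable$module == m &
                                   enrichTable$region == r &
                                   enrichTable$direction == "down"]
            qUp <- if (length(qUp)) min(qUp) else NA_real_
            qDown <- if (length(qDown)) min(qDown) else NA_real_
            sigUp <- isTRUE(qUp < qCut); sigDown <- isTRUE(qDown < qCut)
            call <- if (sigUp && sigDown) "mixed"
                    else if (sigUp) "up"
                    else if (sigDown) "down" else "none"
            rows[[length(rows) + 1]] <- data.frame(
                module = m, region = r, call = call, qUp = qUp, qDown = qDown,
                exprRank = as.integer(rrank[r]),
                markerGenes = paste(hubDeg, collapse = ";"))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Ranked circuit hypotheses from coregulated region pairs
#'
#' For every neuron-flagged, selection-responsive module and every ordered
#' region pair (r1, r2) that is regulated in both regions (call != "none")
#' and present as a directed edge in the connectivity table, emits a
#' hypothesis scored by `-log10 q(r1) - log10 q(r2)` (q = the stronger
#' per-direction enrichment q in that region). Coregulated pairs absent from
#' the table in both directions are emitted as "common-upstream" candidates:
#' a third region may drive both. Output is deterministic, sorted by
#' decreasing score. The `annotation` free-text slot is meant for manual
#' curation (e.g. known upstream neurotransmitters).
#'
#' @param regionProfiles output of [moduleRegionProfiles()].
#' @param connectivity data.frame (source, target, annotation, citation); an
#'   empty table yields only common-upstream candidates, with a warning.
#' @param moduleFlags data.frame with columns `module`, `neuronSpecific`,
#'   `selectionResponsive`.
#' @return data.frame: module, source, target, type
#'   ("direct_connection" or "common_upstream"), score, calls, markerGenes,
#'   annotation, citation.
#' @export
candidateConnections <- function(regionProfiles, connectivity, moduleFlags) {
    need <- c("module", "neuronSpecific", "selectionResponsive")
    if (!all(need %in% colnames(moduleFlags)))
        stop("missing annotation: ",
             paste(setdiff(need, colnames(moduleFlags)), collapse = ", "))
    if (!nrow(connectivity))
        warning("empty connectivity table: only common-upstream candidates produced")
    eligible <- moduleFlags$module[moduleFlags$neuronSpecific &
                                   moduleFlags$selectionResponsive]
    edgeKey <- paste(connectivity$source, connectivity$target)
    rows <- list()
    for (m in intersect(eligible, unique(regionProfiles$module))) {
        sub <- regionProfiles[regionProfiles$module == m &
                              regionProfiles$call != "none", , drop = FALSE]
        if (nrow(sub) < 2) next
        qOf <- stats::setNames(pmin(sub$qUp, sub$qDown, na.rm = TRUE),
                               sub$region)
        markers <- sub$markerGenes[1]
        regs <- sort(sub$region)
        for (r1 in sub$region) for (r2 in sub$region) {
            if (r1 == r2) next
            hit <- match(paste(r1, r2), edgeKey)
            if (!is.na(hit)) {
                rows[[length(rows) + 1]] <- data.frame(
                    module = m, source = r1, target = r2,
                    type = "direct_connection",
                    score = -log10(qOf[r1]) - log10(qOf[r2]),
                    calls = paste0(r1, ":", sub$call[sub$region == r1], ",",
                                   r2, ":", sub$call[sub$region == r2]),
                    markerGenes = markers,
                    annotation = connectivity$annotation[hit],
                    citation = connectivity$citation[hit])
            }
        }
        # unordered pairs with no direct edge in either direction
        for (i in seq_along(regs)) for (j in seq_along(regs)) {
            if (i >= j) next
            r1 <- regs[i]; r2 <- regs[j]
            if (paste(r1, r2) %in% edgeKey || paste(r2, r1) %in% edgeKey) next
            rows[[length(rows) + 1]] <- data.frame(
                module = m, source = r1, target = r2,
                type = "common_upstream",
                score = -log10(qOf[r1]) - log10(qOf[r2]),
                calls = paste0(r1, ":", sub$call[sub$region == r1], ",",
                               r2, ":", sub$call[sub$region == r2]),
                markerGenes = markers,
                annotation = "", citation = "")
        }
    }
    if (!length(rows))
        return(data.frame(module = character(), source = character(),
                          target = character(), type = character(),
                          score = numeric(), calls = character(),
                          markerGenes = character(), annotation = character(),
                          citation = character()))
    out <- do.call(rbind, rows)
    out <- out[order(-out$score, out$module, out$source, out$target), ]
    rownames(out) <- NULL
    out
}
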