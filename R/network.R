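# Signed weighted coexpression network construction and module detection:
# signed similarity, soft-threshold adjacency with a scale-free fit criterion,
# topological overlap, average-linkage clustering of 1 - TOM, and a dynamic
# (recursive) tree cut. Matrices are dense genes x genes.

# WGCNA's conventional size-ranked module palette
.moduleColors <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

.colorForRank <- function(i) {
    if (i <= length(.moduleColors)) .moduleColors[i]
    else paste0("module", i)
}

#' Signed similarity and soft-threshold adjacency
#'
#' Computes the signed similarity `S_ij = (1 + cor(x_i, x_j)) / 2` (Pearson,
#' pairwise-complete over masked values) and the adjacency `a_ij = S_ij^beta`.
#' Mapping correlations to `[0, 1]` before powering keeps strongly negatively
#' correlated genes *unconnected*, which is what distinguishes a signed from
#' an unsigned network. Zero-variance genes get correlation 0 (S = 0.5) with a
#' warning.
#'
#' @param expr numeric matrix, genes x samples.
#' @param beta soft-threshold power; 12 is the conventional signed-network
#'   default at which such networks typically reach approximate scale-free
#'   topology.
#' @return a [CoexpressionNetwork-class] with similarity and adjacency filled.
#' @export
signedAdjacency <- function(expr, beta = 12) {
    if (ncol(expr) < 3) stop("need at least 3 samples")
    cc <- suppressWarnings(stats::cor(t(expr), use = "pairwise.complete.obs"))
    if (anyNA(cc)) {
        warning(sum(is.na(cc[upper.tri(cc)])),
                " undefined correlations (zero-variance genes) set to 0")
        cc[is.na(cc)] <- 0
    }
    S <- (1 + cc) / 2
    diag(S) <- 1
    A <- S^beta
    diag(A) <- 1
    methods::new("CoexpressionNetwork", genes = rownames(expr),
                 similarity = S, power = as.numeric(beta), adjacency = A)
}

#' Scale-free fit index of a connectivity distribution
#'
#' Bins the connectivities into `nBins` equal-width bins, regresses
#' log10(frequency) on log10(mean connectivity), and returns
#' `R^2 * sign(-slope)` so that only declining degree distributions score
#' well.
#'
#' @param k vector of node connectivities.
#' @param nBins number of bins.
#' @return list with `fit`, `slope`, `r2`.
#' @export
scaleFreeFitIndex <- function(k, nBins = 10) {
    if (max(k) - min(k) < .Machine$double.eps^0.5)
        stop("all-constant connectivity: scale-free fit undefined")
    bins <- cut(k, breaks = nBins)
    freq <- tapply(k, bins, length)
    meank <- tapply(k, bins, mean)
    ok <- !is.na(freq) & freq > 0 & meank > 0
    lf <- log10(freq[ok]); lk <- log10(meank[ok])
    if (sum(ok) < 3) stop("too few occupied bins for a scale-free fit")
    fit <- stats::lm(lf ~ lk)
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    list(fit = r2 * sign(-slope), slope = unname(slope), r2 = r2)
}

#' Choose the soft-threshold power
#'
#' For each candidate beta, computes connectivities `k_i = sum_j S_ij^beta`
#' and the scale-free fit index; returns the smallest beta whose index
#' reaches `targetR2`, or the argmax with a warning flag when none does.
#'
#' @param S signed similarity matrix.
#' @param candidateBetas powers to scan.
#' @param targetR2 required fit index.
#' @return list with `beta`, `fitIndices` (data.frame), and `reachedTarget`.
#' @export
pickSoftThreshold <- function(S, candidateBetas = c(1:10, 12, 14, 16, 18, 20),
                              targetR2 = 0.8) {
    if (!length(candidateBetas)) stop("candidateBetas must be non-empty")
    fits <- data.frame(beta = candidateBetas, fit = NA_real_,
                       slope = NA_real_, meanK = NA_real_)
    for (i in seq_along(candidateBetas)) {
        A <- S^candidateBetas[i]
        k <- colSums(A) - 1
        sf <- scaleFreeFitIndex(k)
        fits$fit[i] <- sf$fit
        fits$slope[i] <- sf$slope
        fits$meanK[i] <- mean(k)
    }
    hit <- which(fits$fit >= targetR2)
    if (length(hit)) {
        beta <- candidateBetas[hit[1]]
        reached <- TRUE
    } else {
        beta <- candidateBetas[which.max(fits$fit)]
        reached <- FALSE
        warning("no candidate beta reached the target fit index ", targetR2,
                "; returning the best (beta = ", beta, ")")
    }
    list(beta = beta, fitIndices = fits, reachedTarget = reached)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbours u != i, j and
#' `k_i = sum_u a_iu` over u != i; `TOM_ii = 1`. Two genes overlap highly when
#' they are connected *and* share their neighbourhoods.
#'
#' @param A symmetric adjacency matrix with unit diagonal and values in
#'   `[0, 1]`.
#' @return the TOM matrix.
#' @export
topologicalOverlap <- function(A) {
    if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
    L <- A %*% A
    l <- L - 2 * A          # removes the u = i and u = j terms (diag(A) = 1)
    k <- rowSums(A) - 1
    denom <- outer(k, k, pmin) + 1 - A
    tom <- (l + A) / denom
    diag(tom) <- 1
    tom[tom < 0] <- 0
    tom[tom > 1] <- 1
    dimnames(tom) <- dimnames(A)
    (tom + t(tom)) / 2
}

# leaves under each node of an hclust merge tree; node > 0 indexes merges,
# node < 0 a leaf
.leavesOf <- function(merge, node) {
    if (node < 0) return(-node)
    stack <- node
    leaves <- integer(0)
    while (length(stack)) {
        nd <- stack[length(stack)]
        stack <- stack[-length(stack)]
        for (child in merge[nd, ]) {
            if (child < 0) leaves <- c(leaves, -child)
            else stack <- c(stack, child)
        }
    }
    leaves
}

# internal merge nodes within the subtree rooted at `node`
.subtreeNodes <- function(merge, node) {
    if (node < 0) return(integer(0))
    stack <- node
    nodes <- integer(0)
    while (length(stack)) {
        nd <- stack[length(stack)]
        stack <- stack[-length(stack)]
        nodes <- c(nodes, nd)
        for (child in merge[nd, ]) if (child > 0) stack <- c(stack, child)
    }
    nodes
}

# recursive deep split: cut a branch at its top merge when both children are
# large enough and the merge height exceeds the branch's median merge height
.deepSplit <- function(merge, height, node, minSize) {
    if (node < 0) return(list(-node))
    sub <- .subtreeNodes(merge, node)
    kids <- merge[node, ]
    sizes <- vapply(kids, function(ch) length(.leavesOf(merge, ch)), integer(1))
    if (all(sizes >= minSize) && height[node] > stats::median(height[sub])) {
        c(.deepSplit(merge, height, kids[1], minSize),
          .deepSplit(merge, height, kids[2], minSize))
    } else {
        list(.leavesOf(merge, node))
    }
}

#' Detect modules by average-linkage clustering and a dynamic tree cut
#'
#' Builds the average-linkage dendrogram on the dissimilarity 1 - TOM, cuts it
#' statically at `cutHeight` into candidate branches, and (when `deepSplit`)
#' recursively splits each branch at internal merges where both children hold
#' at least `minModuleSize` leaves and the merge height exceeds the branch's
#' median merge height. Branches smaller than `minModuleSize` become "grey"
#' (unassigned); modules are named by the conventional size-ranked color
#' palette, largest first ("turquoise", "blue", "brown", ...). The procedure
#' is fully deterministic.
#'
#' @param net a [CoexpressionNetwork-class] with the TOM slot filled, or a TOM
#'   matrix.
#' @param minModuleSize smallest accepted module.
#' @param cutHeight static cut height on 1 - TOM.
#' @param deepSplit logical; enable the recursive branch splitting.
#' @return the network object with `labels` and `dendrogram` filled (or, for
#'   a matrix input, a list with `labels` and `hclust`).
#' @export
detectModules <- function(net, minModuleSize = 80, cutHeight = 0.995,
                          deepSplit = TRUE) {
    tom <- if (methods::is(net, "CoexpressionNetwork")) net@TOM else net
    if (!length(tom)) stop("TOM has not been computed")
    genes <- rownames(tom)
    n <- nrow(tom)
    hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    labels <- rep("grey", n)
    if (minModuleSize > n) {
        warning("minModuleSize exceeds the gene count; all genes grey")
    } else {
        groups <- stats::cutree(hc, h = cutHeight)
        merge <- hc$merge; height <- hc$height
        # root merge node of each static branch (largest subtree inside it)
        branchLeaves <- split(seq_len(n), groups)
        nodeLeafCount <- integer(nrow(merge))
        nodeGroup <- integer(nrow(merge))     # 0 = spans several groups
        for (nd in seq_len(nrow(merge))) {
            ch <- merge[nd, ]
            cnt <- grpL <- grpR <- 0
            if (ch[1] < 0) { cnt <- 1; grpL <- groups[-ch[1]] }
            else { cnt <- nodeLeafCount[ch[1]]; grpL <- nodeGroup[ch[1]] }
            if (ch[2] < 0) { cnt <- cnt + 1; grpR <- groups[-ch[2]] }
            else { cnt <- cnt + nodeLeafCount[ch[2]]; grpR <- nodeGroup[ch[2]] }
            nodeLeafCount[nd] <- cnt
            nodeGroup[nd] <- if (grpL == grpR) grpL else 0L
        }
        modules <- list()
        for (g in seq_along(branchLeaves)) {
            lv <- branchLeaves[[g]]
            if (length(lv) == 1) { modules <- c(modules, list(lv)); next }
            root <- which(nodeGroup == g & nodeLeafCount == length(lv))
            root <- root[which.max(nodeLeafCount[root])]
            if (deepSplit) {
                modules <- c(modules,
                             .deepSplit(merge, height, root, minModuleSize))
            } else {
                modules <- c(modules, list(lv))
            }
        }
        keep <- modules[vapply(modules, length, integer(1)) >= minModuleSize]
        if (length(keep)) {
            ord <- order(vapply(keep, length, integer(1)), decreasing = TRUE)
            for (i in seq_along(ord))
                labels[keep[[ord[i]]]] <- .colorForRank(i)
        }
    }
    names(labels) <- genes
    if (methods::is(net, "CoexpressionNetwork")) {
        net@labels <- labels
        net@dendrogram <- list(hclust = hc)
        methods::validObject(net)
        net
    } else list(labels = labels, hclust = hc)
}

#' Compute the TOM for a network object
#'
#' @param net a [CoexpressionNetwork-class] with adjacency filled.
#' @return the network with the TOM slot filled.
#' @export
computeTOM <- function(net) {
    net@TOM <- topologicalOverlap(net@adjacency)
    methods::validObject(net)
    net
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression submatrix (each gene centered and scaled over
#' samples; masked values mean-imputed), a unit-norm vector across samples
#' oriented so its correlation with the module's mean expression profile is
#' non-negative. It summarizes the module as a single meta-gene. A singular
#' submatrix falls back to the standardized mean profile with a warning.
#'
#' @param expr genes x samples matrix.
#' @param labels named module labels per gene ("grey" excluded).
#' @return a [ModuleProfiles-class] object.
#' @export
moduleEigengenes <- function(expr, labels) {
    mods <- setdiff(sort(unique(labels)), "grey")
    if (!length(mods)) stop("no non-grey modules")
    eg <- matrix(NA_real_, length(mods), ncol(expr),
                 dimnames = list(mods, colnames(expr)))
    ve <- stats::setNames(numeric(length(mods)), mods)
    for (m in mods) {
        genes <- names(labels)[labels == m]
        x <- expr[genes, , drop = FALSE]
        xs <- t(scale(t(x)))
        xs[!is.finite(xs)] <- 0
        sv <- tryCatch(svd(xs, nu = 0, nv = 1), error = function(e) NULL)
        if (is.null(sv) || sv$d[1] < .Machine$double.eps^0.5) {
            warning("singular submatrix for module ", m,
                    "; using the standardized mean profile")
            v <- colMeans(xs)
            v <- v / sqrt(sum(v^2))
            ve[m] <- NA_real_
        } else {
            v <- sv$v[, 1]
            ve[m] <- sv$d[1]^2 / sum(sv$d^2)
        }
        mp <- colMeans(x, na.rm = TRUE)
        if (stats::cor(v, mp) < 0) v <- -v
        eg[m, ] <- v
    }
    methods::new("ModuleProfiles", eigengenes = eg, varExplained = ve,
                 labels = labels)
}

#' Intramodular connectivity and hub genes
#'
#' `K_in(g)` is the sum of the adjacencies between gene g and the other
#' members of its module. Hub genes are the top `ceil(topFraction * size)`
#' members by `K_in`, ties broken by gene id (lexicographic).
#'
#' @param A adjacency matrix.
#' @param labels named module labels aligned with A's genes.
#' @param topFraction fraction of a module counted as hubs.
#' @return list with `kIn` (named numeric) and `hubs` (per-module character
#'   vectors).
#' @export
intramodularConnectivity <- function(A, labels, topFraction = 0.2) {
    genes <- rownames(A)
    labels <- labels[genes]
    kIn <- stats::setNames(numeric(length(genes)), genes)
    hubs <- list()
    for (m in setdiff(unique(labels), "grey")) {
        member <- genes[labels == m]
        sub <- A[member, member, drop = FALSE]
        kIn[member] <- rowSums(sub) - 1
        ord <- member[order(-kIn[member], member)]
        hubs[[m]] <- ord[seq_len(ceiling(topFraction * length(member)))]
    }
    list(kIn = kIn, hubs = hubs)
}

#' Hub-module scores
#'
#' Edges are gene pairs whose adjacency reaches the `(1 - density)` quantile
#' of the off-diagonal adjacency among assigned (non-grey) genes; the default
#' (0.25) treats the top quartile of gene-pair adjacencies as the network's
#' "connections". For module m, `scoreAll` counts edges with exactly one
#' endpoint in m, normalized by module size; `scoreTopQuartile` restricts the
#' count to edges whose weight lies in the top quartile of retained edge
#' weights. The module maximizing `scoreAll` is the network's hub module.
#'
#' @param A adjacency matrix.
#' @param labels named module labels.
#' @param density fraction of off-diagonal pairs retained as edges.
#' @return data.frame (module, size, scoreAll, scoreTopQuartile, hubModule
#'   flag), ordered by decreasing scoreAll.
#' @export
hubModuleScores <- function(A, labels, density = 0.25) {
    genes <- rownames(A)
    labels <- labels[genes]
    assigned <- genes[labels != "grey"]
    if (length(unique(labels[assigned])) < 2)
        stop("need at least 2 non-grey modules")
    sub <- A[assigned, assigned, drop = FALSE]
    w <- sub[upper.tri(sub)]
    if (max(w) - min(w) < .Machine$double.eps^0.5)
        stop("degenerate adjacency (all weights equal): lower beta or check input")
    tau <- stats::quantile(w, 1 - density, names = FALSE)
    idx <- which(upper.tri(sub) & sub >= tau, arr.ind = TRUE)
    ew <- sub[cbind(idx[, 1], idx[, 2])]
    la <- labels[assigned][idx[, 1]]
    lb <- labels[assigned][idx[, 2]]
    inter <- la != lb
    topq <- ew >= stats::quantile(ew, 0.75, names = FALSE)
    mods <- sort(unique(labels[assigned]))
    res <- data.frame(module = mods,
                      size = as.integer(table(labels[assigned])[mods]),
                      scoreAll = NA_real_, scoreTopQuartile = NA_real_)
    for (i in seq_along(mods)) {
        m <- mods[i]
        one <- inter & (la == m | lb == m)
        res$scoreAll[i] <- sum(one) / res$size[i]
        res$scoreTopQuartile[i] <- sum(one & topq) / res$size[i]
    }
    res <- res[order(-res$scoreAll, res$module), ]
    res$hubModule <- seq_len(nrow(res)) == 1
    rownames(res) <- NULL
    res
}

#' Build the full coexpression network in one call
#'
#' Convenience wrapper: similarity/adjacency (optionally choosing beta by the
#' scale-free criterion), TOM, and module detection.
#'
#' @param expr genes x samples matrix.
#' @param beta soft power, or `NULL` to select it with [pickSoftThreshold()].
#' @param candidateBetas,targetR2 passed to [pickSoftThreshold()].
#' @param minModuleSize,cutHeight,deepSplit passed to [detectModules()].
#' @return a [CoexpressionNetwork-class] with all slots filled.
#' @export
buildNetwork <- function(expr, beta = NULL,
                         candidateBetas = c(1:10, 12, 14, 16, 18, 20),
                         targetR2 = 0.8, minModuleSize = 80,
                         cutHeight = 0.995, deepSplit = TRUE) {
    fits <- data.frame()
    if (is.null(beta)) {
        S <- (1 + {
            cc <- stats::cor(t(expr), use = "pairwise.complete.obs")
            cc[is.na(cc)] <- 0
            cc
        }) / 2
        diag(S) <- 1
        pick <- pickSoftThreshold(S, candidateBetas, targetR2)
        beta <- pick$beta
        fits <- pick$fitIndices
    }
    net <- signedAdjacency(expr, beta = beta)
    net@fitIndices <- fits
    net <- computeTOM(net)
    detectModules(net, minModuleSize = minModuleSize, cutHeight = cutHeight,
                  deepSplit = deepSplit)
}
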