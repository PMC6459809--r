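# Per-region two-group differential expression with empirical-Bayes moderated
# t statistics. The variance-shrinkage hyperparameters (prior df d0, prior
# variance s0^2) are estimated by the method of moments on log sample
# variances using digamma/trigamma relations, with per-gene residual df (which
# vary when Grubbs masking removed values). Posterior variances are
# s_post^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g) and the moderated t is
# referred to a t distribution on d0 + d_g df.

# Newton inversion of the trigamma function, tolerance 1e-8.
trigammaInverse <- function(x) {
    vapply(x, function(xx) {
        if (!is.finite(xx) || xx <= 0) return(Inf)
        if (xx > 1e7) return(1 / sqrt(xx))
        if (xx < 1e-6) return(1 / xx)
        y <- 0.5 + 1 / xx
        for (i in 1:75) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / xx) / psigamma(y, deriv = 2)
            y <- y + dif
            if (abs(dif) < 1e-8 * y) break
        }
        y
    }, numeric(1))
}

#' Estimate variance-prior hyperparameters by the moment method
#'
#' Given per-gene sample variances `s2` on `df` residual degrees of freedom,
#' fits the scaled inverse-chi-square prior: solves
#' `var(e_g) = trigamma(df_g/2) + trigamma(d0/2)` for the prior df `d0` by
#' monotone (Newton) inversion of the trigamma function, then recovers the
#' prior variance `s0^2` from the mean of `e_g = log(s2) - digamma(df/2) +
#' log(df/2)`. `d0` above 1e6 is reported as `Inf` (complete shrinkage).
#'
#' @param s2 numeric vector of per-gene variances (positive).
#' @param df residual degrees of freedom, recycled to match.
#' @return list with `d0` (prior df) and `s02` (prior variance).
#' @export
fitVariancePrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & s2 > 0 & df > 0
    s2 <- s2[ok]; df <- df[ok]
    if (length(s2) < 2) stop("need at least two positive variances")
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        if (d0 > 1e6) d0 <- Inf
    } else d0 <- Inf
    s02 <- if (is.finite(d0))
        exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(emean)
    list(d0 = d0, s02 = s02)
}

#' Moderated t-test between genotypes within one region
#'
#' Two-group comparison (selected vs control) with empirical-Bayes variance
#' shrinkage. Masked (`NA`) values are excluded gene-wise, so group sizes and
#' residual df vary by gene and enter both the hyperparameter fit and the
#' posterior formula. Setting `priorDf` forces `d0` (0 reproduces the ordinary
#' pooled t exactly; `Inf` gives the fully shrunken, z-like statistic).
#'
#' @param ds a [RegionExpressionSet-class].
#' @param region region label to test.
#' @param groups length-2 character: the (test, reference) genotype labels;
#'   `delta = mean(test) - mean(reference)`.
#' @param priorDf optional fixed prior df overriding the empirical fit.
#' @return data.frame with one row per gene: group means, `delta` (log2),
#'   signed `foldChange` (`sign(delta) * 2^|delta|`), `ordinaryT`,
#'   `moderatedT`, `df` (d0 + d_g), `rawP`, `q` (BH within region),
#'   `direction`; hyperparameters in attributes `d0` and `s02`.
#' @export
moderatedTTest <- function(ds, region, groups = c("selected", "control"),
                           priorDf = NULL) {
    cols <- sampleRegion(ds) == region
    if (!any(cols)) stop("no samples in region ", region)
    x <- exprValues(ds)[, cols, drop = FALSE]
    gt <- sampleGenotype(ds)[cols]
    x1 <- x[, gt == groups[1], drop = FALSE]
    x2 <- x[, gt == groups[2], drop = FALSE]
    n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
    if (max(n1) < 2 || max(n2) < 2)
        stop("both genotype groups need at least 2 samples in region ", region)
    m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
    v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
    v2 <- apply(x2, 1, stats::var, na.rm = TRUE)
    dfg <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dfg
    s2[dfg <= 0] <- NA
    delta <- m1 - m2
    se0 <- sqrt(s2 * (1 / n1 + 1 / n2))
    ordinaryT <- delta / se0

    if (is.null(priorDf)) {
        prior <- fitVariancePrior(s2, dfg)
    } else {
        prior <- list(d0 = priorDf,
                      s02 = if (is.finite(priorDf) && priorDf == 0)
                          NA_real_ else mean(s2, na.rm = TRUE))
        if (is.infinite(priorDf))
            prior$s02 <- fitVariancePrior(s2, dfg)$s02
    }
    d0 <- prior$d0; s02 <- prior$s02
    if (is.infinite(d0)) {
        sPost2 <- rep(s02, length(s2))
        dfTotal <- rep(Inf, length(s2))
    } else if (d0 == 0) {
        sPost2 <- s2
        dfTotal <- dfg
    } else {
        sPost2 <- (d0 * s02 + dfg * s2) / (d0 + dfg)
        dfTotal <- d0 + dfg
    }
    modT <- delta / sqrt(sPost2 * (1 / n1 + 1 / n2))
    eq <- which(abs(delta) < .Machine$double.eps^0.75)
    modT[eq] <- 0
    rawP <- 2 * stats::pt(-abs(modT), df = dfTotal)
    bad <- !is.finite(modT) | dfg < 1 | n1 < 2 | n2 < 2
    modT[bad] <- NA; rawP[bad] <- NA
    q <- rep(NA_real_, length(rawP))
    q[!is.na(rawP)] <- bhFDR(rawP[!is.na(rawP)])
    res <- data.frame(
        gene = rownames(x),
        meanSelected = m1, meanControl = m2, delta = delta,
        foldChange = sign(delta) * 2^abs(delta),
        ordinaryT = ordinaryT, moderatedT = modT, df = dfTotal,
        rawP = rawP, q = q,
        direction = ifelse(delta >= 0, "up", "down"),
        row.names = NULL)
    attr(res, "d0") <- d0
    attr(res, "s02") <- s02
    res
}

#' Differential expression across all regions
#'
#' Runs [moderatedTTest()] per region (each region restricted to its own
#' detection universe when `metadata(ds)$detectionPass` is available) and
#' assembles the combined moderated-t matrix.
#'
#' @param ds a [RegionExpressionSet-class].
#' @param alpha DEG threshold on the raw p-value.
#' @param groups passed to [moderatedTTest()].
#' @return list with `tables` (per-region data.frames), `tMatrix` (genes x
#'   regions moderated t), `pMatrix`, and `degCounts` (DEGs at raw p < alpha
#'   with the excess-over-chance chi-square per region).
#' @export
runDifferentialExpression <- function(ds, alpha = 0.05,
                                      groups = c("selected", "control")) {
    regions <- unique(sampleRegion(ds))
    pass <- metadata(ds)$detectionPass
    tables <- list()
    genes <- rownames(ds)
    tMat <- matrix(NA_real_, length(genes), length(regions),
                   dimnames = list(genes, regions))
    pMat <- tMat
    degCounts <- data.frame(region = regions, nDetected = NA_integer_,
                            nDeg = NA_integer_, chiSq = NA_real_,
                            chiSqP = NA_real_)
    for (i in seq_along(regions)) {
        r <- regions[i]
        sub <- ds
        if (!is.null(pass)) {
            keep <- intersect(genes, rownames(pass)[pass[, r]])
            sub <- ds[keep, ]
        }
        tab <- moderatedTTest(sub, r, groups = groups)
        tables[[r]] <- tab
        tMat[tab$gene, r] <- tab$moderatedT
        pMat[tab$gene, r] <- tab$rawP
        nDet <- sum(!is.na(tab$rawP))
        nDeg <- sum(tab$rawP < alpha, na.rm = TRUE)
        cs <- degsVsChance(nDeg, nDet, alpha)
        degCounts[i, c("nDetected", "nDeg", "chiSq", "chiSqP")] <-
            list(nDet, nDeg, cs$statistic, cs$p)
    }
    list(tables = tables, tMatrix = tMat, pMatrix = pMat,
         degCounts = degCounts)
}

#' Extract per-region, per-direction DEG lists
#'
#' @param de result of [runDifferentialExpression()].
#' @param alpha raw p-value threshold defining a DEG.
#' @param useQ threshold the BH q-value instead of the raw p.
#' @return named list `"<region>.up"` / `"<region>.down"` of gene id vectors.
#' @export
degLists <- function(de, alpha = 0.05, useQ = FALSE) {
    out <- list()
    for (r in names(de$tables)) {
        tab <- de$tables[[r]]
        p <- if (useQ) tab$q else tab$rawP
        sig <- !is.na(p) & p < alpha
        out[[paste0(r, ".up")]] <- tab$gene[sig & tab$direction == "up"]
        out[[paste0(r, ".down")]] <- tab$gene[sig & tab$direction == "down"]
    }
    out
}

#' Chi-square test of DEG count against chance
#'
#' Compares the observed number of significant genes with the `alpha *
#' nDetected` expected by chance using a 1-df chi-square on the
#' (significant, not significant) two-cell table, without continuity
#' correction.
#'
#' @param nDeg observed significant genes.
#' @param nDetected genes tested.
#' @param alpha nominal level defining significance.
#' @return list with `statistic` and `p`.
#' @export
degsVsChance <- function(nDeg, nDetected, alpha = 0.05) {
    if (nDetected <= 0) stop("nDetected must be positive")
    if (nDeg > nDetected) stop("nDeg cannot exceed nDetected")
    e1 <- alpha * nDetected
    e2 <- (1 - alpha) * nDetected
    stat <- (nDeg - e1)^2 / e1 + ((nDetected - nDeg) - e2)^2 / e2
    list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control:
#' `q_i = min over j with p_(j) >= p_(i) of min(1, n p_(j) / j)`,
#' order-preserving with the input.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values aligned with `p`.
#' @export
bhFDR <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' K-means clustering of moderated-t profiles across regions
#'
#' Clusters the region-wise t-statistic profiles of the top significant genes
#' (raw p below `pCut` in at least one region) to visualize region-specific
#' versus shared regulation.
#'
#' @param tMatrix genes x regions matrix of moderated t values.
#' @param pMatrix matching matrix of raw p-values used for the `pCut` filter;
#'   `NULL` disables filtering.
#' @param k number of clusters.
#' @param pCut significance filter on the best region p-value.
#' @param seed RNG seed for the restarts.
#' @param nstart random restarts.
#' @return list with `labels` (named cluster ids), `centers`, and `genes`.
#' @export
clusterTValues <- function(tMatrix, pMatrix = NULL, k = 6, pCut = 0.001,
                           seed = 0, nstart = 25) {
    rows <- rownames(tMatrix)
    if (!is.null(pMatrix)) {
        best <- apply(pMatrix, 1, min, na.rm = TRUE)
        rows <- rownames(tMatrix)[is.finite(best) & best < pCut]
    }
    m <- tMatrix[rows, , drop = FALSE]
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < k)
        stop("fewer rows (", nrow(m), ") than clusters (", k, ")")
    set.seed(seed)
    km <- stats::kmeans(m, centers = k, nstart = nstart)
    list(labels = stats::setNames(km$cluster, rownames(m)),
         centers = km$centers, genes = rownames(m))
}
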