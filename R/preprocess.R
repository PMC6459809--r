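# Preprocessing: normalization, region-wise sample-outlier removal, detection
# filtering and per-gene Grubbs outlier masking. The canonical order, applied
# by preprocessDataset(), is: normalize -> drop outlier samples -> re-normalize
# the survivors -> detection filter -> Grubbs masking.

#' Normalize an expression dataset
#'
#' Optional log2(x + 1) transform (a variance-stabilizing step for raw
#' intensities; skip it for data already on a log-like scale) followed by
#' quantile normalization across all samples: each sample's sorted values are
#' replaced by the mean of sorted values across samples, mapped back by rank,
#' ties receiving the mean of their tied positions. Quantile normalization is
#' idempotent.
#'
#' @param ds a [RegionExpressionSet-class].
#' @param log2Transform apply log2(x + 1) before the quantile step; requires
#'   strictly positive intensities.
#' @return the normalized dataset.
#' @export
normalizeExpression <- function(ds, log2Transform = FALSE) {
    x <- exprValues(ds)
    if (log2Transform) {
        bad <- which(x <= 0, arr.ind = TRUE)
        if (nrow(bad))
            stop("nonpositive intensities at e.g. gene ",
                 rownames(x)[bad[1, 1]], ", sample ", colnames(x)[bad[1, 2]],
                 " (", nrow(bad), " cells); log2 transform needs positive values")
        x <- log2(x + 1)
    }
    if (ncol(x) > 1) x <- limma::normalizeQuantiles(x, ties = TRUE)
    assay(ds, "exprs") <- x
    ds
}

#' Flag and remove outlier samples within each brain region
#'
#' For each region, every sample's Euclidean distance to the region's mean
#' expression profile is computed; samples whose distance strictly exceeds
#' 2 x the median of those distances are removed. A single pass is made.
#' Regions with fewer than 3 samples are skipped with a warning.
#'
#' @param ds a [RegionExpressionSet-class].
#' @return list with `dataset` (outliers dropped) and `flagged` (character
#'   vector of removed sample ids).
#' @export
removeOutlierSamples <- function(ds) {
    x <- exprValues(ds)
    region <- sampleRegion(ds)
    flagged <- character(0)
    for (r in unique(region)) {
        cols <- which(region == r)
        if (length(cols) < 3) {
            warning("region ", r, " has fewer than 3 samples; outlier check skipped")
            next
        }
        sub <- x[, cols, drop = FALSE]
        center <- rowMeans(sub, na.rm = TRUE)
        d <- sqrt(colSums((sub - center)^2, na.rm = TRUE))
        thr <- 2 * stats::median(d)
        flagged <- c(flagged, colnames(sub)[d > thr])
    }
    keep <- setdiff(colnames(x), flagged)
    list(dataset = ds[, keep], flagged = flagged)
}

#' Region-wise detection filter
#'
#' Within each region, a gene is considered expressed when its detection
#' p-value is below `detectionAlpha` in at least `minFraction` of that
#' region's samples (the boundary is inclusive). The returned dataset is
#' restricted to the network universe -- genes expressed in *all* regions --
#' while the full per-region pass matrix is kept in
#' `metadata(ds)$detectionPass` for per-region analyses.
#'
#' @param ds a [RegionExpressionSet-class] carrying detection p-values.
#' @param detectionAlpha per-sample detection threshold.
#' @param minFraction minimum fraction of a region's samples calling the gene
#'   detected.
#' @return the filtered dataset; `metadata(ds)$detectionPass` is a logical
#'   genes x regions matrix over the *input* genes.
#' @export
detectionFilter <- function(ds, detectionAlpha = 0.05, minFraction = 0.75) {
    dp <- detectionP(ds)
    if (is.null(dp))
        stop("no detection p-value matrix present; skip the detection filter ",
             "for data without one")
    region <- sampleRegion(ds)
    regions <- unique(region)
    pass <- matrix(FALSE, nrow(dp), length(regions),
                   dimnames = list(rownames(dp), regions))
    for (r in regions) {
        cols <- region == r
        frac <- rowMeans(dp[, cols, drop = FALSE] < detectionAlpha)
        pass[, r] <- frac >= minFraction
    }
    keep <- rownames(dp)[rowSums(pass) == length(regions)]
    out <- ds[keep, ]
    metadata(out)$detectionPass <- pass
    out
}

#' One-outlier Grubbs critical value
#'
#' `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))` with `t` the upper
#' `alpha/(2N)` quantile of Student's t on `N - 2` degrees of freedom.
#'
#' @param n group size.
#' @param alpha test level.
#' @return the critical value for `max |x - mean| / sd`.
#' @export
grubbsCritical <- function(n, alpha = 0.05) {
    t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Mask per-gene outliers by Grubbs' test within genotype x region groups
#'
#' For each gene within each genotype x region cell, the most extreme value is
#' masked (set NA) when `G = max |x - mean| / sd` exceeds the one-outlier
#' critical value at level `alpha`; the test repeats until no outlier remains
#' or the group shrinks below `minGroupSize`. Groups with zero variance are
#' left untouched, and no more than half of a group is ever masked.
#'
#' @param ds a [RegionExpressionSet-class].
#' @param alpha test level.
#' @param minGroupSize smallest group size still tested.
#' @return the dataset with outliers masked and the removal log extended.
#' @export
grubbsFilter <- function(ds, alpha = 0.05, minGroupSize = 6) {
    x <- exprValues(ds)
    grp <- paste(sampleGenotype(ds), sampleRegion(ds), sep = ".")
    log <- maskLog(ds)
    newLog <- list()
    for (g in unique(grp)) {
        cols <- which(grp == g)
        sub <- x[, cols, drop = FALSE]
        n0 <- length(cols)
        maxMask <- floor(n0 / 2)
        for (i in seq_len(nrow(sub))) {
            v <- sub[i, ]
            nMasked <- 0
            repeat {
                ok <- which(!is.na(v))
                n <- length(ok)
                if (n < minGroupSize || nMasked >= maxMask) break
                m <- mean(v[ok]); s <- stats::sd(v[ok])
                if (!is.finite(s) || s == 0) break
                dev <- abs(v[ok] - m)
                j <- which.max(dev)
                if (dev[j] / s > grubbsCritical(n, alpha)) {
                    v[ok[j]] <- NA
                    nMasked <- nMasked + 1
                    newLog[[length(newLog) + 1]] <-
                        data.frame(gene = rownames(sub)[i],
                                   sample = colnames(sub)[ok[j]],
                                   reason = "grubbs")
                } else break
            }
            sub[i, ] <- v
        }
        x[, cols] <- sub
    }
    assay(ds, "exprs") <- x
    if (length(newLog))
        log <- rbind(log, do.call(rbind, newLog))
    metadata(ds)$maskLog <- log
    ds
}

#' Full preprocessing pipeline
#'
#' Applies, in order: normalization, region-wise sample-outlier removal,
#' re-normalization of the remaining samples, the detection filter (when
#' detection p-values are present), and Grubbs masking within genotype x
#' region groups.
#'
#' @param ds a [RegionExpressionSet-class].
#' @param log2Transform passed to [normalizeExpression()].
#' @param detectionAlpha,minFraction passed to [detectionFilter()].
#' @param grubbsAlpha passed to [grubbsFilter()].
#' @return list with `dataset` and `flaggedSamples`.
#' @export
preprocessDataset <- function(ds, log2Transform = FALSE, detectionAlpha = 0.05,
                              minFraction = 0.75, grubbsAlpha = 0.05) {
    ds <- normalizeExpression(ds, log2Transform = log2Transform)
    out <- removeOutlierSamples(ds)
    ds <- normalizeExpression(out$dataset, log2Transform = FALSE)
    if (!is.null(detectionP(ds)))
        ds <- detectionFilter(ds, detectionAlpha, minFraction)
    ds <- grubbsFilter(ds, alpha = grubbsAlpha)
    list(dataset = ds, flaggedSamples = out$flagged)
}
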