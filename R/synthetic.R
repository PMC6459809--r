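# Synthetic-data generator. Emulates the statistical structure of a
# 2-genotype x 7-brain-region x 12-replicate selective-breeding expression
# study: block-correlated gene modules driven by latent factors (some
# cell-type tagged, some housekeeping-like with flat region profiles),
# region-dependent baselines, genotype effects restricted to region subsets,
# planted outlier samples, and detection p-values. Known ground truth makes
# every downstream stage testable without external data.

#' Default brain-region vocabulary
#'
#' The seven interconnected regions of the study design: prefrontal cortex,
#' nucleus accumbens core and shell, bed nucleus of the stria terminalis,
#' basolateral and central amygdala, and ventral tegmental area.
#' @return character vector of region labels
#' @export
studyRegions <- function() c("PFC", "AcbC", "AcbSh", "BNST", "BLA", "CeA", "VTA")

# centered region profile: +amp on `up`, compensating negative shift elsewhere
.regionProfile <- function(regions, up = character(), amp = 0.3) {
    p <- stats::setNames(rep(0, length(regions)), regions)
    if (length(up)) {
        p[up] <- amp
        p[setdiff(regions, up)] <- -amp * length(up) / (length(regions) - length(up))
    }
    p
}

.effectVec <- function(regions, ...) {
    e <- stats::setNames(rep(0, length(regions)), regions)
    v <- c(...)
    e[names(v)] <- v
    e
}

#' Default module specification
#'
#' Eight modules, sizes 100-400 (2050 genes total), factor loading 0.8: two
#' neuronal modules with genotype effects concentrated in the extended
#' amygdala / mesolimbic regions, glial modules (astrocyte, oligodendrocyte,
#' microglia), and housekeeping-like modules with flat region profiles and no
#' genotype response. Region baselines use a modest 0.3 log2 amplitude and
#' genotype effects 0.5 log2, typical microarray-scale shifts.
#'
#' @param regions character vector of region labels.
#' @param loading latent-factor loading in (0,1) shared by all modules.
#' @param effectSize absolute log2 genotype shift used for responsive modules.
#' @param amp region-baseline amplitude (log2).
#' @return a list of per-module specifications (id, size, loading, cellType,
#'   regionProfile, genotypeEffect, crossLoading).
#' @export
defaultModuleSpec <- function(regions = studyRegions(), loading = 0.8,
                              effectSize = 0.5, amp = 0.3) {
    mk <- function(id, size, cellType, up, eff) {
        list(id = id, size = size, loading = loading,
             cellType = cellType,
             regionProfile = .regionProfile(regions, up, amp),
             genotypeEffect = eff, crossLoading = 0)
    }
    e <- effectSize
    z <- .effectVec(regions)
    list(
        mk("M1", 400, "neuron",          c("PFC", "BLA"),
           .effectVec(regions, BLA = e, CeA = e, AcbSh = e)),
        mk("M2", 350, "neuron",          c("AcbC", "AcbSh"),
           .effectVec(regions, AcbSh = -e, VTA = -e)),
        mk("M3", 300, "astrocyte",       c("CeA", "BNST"),
           .effectVec(regions, PFC = e)),
        mk("M4", 300, "oligodendrocyte", "VTA",            z),
        mk("M5", 250, NA_character_,     character(),      z),
        mk("M6", 200, "microglia",       c("AcbC", "VTA"),
           .effectVec(regions, AcbC = -e)),
        mk("M7", 150, NA_character_,     character(),      z),
        mk("M8", 100, NA_character_,     c("CeA", "AcbSh"), z))
}

#' Synthetic study configuration
#'
#' Collects every knob of the generator. The defaults are the study design
#' itself: 2 genotypes x 7 regions x 12 replicates = 168 samples, 3000 genes
#' of which 2050 sit in the eight default modules, noise sd 0.6, and two
#' planted outlier samples (control samples in AcbC and BNST, mirroring the
#' two samples the real study discarded).
#'
#' @param nGenotypes number of genotype groups (first is "selected").
#' @param regions character vector of region labels.
#' @param nReplicates replicates per genotype x region cell.
#' @param nGenes total gene count; genes beyond the module spec are
#'   uncorrelated background noise.
#' @param moduleSpec list of module specifications, see [defaultModuleSpec()].
#' @param noiseSd standard deviation of the additive Gaussian noise (log2
#'   scale); must be positive.
#' @param geneBaselineMean,geneBaselineSd mean and spread (log2) of the
#'   per-gene baseline expression level; the spread is what makes sample
#'   profiles mutually correlated, as in real array data.
#' @param nOutlierSamples number of planted outlier samples; an outlier is a
#'   degraded/mislabeled array emulated by permuting the sample's values
#'   across genes, which decorrelates it from its region's profile.
#' @param absentFraction fraction of background genes simulated as undetected
#'   in a random subset of regions.
#' @param seed integer seed; identical seed + config gives byte-identical
#'   output.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenotypes = 2, regions = studyRegions(),
                            nReplicates = 12, nGenes = 3000,
                            moduleSpec = defaultModuleSpec(regions),
                            noiseSd = 0.6, geneBaselineMean = 7,
                            geneBaselineSd = 2, nOutlierSamples = 2,
                            absentFraction = 0.05, seed = 1) {
    cfg <- list(nGenotypes = nGenotypes, regions = regions,
                nReplicates = nReplicates, nGenes = nGenes,
                moduleSpec = moduleSpec, noiseSd = noiseSd,
                geneBaselineMean = geneBaselineMean,
                geneBaselineSd = geneBaselineSd,
                nOutlierSamples = nOutlierSamples,
                absentFraction = absentFraction, seed = as.integer(seed))
    class(cfg) <- "SyntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

#' Validate a synthetic configuration
#'
#' Checks the structural invariants: module sizes must fit within `nGenes`
#' (the remainder is background), loadings strictly in (0,1), positive noise.
#' @param cfg a `SyntheticConfig` list.
#' @return the config, invisibly; errors describe the violation.
#' @export
validateSyntheticConfig <- function(cfg) {
    sizes <- vapply(cfg$moduleSpec, `[[`, numeric(1), "size")
    if (sum(sizes) > cfg$nGenes)
        stop("module sizes (", sum(sizes), ") exceed nGenes (", cfg$nGenes,
             "): inconsistent config")
    loadings <- vapply(cfg$moduleSpec, `[[`, numeric(1), "loading")
    if (length(loadings) && any(loadings <= 0 | loadings >= 1))
        stop("factor loadings must lie strictly between 0 and 1")
    if (cfg$noiseSd <= 0) stop("noiseSd must be > 0")
    if (cfg$nGenotypes < 2) stop("need at least 2 genotype groups")
    ids <- vapply(cfg$moduleSpec, `[[`, character(1), "id")
    if (anyDuplicated(ids)) stop("module ids must be unique")
    invisible(cfg)
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Gene g in module m gets expression
#' `geneBaseline + regionBaseline + genotypeEffect + loading * F(m, sample) +
#' noise`,
#' where F is a per-module, per-sample standard-normal latent factor. The
#' expected within-module Pearson correlation is therefore
#' `loading^2 / (loading^2 + noiseSd^2)` for flat modules. Background genes
#' are pure noise. Detection p-values are Beta(0.1, 10) for present
#' gene-regions and Uniform(0, 1) for absent ones.
#'
#' @param cfg a [syntheticConfig()] object.
#' @return list with `dataset` (a [RegionExpressionSet-class]) and `truth`
#'   (gene-to-module map, cell-type tags, per-gene per-region true effects,
#'   sample map, planted outliers, and the latent factor matrix).
#' @examples
#' sim <- generateDataset(syntheticConfig(nGenes = 300,
#'     moduleSpec = defaultModuleSpec()[8], nOutlierSamples = 0, seed = 7))
#' dim(exprValues(sim$dataset))
#' @export
generateDataset <- function(cfg) {
    validateSyntheticConfig(cfg)
    set.seed(cfg$seed)
    genotypes <- c("selected", "control")[seq_len(min(cfg$nGenotypes, 2))]
    if (cfg$nGenotypes > 2)
        genotypes <- c(genotypes, paste0("group", seq_len(cfg$nGenotypes - 2) + 2))
    samp <- expand.grid(rep = seq_len(cfg$nReplicates), genotype = genotypes,
                        region = cfg$regions, stringsAsFactors = FALSE)
    sampleIds <- sprintf("%s_%s_%02d", samp$region, samp$genotype, samp$rep)
    nS <- nrow(samp)
    nMod <- length(cfg$moduleSpec)
    sizes <- vapply(cfg$moduleSpec, `[[`, numeric(1), "size")
    nBackground <- cfg$nGenes - sum(sizes)

    geneIds <- sprintf("g%05d", seq_len(cfg$nGenes))
    geneModule <- rep("background", cfg$nGenes)
    cellType <- rep(NA_character_, cfg$nGenes)
    expr <- matrix(0, cfg$nGenes, nS, dimnames = list(geneIds, sampleIds))
    effects <- matrix(0, cfg$nGenes, length(cfg$regions),
                      dimnames = list(geneIds, cfg$regions))

    geneBaseline <- stats::rnorm(cfg$nGenes, cfg$geneBaselineMean,
                                 cfg$geneBaselineSd)

    # per-module latent factors, one sub-stream each in module order
    factors <- matrix(0, max(nMod, 1), nS,
                      dimnames = list(NULL, sampleIds))
    if (nMod) rownames(factors) <- vapply(cfg$moduleSpec, `[[`, character(1), "id")
    for (m in seq_len(nMod)) factors[m, ] <- stats::rnorm(nS)

    isSelected <- samp$genotype == "selected"
    offset <- 0
    for (m in seq_len(nMod)) {
        sp <- cfg$moduleSpec[[m]]
        idx <- offset + seq_len(sp$size)
        offset <- offset + sp$size
        geneModule[idx] <- sp$id
        cellType[idx] <- sp$cellType
        base <- sp$regionProfile[samp$region] +
            ifelse(isSelected, sp$genotypeEffect[samp$region], 0)
        common <- sp$loading * factors[m, ]
        if (!is.null(sp$crossLoading) && sp$crossLoading > 0 && nMod > 1)
            common <- common + sp$crossLoading *
                colSums(factors[-m, , drop = FALSE])
        signal <- matrix(base + common, sp$size, nS, byrow = TRUE)
        expr[idx, ] <- signal +
            matrix(stats::rnorm(sp$size * nS, sd = cfg$noiseSd), sp$size, nS)
        effects[idx, ] <- matrix(sp$genotypeEffect, sp$size, length(cfg$regions),
                                 byrow = TRUE)
    }
    if (nBackground > 0) {
        idx <- offset + seq_len(nBackground)
        expr[idx, ] <- matrix(stats::rnorm(nBackground * nS, sd = cfg$noiseSd),
                              nBackground, nS)
    }

    expr <- expr + geneBaseline

    # planted outlier samples: first control replicate of successive regions,
    # emulating degraded arrays by scrambling the profile across genes
    outliers <- character(0)
    if (cfg$nOutlierSamples > 0) {
        pref <- intersect(c("AcbC", "BNST"), cfg$regions)
        ordRegions <- c(pref, setdiff(cfg$regions, pref))
        pick <- ordRegions[((seq_len(cfg$nOutlierSamples) - 1) %%
                            length(ordRegions)) + 1]
        for (r in pick) {
            cand <- which(samp$region == r & !isSelected &
                          !(sampleIds %in% outliers))
            if (!length(cand)) cand <- which(!(sampleIds %in% outliers))
            outliers <- c(outliers, sampleIds[cand[1]])
        }
        for (o in outliers)
            expr[, o] <- expr[sample.int(cfg$nGenes), o]
    }

    # detection p-values: absent background gene-regions are Uniform(0,1)
    detection <- matrix(stats::rbeta(cfg$nGenes * nS, 0.1, 10), cfg$nGenes, nS,
                        dimnames = dimnames(expr))
    absent <- matrix(FALSE, cfg$nGenes, length(cfg$regions),
                     dimnames = list(geneIds, cfg$regions))
    if (cfg$absentFraction > 0 && nBackground > 0) {
        bg <- which(geneModule == "background")
        nAbsent <- round(cfg$absentFraction * length(bg))
        if (nAbsent > 0) {
            absentGenes <- sample(bg, nAbsent)
            for (g in absentGenes) {
                k <- sample.int(length(cfg$regions), 1)
                rs <- sample(cfg$regions, k)
                absent[g, rs] <- TRUE
                cols <- samp$region %in% rs
                detection[g, cols] <- stats::runif(sum(cols))
            }
        }
    }

    ds <- RegionExpressionSet(expr, genotype = samp$genotype,
                              region = samp$region, detection = detection)
    truth <- list(
        geneModule = stats::setNames(geneModule, geneIds),
        cellType = stats::setNames(cellType, geneIds),
        effects = effects,
        sampleMap = data.frame(sample = sampleIds, genotype = samp$genotype,
                               region = samp$region),
        outlierSamples = outliers,
        geneBaseline = stats::setNames(geneBaseline, geneIds),
        factors = factors,
        absent = absent,
        config = cfg)
    list(dataset = ds, truth = truth)
}

#' Build marker and decoy gene-set collections from ground truth
#'
#' One set per cell-type tag, containing the tagged modules' genes plus a
#' contamination fraction of random non-member genes, alongside random decoy
#' sets. Mirrors how curated cell-type marker lists behave: largely specific
#' but imperfect.
#'
#' @param truth ground truth from [generateDataset()].
#' @param contamination fraction of each marker set replaced-by-addition with
#'   random genes (0 gives the pure module gene lists).
#' @param nDecoys number of random decoy sets.
#' @param decoySize genes per decoy set.
#' @return named list of character vectors (a GMT-style collection); the
#'   `category` attribute distinguishes "cell_type" from "decoy" sets.
#' @export
generateMarkerSets <- function(truth, contamination = 0.2, nDecoys = 3,
                               decoySize = 100) {
    tags <- sort(unique(stats::na.omit(truth$cellType)))
    universe <- names(truth$geneModule)
    sets <- list()
    category <- character(0)
    for (tg in tags) {
        members <- universe[!is.na(truth$cellType) & truth$cellType == tg]
        nCont <- round(contamination * length(members))
        cont <- if (nCont > 0)
            sample(setdiff(universe, members), nCont) else character(0)
        sets[[paste0("markers_", tg)]] <- c(members, cont)
        category <- c(category, "cell_type")
    }
    for (i in seq_len(nDecoys)) {
        sets[[sprintf("decoy_%02d", i)]] <- sample(universe,
                                                   min(decoySize, length(universe)))
        category <- c(category, "decoy")
    }
    attr(sets, "category") <- stats::setNames(category, names(sets))
    sets
}

#' Generate a cross-species dataset pair with an ortholog map
#'
#' Two datasets sharing the module structure of `cfg`: the second is
#' regenerated with independent noise and latent factors (seed `seedB`) and
#' carries renamed gene ids. The returned two-column ortholog table links the
#' ids; a `dropFraction` of genes is removed from the map to emulate unmapped
#' orthologs.
#'
#' @param cfg a [syntheticConfig()] object (used for both species).
#' @param idPrefixes length-2 character; id prefixes for the two species.
#' @param dropFraction fraction of genes absent from the ortholog map.
#' @param seedB seed for the second species (same seed gives matrices
#'   identical up to id renaming).
#' @return list with `a`, `b` (each a [generateDataset()] result) and
#'   `orthologs` (data.frame source, target).
#' @export
generateSpeciesPair <- function(cfg, idPrefixes = c("mm_", "hs_"),
                                dropFraction = 0.1, seedB = cfg$seed + 1L) {
    a <- generateDataset(cfg)
    cfgB <- cfg
    cfgB$seed <- as.integer(seedB)
    b <- generateDataset(cfgB)
    renameGenes <- function(sim, prefix) {
        ids <- paste0(prefix, rownames(exprValues(sim$dataset)))
        rownames(sim$dataset) <- ids
        names(sim$truth$geneModule) <- ids
        names(sim$truth$cellType) <- ids
        rownames(sim$truth$effects) <- ids
        rownames(sim$truth$absent) <- ids
        sim
    }
    baseIds <- rownames(exprValues(a$dataset))
    a <- renameGenes(a, idPrefixes[1])
    b <- renameGenes(b, idPrefixes[2])
    map <- data.frame(source = paste0(idPrefixes[1], baseIds),
                      target = paste0(idPrefixes[2], baseIds))
    if (dropFraction > 0) {
        set.seed(cfg$seed + 104729L)  # independent sub-stream for the map
        keep <- sort(sample.int(nrow(map), round((1 - dropFraction) * nrow(map))))
        map <- map[keep, , drop = FALSE]
        rownames(map) <- NULL
    }
    list(a = a, b = b, orthologs = map)
}
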