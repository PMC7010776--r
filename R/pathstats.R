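#' Right-sided Mann-Whitney test
#'
#' One-sided p-value for the alternative "x is stochastically greater than
#' y". The exact U distribution is used for tie-free samples with
#' \code{length(x) + length(y) <= 20}; otherwise the tie-corrected normal
#' approximation with continuity correction. Degenerate input (a single
#' shared value across both samples) returns 0.5 with a warning.
#'
#' @param x,y numeric samples of length >= 2.
#' @return p-value in (0, 1].
#' @examples
#' mannWhitneyRight(c(3, 4), c(1, 2))   # exact: 1/choose(4, 2)
#' @export
mannWhitneyRight <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
        stop("both samples need at least two values", call. = FALSE)
    if (length(unique(c(x, y))) == 1L) {
        warning("degenerate samples: all values identical", call. = FALSE)
        return(0.5)
    }
    hasTies <- anyDuplicated(c(x, y)) > 0L
    exact <- !hasTies && (length(x) + length(y) <= 20L)
    suppressWarnings(
        stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                           correct = TRUE)$p.value)
}

#' Worst-case (least significant) p-value
#'
#' @param pValues non-empty numeric vector of p-values in (0, 1].
#' @return the maximum.
#' @export
worstCase <- function(pValues) {
    if (!length(pValues)) stop("no p-values supplied", call. = FALSE)
    if (any(pValues <= 0 | pValues > 1))
        stop("p-values must lie in (0, 1]", call. = FALSE)
    max(pValues)
}

#' Select related disease pairs from association and similarity tables
#'
#' Reproduces the related-pair selection filters: diseases with fewer than
#' \code{minGenes} network-mapped associated genes are removed; the
#' similarity cut is the \code{percentile} quantile of the positive,
#' retrievable pairwise similarities (unretrievable similarities enter the
#' table as 0 and are excluded from the percentile computation); kept
#' pairs have similarity strictly above the cut, strictly below 1 (to
#' avoid synonymous phenotype ids) and fewer than \code{maxOverlap}
#' overlapping associated genes.
#'
#' @param gda data.frame of gene-disease associations with columns
#'   \code{disease}, \code{gene} (first two columns used).
#' @param similarities data.frame with columns \code{diseaseA},
#'   \code{diseaseB}, \code{similarity}; NA similarities are treated as
#'   unretrievable (0).
#' @param x an [Interactome-class] used for gene mapping.
#' @param minGenes minimum mapped genes per disease (default 50).
#' @param maxOverlap strict upper bound on shared genes (default 10).
#' @param percentile similarity quantile for the cut (default 0.9).
#' @return data.frame with one row per selected pair: \code{diseaseA},
#'   \code{diseaseB}, \code{similarity}, \code{overlap}, \code{nGenesA},
#'   \code{nGenesB}. Empty (with a warning) when nothing qualifies.
#' @export
selectRelatedPairs <- function(gda, similarities, x, minGenes = 50L,
                               maxOverlap = 10L, percentile = 0.9) {
    stopifnot(is(x, "Interactome"))
    gda <- data.frame(disease = as.character(gda[[1L]]),
                      gene = as.character(gda[[2L]]),
                      stringsAsFactors = FALSE)
    net <- genes(x)
    sets <- lapply(split(gda$gene, gda$disease),
                   function(g) intersect(unique(g), net))
    sets <- sets[lengths(sets) >= minGenes]
    sim <- data.frame(diseaseA = as.character(similarities[[1L]]),
                      diseaseB = as.character(similarities[[2L]]),
                      similarity = as.numeric(similarities[[3L]]),
                      stringsAsFactors = FALSE)
    sim$similarity[is.na(sim$similarity)] <- 0
    cut <- stats::quantile(sim$similarity[sim$similarity > 0], percentile,
                           names = FALSE, type = 7)
    keep <- sim$diseaseA %in% names(sets) & sim$diseaseB %in% names(sets) &
        sim$similarity > cut & sim$similarity < 1
    sim <- sim[keep, , drop = FALSE]
    if (!nrow(sim)) {
        warning("no disease pair passes the filters", call. = FALSE)
        return(data.frame(diseaseA = character(0), diseaseB = character(0),
                          similarity = numeric(0), overlap = integer(0),
                          nGenesA = integer(0), nGenesB = integer(0)))
    }
    ov <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])),
                 sim$diseaseA, sim$diseaseB)
    sim$overlap <- as.integer(ov)
    sim <- sim[sim$overlap < maxOverlap, , drop = FALSE]
    sim$nGenesA <- lengths(sets[sim$diseaseA])
    sim$nGenesB <- lengths(sets[sim$diseaseB])
    sim <- sim[order(sim$diseaseA, sim$diseaseB), , drop = FALSE]
    rownames(sim) <- NULL
    if (!nrow(sim)) warning("no disease pair passes the filters", call. = FALSE)
    sim
}

#' Select unrelated phenotypes by mapped gene-set size
#'
#' Keeps the phenotypes whose network-mapped gene sets fall in an
#' inclusive size range (matched to the scale of typical curated seed gene
#' sets).
#'
#' @param gda gene-disease association data.frame (columns disease, gene).
#' @param x an [Interactome-class].
#' @param sizeRange inclusive bounds, default \code{c(25, 35)}.
#' @return named list of mapped gene sets.
#' @export
selectUnrelatedPhenotypes <- function(gda, x, sizeRange = c(25L, 35L)) {
    stopifnot(is(x, "Interactome"))
    gda <- data.frame(disease = as.character(gda[[1L]]),
                      gene = as.character(gda[[2L]]),
                      stringsAsFactors = FALSE)
    net <- genes(x)
    sets <- lapply(split(gda$gene, gda$disease),
                   function(g) intersect(unique(g), net))
    sets[lengths(sets) >= sizeRange[[1L]] & lengths(sets) <= sizeRange[[2L]]]
}

#' Specificity of a disease pair's path similarity under module randomization
#'
#' Draws \code{nRandom} degree-preserved random replacements of the two
#' gene sets, selects each random pair's "random flow-central paths" (the
#' geodesics between the random sets whose intermediates pass the original
#' FCS filter), and compares the original pair's sequential similarities
#' against each random pair's by a right-sided Mann-Whitney test.
#' Replicates with fewer than two qualifying random paths are skipped with
#' a warning.
#'
#' @param x an [Interactome-class].
#' @param bins a [DegreeBins-class].
#' @param genesA,genesB the original disease gene sets.
#' @param fcsResult the original pair's [FlowCentralityResult-class]; its
#'   scores also filter the random pairs' paths.
#' @param corpus an [AnnotationCorpus-class].
#' @param originalSS sequential similarities of the original pair's
#'   flow-central paths.
#' @param nRandom number of random module pairs (default 100).
#' @param fcsThreshold,minSupport,relaxed passed to [selectFcPaths()].
#' @param perPairCap geodesic cap per pair during enumeration.
#' @param seed optional integer seed.
#' @return numeric vector of p-values (one per non-skipped replicate).
#' @export
specificityRandomization <- function(x, bins, genesA, genesB, fcsResult,
                                     corpus, originalSS, nRandom = 100L,
                                     fcsThreshold = 2, minSupport = 0L,
                                     relaxed = FALSE, perPairCap = 100L,
                                     seed = NULL) {
    stopifnot(is(x, "Interactome"), is(bins, "DegreeBins"))
    if (length(originalSS) < 2L)
        stop("need at least two original similarity values", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    out <- numeric(0)
    for (i in seq_len(nRandom)) {
        ra <- sampleDegreePreserved(bins, genesA)
        rb <- sampleDegreePreserved(bins, genesB)
        pool <- enumerateSeedShortestPaths(x, ra, rb, perPairCap = perPairCap)
        rfc <- selectFcPaths(pool, fcsResult, fcsThreshold = fcsThreshold,
                             minSupport = minSupport, relaxed = relaxed)
        ss <- poolSequentialSimilarity(rfc, corpus)
        if (length(ss) < 2L) {
            warning(sprintf(
                "replicate %d skipped: fewer than two qualifying random paths",
                i), call. = FALSE)
            next
        }
        out <- c(out, mannWhitneyRight(originalSS, ss))
    }
    out
}
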