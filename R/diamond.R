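#' Connectivity significance of a candidate node
#'
#' Hypergeometric p-value of observing at least \code{ks} of a node's
#' \code{k} links inside a module of \code{s} genes, in a network of
#' \code{N} genes:
#' \deqn{p = \sum_{k_i = k_s}^{k} \binom{s}{k_i}\binom{N-s}{k-k_i} \Big/ \binom{N}{k}}
#' This is the per-iteration score driving DIAMOnD module expansion.
#'
#' @param k node degree.
#' @param ks number of the node's edges into the current module.
#' @param s current module size.
#' @param N total number of genes in the network.
#' @return p-value in (0, 1].
#' @examples
#' connectivityPvalue(k = 2, ks = 2, s = 4, N = 10)  # 6/45
#' @export
connectivityPvalue <- function(k, ks, s, N) {
    if (any(ks < 0) || any(ks > k) || any(k > N) || any(s < 0) || any(s >= N))
        stop("require 0 <= ks <= k <= N and 0 <= s < N", call. = FALSE)
    if (any(ks > pmin(k, s)))
        stop("ks cannot exceed min(k, s)", call. = FALSE)
    stats::phyper(ks - 1, s, N - s, k, lower.tail = FALSE)
}

#' Expand a seed gene set into a disease module (DIAMOnD)
#'
#' Iterative connectivity-significance expansion: at every iteration each
#' node adjacent to the current module is scored with
#' [connectivityPvalue()] and the most significantly connected node is
#' appended. Ties are broken deterministically: lowest p-value, then
#' highest \code{ks}, then lowest degree, then lexicographically smallest
#' gene identifier.
#'
#' @param x an [Interactome-class].
#' @param seedGenes character vector of seed genes (must be in the network).
#' @param nIter number of genes to add. If the module boundary empties
#'   first, expansion stops early with a warning.
#' @return a [DiseaseModule-class].
#' @export
diamondExpand <- function(x, seedGenes, nIter) {
    stopifnot(is(x, "Interactome"))
    if (!length(seedGenes)) stop("seed gene set is empty", call. = FALSE)
    seedGenes <- unique(as.character(seedGenes))
    nm <- genes(x)
    sidx <- match(seedGenes, nm)
    if (anyNA(sidx))
        stop("seed genes absent from the network: ",
             paste(seedGenes[is.na(sidx)], collapse = ", "), call. = FALSE)
    nIter <- as.integer(nIter)
    if (nIter < 0L) stop("nIter must be >= 0", call. = FALSE)

    adj <- .adj1(x)
    N <- length(adj)
    deg <- lengths(adj)
    inMod <- logical(N)
    inMod[sidx] <- TRUE
    ks <- tabulate(unlist(adj[sidx], use.names = FALSE), nbins = N)

    rank <- integer(0); gene <- character(0); kk <- integer(0)
    kks <- integer(0); ss <- integer(0); pv <- numeric(0)
    for (it in seq_len(nIter)) {
        cand <- which(!inMod & ks > 0L)
        if (!length(cand)) {
            warning(sprintf(
                "module boundary exhausted after %d of %d iterations",
                it - 1L, nIter), call. = FALSE)
            break
        }
        s <- sum(inMod)
        p <- stats::phyper(ks[cand] - 1L, s, N - s, deg[cand],
                           lower.tail = FALSE)
        best <- order(p, -ks[cand], deg[cand], nm[cand])[1L]
        pick <- cand[best]
        rank <- c(rank, it); gene <- c(gene, nm[pick])
        kk <- c(kk, deg[pick]); kks <- c(kks, ks[pick])
        ss <- c(ss, s); pv <- c(pv, p[best])
        inMod[pick] <- TRUE
        nb <- adj[[pick]]
        ks[nb] <- ks[nb] + 1L
    }
    new("DiseaseModule", seeds = seedGenes,
        added = data.frame(rank = rank, gene = gene, k = kk, ks = kks,
                           s = ss, pvalue = pv, stringsAsFactors = FALSE))
}

#' Choose a module size by reference gene-set enrichment
#'
#' Runs DIAMOnD for \code{maxIter} iterations and, after each one, computes
#' the one-sided hypergeometric over-representation p-value of a reference
#' gene set (e.g. GWAS-significant genes, pre-filtered to exclude the
#' seeds) among the genes added so far. The universe is the network minus
#' the seed genes. The selected size is the iteration minimizing the curve
#' (smallest iteration on ties).
#'
#' @param x an [Interactome-class].
#' @param seedGenes character vector of seed genes.
#' @param referenceGenes character vector of reference genes; genes absent
#'   from the network are dropped, genes overlapping the seeds are removed.
#' @param maxIter number of expansion iterations to score.
#' @return list with elements \code{module} (the full
#'   [DiseaseModule-class] of \code{maxIter} additions), \code{curve}
#'   (data.frame iteration/overlap/pvalue) and \code{nStar} (selected
#'   iteration cutoff).
#' @export
selectModuleSize <- function(x, seedGenes, referenceGenes, maxIter) {
    stopifnot(is(x, "Interactome"))
    seedGenes <- unique(as.character(seedGenes))
    ref <- setdiff(unique(as.character(referenceGenes)), seedGenes)
    ref <- intersect(ref, genes(x))
    if (!length(ref))
        stop("no reference genes map to the network", call. = FALSE)
    mod <- diamondExpand(x, seedGenes, maxIter)
    addedGenes <- mod@added$gene
    nAdd <- length(addedGenes)
    if (!nAdd) stop("no genes could be added to the module", call. = FALSE)
    universe <- setdiff(genes(x), seedGenes)
    white <- length(ref)
    Nu <- length(universe)
    hit <- cumsum(addedGenes %in% ref)
    it <- seq_len(nAdd)
    pv <- stats::phyper(hit - 1, white, Nu - white, it, lower.tail = FALSE)
    nStar <- which.min(pv)
    list(module = mod,
         curve = data.frame(iteration = it, overlap = hit, pvalue = pv),
         nStar = nStar)
}

#' Empirical significance of the overlap between two disease modules
#'
#' Generates random module pairs with [randomizeModule()] and returns the
#' plus-one corrected fraction of pairs whose overlap is at least the
#' observed one: \code{(1 + #[overlap_rand >= overlap_obs]) / (1 + nRand)}.
#'
#' @param x an [Interactome-class].
#' @param moduleA,moduleB [DiseaseModule-class] objects.
#' @param nRand number of random module pairs (default 1000).
#' @param bins a [DegreeBins-class]; built on the fly when NULL.
#' @param mode randomization mode passed to [randomizeModule()].
#' @param seed integer seed for reproducibility.
#' @return list with \code{pvalue}, \code{observed} overlap size and the
#'   vector of \code{nullOverlaps}.
#' @export
moduleOverlapPvalue <- function(x, moduleA, moduleB, nRand = 1000L,
                                bins = NULL, mode = c("diamond", "degree_only"),
                                seed = NULL) {
    stopifnot(is(x, "Interactome"), is(moduleA, "DiseaseModule"),
              is(moduleB, "DiseaseModule"))
    mode <- match.arg(mode)
    nRand <- as.integer(nRand)
    if (nRand < 1L) stop("nRand must be >= 1", call. = FALSE)
    if (is.null(bins)) bins <- buildDegreeBins(x)
    if (!is.null(seed)) set.seed(seed)
    obs <- length(intersect(genes(moduleA), genes(moduleB)))
    nullOv <- integer(nRand)
    for (i in seq_len(nRand)) {
        ra <- randomizeModule(x, bins, moduleA, mode = mode)
        rb <- randomizeModule(x, bins, moduleB, mode = mode)
        nullOv[[i]] <- length(intersect(ra, rb))
    }
    list(pvalue = (1 + sum(nullOv >= obs)) / (1 + nRand),
         observed = obs, nullOverlaps = nullOv)
}
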