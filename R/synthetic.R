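#' Specification of a planted-bridge benchmark graph
#'
#' Describes a random graph with two dense disease-like modules whose only
#' inter-module connections run through a small set of designated bridge
#' nodes — the topology in which a module-to-module betweenness measure
#' should single out the bridges. A sparse background is attached to the
#' source module only, so no shortcut bypasses the bridges, and one
#' degree-matched non-bridge control hub is wired into the source module
#' for specificity checks.
#'
#' @param nA,nB module sizes (default 60 each).
#' @param pIn within-module edge probability (default 0.15).
#' @param nBackground background nodes (default 200).
#' @param pBackground background edge probability (default 0.02).
#' @param nBridge number of bridge nodes (default 3).
#' @param bridgeDegree edges from each bridge into each module (default
#'   8).
#' @param nSeeds seed genes drawn per module (default 10).
#' @return a list of class \code{"plantedBridgeSpec"}.
#' @export
plantedBridgeSpec <- function(nA = 60L, nB = 60L, pIn = 0.15,
                              nBackground = 200L, pBackground = 0.02,
                              nBridge = 3L, bridgeDegree = 8L,
                              nSeeds = 10L) {
    spec <- list(nA = as.integer(nA), nB = as.integer(nB), pIn = pIn,
                 nBackground = as.integer(nBackground),
                 pBackground = pBackground, nBridge = as.integer(nBridge),
                 bridgeDegree = as.integer(bridgeDegree),
                 nSeeds = as.integer(nSeeds))
    stopifnot(spec$nA >= 2L, spec$nB >= 2L, spec$nBridge >= 1L,
              spec$bridgeDegree >= 1L, spec$nSeeds >= 1L,
              spec$nSeeds <= spec$nA, spec$nSeeds <= spec$nB,
              spec$bridgeDegree <= spec$nA, spec$bridgeDegree <= spec$nB)
    class(spec) <- "plantedBridgeSpec"
    spec
}

## internal: Erdos-Renyi edges among a node vector
.erEdges <- function(nodes, p) {
    n <- length(nodes)
    if (n < 2L || p <= 0) return(NULL)
    pairs <- utils::combn(n, 2L)
    pick <- stats::runif(ncol(pairs)) < p
    if (!any(pick)) return(NULL)
    cbind(nodes[pairs[1L, pick]], nodes[pairs[2L, pick]])
}

#' Generate a planted-bridge benchmark graph
#'
#' Realizes a [plantedBridgeSpec()]: two Erdos-Renyi modules, a sparse
#' background attached to the source module, bridge nodes carrying every
#' inter-module connection, and a degree-matched control hub wired only
#' into the source module. Connectivity is enforced by rejection sampling
#' (up to 50 regenerations) rather than edge augmentation, to avoid
#' biasing the degree structure. All randomness is a pure function of
#' \code{seed}.
#'
#' @param spec a [plantedBridgeSpec()].
#' @param seed integer seed.
#' @return list with \code{interactome} (an [Interactome-class]),
#'   \code{seedsA}, \code{seedsB} (random module subsets), \code{bridges}
#'   (the planted mediator genes), \code{control} (the degree-matched
#'   non-bridge hub), and \code{moduleA}, \code{moduleB} (full module
#'   memberships).
#' @export
makePlantedBridgeGraph <- function(spec = plantedBridgeSpec(), seed = 1L) {
    stopifnot(inherits(spec, "plantedBridgeSpec"))
    set.seed(seed)
    aN <- sprintf("A%03d", seq_len(spec$nA))
    bN <- sprintf("B%03d", seq_len(spec$nB))
    gN <- if (spec$nBackground > 0L)
              sprintf("G%03d", seq_len(spec$nBackground)) else character(0)
    brN <- sprintf("X%02d", seq_len(spec$nBridge))
    ctrl <- "C01"
    for (try in seq_len(50L)) {
        edges <- rbind(
            .erEdges(aN, spec$pIn),
            .erEdges(bN, spec$pIn),
            .erEdges(gN, spec$pBackground))
        # every background node hooks into the source module once
        if (length(gN))
            edges <- rbind(edges, cbind(gN, sample(aN, length(gN),
                                                   replace = TRUE)))
        for (br in brN)
            edges <- rbind(edges,
                           cbind(br, sample(aN, spec$bridgeDegree)),
                           cbind(br, sample(bN, spec$bridgeDegree)))
        # degree-matched control: same total degree, all edges into module A
        edges <- rbind(edges,
                       cbind(ctrl, sample(aN, min(2L * spec$bridgeDegree,
                                                  spec$nA))))
        g <- igraph::simplify(
            igraph::graph_from_edgelist(edges, directed = FALSE))
        if (igraph::is_connected(g) &&
            igraph::vcount(g) == length(aN) + length(bN) + length(gN) +
                length(brN) + 1L) {
            net <- new("Interactome", graph = g)
            return(list(interactome = net,
                        seedsA = sort(sample(aN, spec$nSeeds)),
                        seedsB = sort(sample(bN, spec$nSeeds)),
                        bridges = brN, control = ctrl,
                        moduleA = aN, moduleB = bN))
        }
    }
    stop("could not generate a connected graph in 50 attempts", call. = FALSE)
}

#' Generate a synthetic annotation corpus with optional planted paths
#'
#' Builds a random rooted layered DAG and annotates genes to it. Each
#' background gene receives \code{annPerGene} random terms drawn from the
#' non-leaf layers. Every planted path is assigned one term from the
#' deepest layer — never used for background annotation, hence of high
#' information content — annotated to all its genes, so adjacent genes of
#' a planted path share a deep term and obtain elevated best-match-average
#' similarity. With no planted paths the annotations carry no path-aligned
#' structure at all. Deterministic under \code{seed}.
#'
#' @param genes character vector of all gene identifiers.
#' @param plantedPaths list of character vectors (paths to plant); may be
#'   empty.
#' @param nTerms total number of terms (default 60).
#' @param depth number of layers below the root (default 4; must be >= 2).
#' @param annPerGene background annotations per gene (default 3).
#' @param seed integer seed.
#' @return an [AnnotationCorpus-class].
#' @export
makeSyntheticOntology <- function(genes, plantedPaths = list(),
                                  nTerms = 60L, depth = 4L,
                                  annPerGene = 3L, seed = 1L) {
    nTerms <- as.integer(nTerms); depth <- as.integer(depth)
    if (nTerms < depth + 1L || depth < 2L)
        stop("need nTerms >= depth + 1 and depth >= 2", call. = FALSE)
    set.seed(seed)
    root <- "T000"
    inner <- nTerms - 1L
    layerOf <- sort(rep_len(seq_len(depth), inner))
    ids <- sprintf("T%03d", seq_len(inner))
    parents <- stats::setNames(vector("list", nTerms), c(root, ids))
    parents[[root]] <- character(0)
    for (i in seq_len(inner)) {
        lay <- layerOf[[i]]
        pool <- if (lay == 1L) root else ids[layerOf == lay - 1L]
        nPar <- min(length(pool), sample.int(2L, 1L))
        parents[[ids[[i]]]] <- sample(pool, nPar)
    }
    shallow <- ids[layerOf < depth]
    deep <- ids[layerOf == depth]
    if (length(shallow) < annPerGene)
        stop("too few non-leaf terms for the requested annotations per gene",
             call. = FALSE)
    ann <- data.frame(
        gene = rep(genes, each = annPerGene),
        term = unlist(lapply(genes, function(g) sample(shallow, annPerGene))),
        stringsAsFactors = FALSE)
    if (length(plantedPaths)) {
        for (j in seq_along(plantedPaths)) {
            tau <- deep[[(j - 1L) %% length(deep) + 1L]]
            pg <- plantedPaths[[j]]
            ann <- rbind(ann, data.frame(gene = pg,
                                         term = rep(tau, length(pg)),
                                         stringsAsFactors = FALSE))
        }
    }
    buildCorpus(parents, ann)
}

#' Generate a synthetic expression matrix with a planted latent factor
#'
#' Genes on planted paths load on a single shared latent factor,
#' \deqn{x_g = \lambda f + \sqrt{1 - \lambda^2}\,\sigma\,\varepsilon_g,}
#' while background genes are pure noise \eqn{x_g = \sigma \varepsilon_g};
#' each gene is emitted as \code{probesPerGene} probes with independent
#' probe noise of sd \code{0.25 * noiseSd}. With \code{factorLoading = 1}
#' and \code{noiseSd = 0} all planted probes equal the factor exactly;
#' with \code{factorLoading = 0} planted and background genes are
#' indistinguishable. Samples are split evenly into a disease and a
#' control class; the factor acts in both, emulating interaction cascades
#' active in either state. Deterministic under \code{seed}.
#'
#' @param genes character vector of gene identifiers.
#' @param plantedPaths list of character vectors; their union loads on the
#'   factor.
#' @param nSamples number of samples (>= 4; default 40).
#' @param factorLoading loading in [0, 1] (default 0.7).
#' @param noiseSd residual sd (default 1).
#' @param probesPerGene probes emitted per gene (default 2).
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment} with assay \code{"exprs"},
#'   \code{rowData$gene} and \code{colData$class}.
#' @export
makeSyntheticExpression <- function(genes, plantedPaths = list(),
                                    nSamples = 40L, factorLoading = 0.7,
                                    noiseSd = 1, probesPerGene = 2L,
                                    seed = 1L) {
    nSamples <- as.integer(nSamples)
    if (nSamples < 4L) stop("need at least 4 samples", call. = FALSE)
    if (factorLoading < 0 || factorLoading > 1)
        stop("factorLoading must lie in [0, 1]", call. = FALSE)
    set.seed(seed)
    planted <- unique(unlist(plantedPaths, use.names = FALSE))
    f <- stats::rnorm(nSamples)
    resid <- sqrt(1 - factorLoading^2) * noiseSd
    nP <- as.integer(probesPerGene)
    mat <- matrix(0, nrow = length(genes) * nP, ncol = nSamples)
    probe <- character(length(genes) * nP)
    geneOf <- character(length(genes) * nP)
    r <- 0L
    for (g in genes) {
        x <- if (g %in% planted)
                 factorLoading * f + resid * stats::rnorm(nSamples)
             else noiseSd * stats::rnorm(nSamples)
        for (p in seq_len(nP)) {
            r <- r + 1L
            mat[r, ] <- x + 0.25 * noiseSd * stats::rnorm(nSamples)
            probe[[r]] <- sprintf("%s.p%d", g, p)
            geneOf[[r]] <- g
        }
    }
    rownames(mat) <- probe
    colnames(mat) <- sprintf("S%03d", seq_len(nSamples))
    half <- nSamples %/% 2L
    cls <- c(rep("disease", half), rep("control", nSamples - half))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        rowData = S4Vectors::DataFrame(gene = geneOf),
        colData = S4Vectors::DataFrame(class = cls,
                                       row.names = colnames(mat)))
}
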