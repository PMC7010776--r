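#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib flowCentral, .registration = TRUE
NULL

#' Interactome: a cleaned protein-protein interaction network
#'
#' Thin S4 wrapper around an undirected \pkg{igraph} object holding the
#' protein-protein interaction network used as the universe for all
#' statistics. The constructor guarantees a simple (no self-loops, no
#' duplicate edges), undirected graph restricted to its largest connected
#' component, with gene identifiers as vertex names.
#'
#' @slot graph an undirected, simple, connected \code{igraph} object with a
#'   \code{name} vertex attribute.
#'
#' @seealso [loadEdgeList()], [Interactome()]
#' @export
setClass("Interactome", slots = c(graph = "ANY"))

setValidity("Interactome", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
    if (igraph::is_directed(g)) return("graph must be undirected")
    if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
    if (igraph::vcount(g) > 0L && !igraph::is_connected(g))
        return("graph must be connected (a single component)")
    if (is.null(igraph::V(g)$name)) return("vertices must be named")
    TRUE
})

#' DegreeBins: a contiguous-degree partition of network nodes
#'
#' Partition of the interactome nodes into contiguous degree ranges, each
#' holding at least a configurable minimum number of nodes. Degree bins are
#' the sampling frame behind every degree-preserved randomization in the
#' package: a node is always replaced by a node from its own bin.
#'
#' @slot bins list of character vectors, one per bin, in increasing degree
#'   order; together they partition the node set.
#' @slot binOf named integer vector mapping every gene to its bin index.
#' @slot minBinSize the minimum occupancy the bins were built with.
#'
#' @seealso [buildDegreeBins()]
#' @export
setClass("DegreeBins",
    slots = c(bins = "list", binOf = "integer", minBinSize = "integer"))

setValidity("DegreeBins", function(object) {
    all_genes <- unlist(object@bins, use.names = FALSE)
    if (anyDuplicated(all_genes)) return("bins must be disjoint")
    if (length(all_genes) != length(object@binOf))
        return("binOf must cover exactly the binned nodes")
    if (!setequal(all_genes, names(object@binOf)))
        return("binOf names must match the binned nodes")
    for (i in seq_along(object@bins))
        if (!all(object@binOf[object@bins[[i]]] == i))
            return("binOf is inconsistent with bins")
    TRUE
})

#' DiseaseModule: seed genes plus DIAMOnD-ranked additions
#'
#' A disease module as produced by iterative connectivity-significance
#' expansion: the curated seed genes plus an ordered list of added genes,
#' each with its per-iteration degree, module connectivity and
#' hypergeometric p-value.
#'
#' @slot seeds character vector of seed gene identifiers.
#' @slot added data.frame with one row per expansion iteration and columns
#'   \code{rank}, \code{gene}, \code{k} (degree), \code{ks} (edges into the
#'   module at evaluation), \code{s} (module size at evaluation) and
#'   \code{pvalue}.
#'
#' @seealso [diamondExpand()]
#' @export
setClass("DiseaseModule", slots = c(seeds = "character", added = "data.frame"))

setValidity("DiseaseModule", function(object) {
    a <- object@added
    need <- c("rank", "gene", "k", "ks", "s", "pvalue")
    if (!all(need %in% names(a))) return("added must have columns rank, gene, k, ks, s, pvalue")
    if (anyDuplicated(object@seeds)) return("seeds must be unique")
    if (anyDuplicated(a$gene)) return("added genes must be unique")
    if (length(intersect(object@seeds, a$gene))) return("seeds and added genes must be disjoint")
    if (nrow(a) && (any(a$pvalue <= 0) || any(a$pvalue > 1)))
        return("iteration p-values must lie in (0, 1]")
    if (nrow(a) && any(a$ks > pmin(a$k, a$s))) return("ks must be <= min(k, s)")
    TRUE
})

#' FlowCentralityResult: per-node flow centrality and its significance
#'
#' Per-node raw flow centrality, null mean/sd under module randomization,
#' the z-score flow centrality score (FCS), a right-tailed empirical
#' p-value, and the number of source-target geodesics supporting the node.
#'
#' @slot table data.frame with columns \code{gene}, \code{fc},
#'   \code{muNull}, \code{sigmaNull}, \code{fcs}, \code{empP},
#'   \code{support}. When the null sd is zero, \code{fcs} is 0 if the
#'   observed value equals the null mean and a signed \code{Inf} sentinel
#'   otherwise; consumers should then fall back on \code{empP}.
#' @slot nSamples number of null module pairs.
#' @slot mode null-module generation mode, \code{"degree_only"} or
#'   \code{"diamond"}.
#' @slot seed integer seed the null ensemble was drawn with (NA if none).
#' @slot pooledNull logical; TRUE when the null mean/sd were pooled across
#'   nodes rather than computed per node.
#'
#' @seealso [flowCentralityScore()]
#' @export
setClass("FlowCentralityResult",
    slots = c(table = "data.frame", nSamples = "integer", mode = "character",
              seed = "integer", pooledNull = "logical"))

setValidity("FlowCentralityResult", function(object) {
    need <- c("gene", "fc", "muNull", "sigmaNull", "fcs", "empP", "support")
    if (!all(need %in% names(object@table)))
        return("table must have columns gene, fc, muNull, sigmaNull, fcs, empP, support")
    tb <- object@table
    if (any(tb$fc < 0)) return("fc must be non-negative")
    if (any(tb$empP <= 0 | tb$empP > 1)) return("empP must lie in (0, 1]")
    if (any(tb$support < 0)) return("support must be non-negative")
    TRUE
})

#' PathPool: a collection of network paths
#'
#' An ordered collection of network paths, each an ordered sequence of at
#' least two unique, consecutively adjacent genes. Pools carry a provenance
#' tag: \code{"fc"} for selected flow-central paths, \code{"shortest"} for
#' raw seed-to-seed geodesics, \code{"typeA"} for length-preserved
#' self-avoiding random walks, \code{"typeB"} for endpoint-preserved
#' uniform geodesic draws, and \code{"seed_to_set"} for seed-to-phenotype
#' geodesic samples.
#'
#' @slot paths list of character vectors (gene sequences).
#' @slot provenance one of "shortest", "fc", "typeA", "typeB", "seed_to_set".
#' @slot meta list of generation metadata (seed, histogram, caps, ...).
#'
#' @seealso [enumerateSeedShortestPaths()], [selectFcPaths()],
#'   [sampleTypeA()], [sampleTypeB()]
#' @export
setClass("PathPool",
    slots = c(paths = "list", provenance = "character", meta = "list"))

setValidity("PathPool", function(object) {
    ok <- c("shortest", "fc", "typeA", "typeB", "seed_to_set")
    if (length(object@provenance) != 1L || !object@provenance %in% ok)
        return(sprintf("provenance must be one of %s", paste(ok, collapse = ", ")))
    for (p in object@paths) {
        if (!is.character(p) || length(p) < 2L)
            return("each path must be a character vector of length >= 2")
        if (anyDuplicated(p)) return("path genes must be unique")
    }
    TRUE
})

#' AnnotationCorpus: ontology DAG, gene annotations and information content
#'
#' A rooted, acyclic is_a term hierarchy together with direct gene
#' annotations, their ancestor-propagated closure and per-term information
#' content \code{ic(t) = -log(n_t / n_root)}, where counts are taken after
#' propagation and each term is normalized by its own namespace root.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents list mapping each term to its is_a parents (character).
#' @slot ancestors list mapping each term to all its ancestors including
#'   itself.
#' @slot direct list mapping genes to their directly annotated terms.
#' @slot propagated list mapping genes to their ancestor-closed term sets.
#' @slot ic named numeric vector of information content values (>= 0).
#' @slot roots character vector of root terms (no is_a parents).
#'
#' @seealso [buildCorpus()], [resnikSim()], [bmaSimilarity()]
#' @export
setClass("AnnotationCorpus",
    slots = c(terms = "character", parents = "list", ancestors = "list",
              direct = "list", propagated = "list", ic = "numeric",
              roots = "character"))

setValidity("AnnotationCorpus", function(object) {
    if (!setequal(object@terms, names(object@parents)))
        return("parents must be keyed by terms")
    if (any(object@ic < -1e-12)) return("information content must be non-negative")
    if (length(object@roots) &&
        any(abs(object@ic[object@roots]) > 1e-12, na.rm = TRUE))
        return("root terms must have zero information content")
    TRUE
})

## ---- generics -------------------------------------------------------------

#' Gene identifiers of an object
#'
#' For an [Interactome-class] the vertex names; for a [DiseaseModule-class]
#' the seed genes followed by the DIAMOnD-added genes in rank order; for a
#' [PathPool-class] the union of genes on its paths.
#'
#' @param x the object.
#' @return character vector of gene identifiers.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname genes
#' @export
setMethod("genes", "Interactome", function(x) igraph::V(x@graph)$name)

#' @rdname genes
#' @export
setMethod("genes", "DiseaseModule", function(x) c(x@seeds, x@added$gene))

#' @rdname genes
#' @export
setMethod("genes", "PathPool",
    function(x) unique(unlist(x@paths, use.names = FALSE)))

#' Seed genes of a disease module
#' @param x a [DiseaseModule-class].
#' @return character vector of seed genes.
#' @export
setGeneric("seeds", function(x) standardGeneric("seeds"))

#' @rdname seeds
#' @export
setMethod("seeds", "DiseaseModule", function(x) x@seeds)

#' Paths held by a pool
#' @param x a [PathPool-class].
#' @return list of character vectors.
#' @export
setGeneric("paths", function(x) standardGeneric("paths"))

#' @rdname paths
#' @export
setMethod("paths", "PathPool", function(x) x@paths)

#' Flow centrality result table
#' @param x a [FlowCentralityResult-class].
#' @return the per-node data.frame.
#' @export
setGeneric("fcTable", function(x) standardGeneric("fcTable"))

#' @rdname fcTable
#' @export
setMethod("fcTable", "FlowCentralityResult", function(x) x@table)

#' @export
setMethod("length", "PathPool", function(x) length(x@paths))

#' Underlying igraph object of an Interactome
#' @param x an [Interactome-class].
#' @return the igraph object.
#' @export
interactomeGraph <- function(x) {
    stopifnot(is(x, "Interactome"))
    x@graph
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "Interactome", function(object) {
    g <- object@graph
    cat(sprintf("Interactome: %d genes, %d interactions\n",
                igraph::vcount(g), igraph::ecount(g)))
})

setMethod("show", "DegreeBins", function(object) {
    cat(sprintf("DegreeBins: %d bins over %d nodes (min occupancy %d)\n",
                length(object@bins), length(object@binOf), object@minBinSize))
})

setMethod("show", "DiseaseModule", function(object) {
    cat(sprintf("DiseaseModule: %d seeds + %d added genes (size %d)\n",
                length(object@seeds), nrow(object@added),
                length(object@seeds) + nrow(object@added)))
})

setMethod("show", "FlowCentralityResult", function(object) {
    tb <- object@table
    cat(sprintf(
        "FlowCentralityResult: %d nodes, %d null samples (mode '%s')\n",
        nrow(tb), object@nSamples, object@mode))
    top <- utils::head(tb[order(-tb$fcs), c("gene", "fc", "fcs", "empP")], 5L)
    cat("Top nodes by FCS:\n")
    print(top, row.names = FALSE)
})

setMethod("show", "PathPool", function(object) {
    lens <- lengths(object@paths)
    cat(sprintf("PathPool (%s): %d paths, lengths %s\n",
                object@provenance, length(object@paths),
                if (length(lens)) paste0(min(lens), "-", max(lens)) else "-"))
})

setMethod("show", "AnnotationCorpus", function(object) {
    cat(sprintf(
        "AnnotationCorpus: %d terms (%d roots), %d annotated genes\n",
        length(object@terms), length(object@roots), length(object@direct)))
})
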