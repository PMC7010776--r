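#' Construct an Interactome from an edge list
#'
#' Builds the cleaned interaction network used as the universe for every
#' statistic in the package: self-loops are dropped, duplicate and reversed
#' edges collapsed, and the graph restricted to its largest connected
#' component.
#'
#' @param edges two-column character matrix/data.frame of gene pairs, or an
#'   igraph object.
#' @return an [Interactome-class].
#' @export
Interactome <- function(edges) {
    if (igraph::is_igraph(edges)) {
        g <- edges
        if (is.null(igraph::V(g)$name))
            igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
        if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    } else {
        em <- as.matrix(edges)[, 1:2, drop = FALSE]
        storage.mode(em) <- "character"
        g <- igraph::graph_from_edgelist(em, directed = FALSE)
    }
    g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
    if (igraph::ecount(g) == 0L)
        stop("no edges remain after cleaning", call. = FALSE)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    new("Interactome", graph = g)
}

#' Load a protein interaction network from a two-column edge list file
#'
#' Reads a whitespace- or tab-separated two-column edge list (lines starting
#' with \code{#} are ignored), drops self-loops, collapses duplicate and
#' reversed edges, and keeps only the largest connected component.
#'
#' @param path path to the edge list file.
#' @return an [Interactome-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc", "a\ta", "d\te"), f)
#' net <- loadEdgeList(f)
#' genes(net)   # a, b, c: self-loop and the smaller component removed
#' @export
loadEdgeList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- which(keep)
    if (!length(lines)) stop("empty edge list: ", path, call. = FALSE)
    toks <- strsplit(lines, "\\s+")
    bad <- which(vapply(toks, length, 1L) < 2L)
    if (length(bad))
        stop(sprintf("malformed edge list line %d in %s", lineno[bad[1L]], path),
             call. = FALSE)
    em <- t(vapply(toks, function(x) x[1:2], character(2)))
    Interactome(em)
}

#' Write an Interactome back to a two-column edge list file
#'
#' Emits the same tab-separated dialect [loadEdgeList()] reads, so a
#' write/read round trip reproduces the identical node and edge sets.
#'
#' @param x an [Interactome-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(x, path) {
    stopifnot(is(x, "Interactome"))
    el <- igraph::as_edgelist(x@graph)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Partition nodes into contiguous degree bins
#'
#' Sorts the nodes by degree and greedily groups them into contiguous bins
#' of at least \code{minBinSize} nodes. Nodes sharing a degree always land
#' in the same bin (a bin is only closed at a degree boundary), and a short
#' final bin is merged backwards. With \code{minBinSize = 1} this reduces
#' to exact-degree classes; exhausted (e.g. singleton) classes fall back to
#' the nearest neighbouring bin at sampling time, see
#' [sampleDegreePreserved()].
#'
#' @param x an [Interactome-class].
#' @param minBinSize minimum number of nodes per bin (default 20).
#' @return a [DegreeBins-class].
#' @export
buildDegreeBins <- function(x, minBinSize = 20L) {
    stopifnot(is(x, "Interactome"))
    minBinSize <- as.integer(minBinSize)
    if (minBinSize < 1L) stop("minBinSize must be >= 1", call. = FALSE)
    deg <- igraph::degree(x@graph)
    if (minBinSize > length(deg))
        stop("minBinSize exceeds the number of nodes", call. = FALSE)
    ord <- order(deg, names(deg))
    nm <- names(deg)[ord]
    dg <- deg[ord]
    bins <- list()
    cur <- character(0)
    i <- 1L
    runs <- rle(as.integer(dg))$lengths
    for (len in runs) {
        # take whole degree classes so bins stay contiguous degree ranges
        cur <- c(cur, nm[i:(i + len - 1L)])
        i <- i + len
        if (length(cur) >= minBinSize) {
            bins[[length(bins) + 1L]] <- cur
            cur <- character(0)
        }
    }
    if (length(cur)) {
        if (length(bins)) {
            bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
        } else {
            bins[[1L]] <- cur
        }
    }
    binOf <- integer(0)
    for (b in seq_along(bins)) {
        v <- rep.int(b, length(bins[[b]]))
        names(v) <- bins[[b]]
        binOf <- c(binOf, v)
    }
    new("DegreeBins", bins = bins, binOf = binOf, minBinSize = minBinSize)
}

#' Draw a degree-preserved replacement for a gene set
#'
#' Replaces each gene by a uniform draw from its own degree bin, without
#' replacement across the drawn set. If a bin is exhausted the draw falls
#' back to the nearest neighbouring bin with available nodes, with a
#' warning.
#'
#' @param bins a [DegreeBins-class].
#' @param geneSet character vector of genes to randomize (all must be
#'   binned).
#' @return character vector of the same length as \code{geneSet}.
#' @export
sampleDegreePreserved <- function(bins, geneSet) {
    stopifnot(is(bins, "DegreeBins"))
    bin_idx <- bins@binOf[geneSet]
    if (anyNA(bin_idx))
        stop("genes not present in the degree binning: ",
             paste(geneSet[is.na(bin_idx)], collapse = ", "), call. = FALSE)
    chosen <- character(length(geneSet))
    used <- new.env(parent = emptyenv())
    nb <- length(bins@bins)
    for (i in seq_along(geneSet)) {
        b <- bin_idx[[i]]
        avail <- bins@bins[[b]]
        avail <- avail[!vapply(avail, exists, NA, envir = used)]
        if (!length(avail)) {
            # walk outward to the nearest non-empty bin
            for (off in seq_len(nb)) {
                for (cand in c(b - off, b + off)) {
                    if (cand >= 1L && cand <= nb) {
                        avail <- bins@bins[[cand]]
                        avail <- avail[!vapply(avail, exists, NA, envir = used)]
                        if (length(avail)) break
                    }
                }
                if (length(avail)) break
            }
            if (!length(avail))
                stop("all degree bins exhausted while sampling", call. = FALSE)
            warning("degree bin exhausted; sampling from an adjacent bin",
                    call. = FALSE)
        }
        pick <- avail[[sample.int(length(avail), 1L)]]
        chosen[[i]] <- pick
        assign(pick, TRUE, envir = used)
    }
    chosen
}

## internal: 0-based adjacency list for the C++ core
.adj0 <- function(x) {
    lapply(igraph::as_adj_list(x@graph), function(v) as.integer(v) - 1L)
}

## internal: 1-based adjacency list of integer indices
.adj1 <- function(x) {
    lapply(igraph::as_adj_list(x@graph), as.integer)
}
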