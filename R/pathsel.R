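## BFS shortest-path machinery shared by path enumeration and sampling.
## adj is a 1-based integer adjacency list; s a 1-based node index.
.bfsDag <- function(adj, s) {
    n <- length(adj)
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    q <- integer(n)
    dist[s] <- 0L; sigma[s] <- 1
    q[1L] <- s; qh <- 1L; qt <- 1L
    while (qh <= qt) {
        v <- q[qh]; qh <- qh + 1L
        for (w in adj[[v]]) {
            if (dist[w] < 0L) {
                dist[w] <- dist[v] + 1L
                qt <- qt + 1L; q[qt] <- w
            }
            if (dist[w] == dist[v] + 1L) {
                sigma[w] <- sigma[w] + sigma[v]
                preds[[w]] <- c(preds[[w]], v)
            }
        }
    }
    list(dist = dist, sigma = sigma, preds = preds)
}

## Expand all geodesics s -> b from a predecessor DAG, walking backwards
## from b with predecessors visited in lexicographic gene order, truncated
## deterministically at cap paths.
.expandGeodesics <- function(preds, nm, s, b, cap) {
    out <- vector("list", 0L)
    rec <- function(v, suffix) {
        if (length(out) >= cap) return(invisible())
        if (v == s) {
            out[[length(out) + 1L]] <<- c(v, suffix)
            return(invisible())
        }
        ps <- preds[[v]]
        for (p in ps[order(nm[ps])]) {
            if (length(out) >= cap) break
            rec(p, c(v, suffix))
        }
    }
    rec(b, integer(0))
    out
}

## Uniform draw of one geodesic s -> b: walk back from b picking each
## predecessor with probability proportional to its path count.
.sampleGeodesic <- function(bfs, s, b) {
    path <- b
    v <- b
    while (v != s) {
        ps <- bfs$preds[[v]]
        v <- if (length(ps) == 1L) ps else {
            ps[sample.int(length(ps), 1L, prob = bfs$sigma[ps])]
        }
        path <- c(v, path)
    }
    path
}

#' Enumerate all shortest paths between two seed gene sets
#'
#' For every ordered pair (a in \code{seedsA}, b in \code{seedsB}), expands
#' all geodesics from the BFS predecessor DAG rooted at \code{a}.
#' Expansion is deterministic (predecessors visited in lexicographic gene
#' order) and truncated at \code{perPairCap} paths per pair; a message
#' notes whenever the cap binds. Disconnected pairs and pairs with
#' \code{a == b} are skipped.
#'
#' @param x an [Interactome-class].
#' @param seedsA,seedsB non-empty character gene sets; genes absent from
#'   the network are dropped with a warning.
#' @param perPairCap maximum geodesics kept per ordered pair (default
#'   1000).
#' @return a [PathPool-class] with provenance \code{"shortest"}.
#' @export
enumerateSeedShortestPaths <- function(x, seedsA, seedsB, perPairCap = 1000L) {
    stopifnot(is(x, "Interactome"))
    nm <- genes(x)
    A <- .mapGenes(seedsA, nm, "source seed")
    B <- .mapGenes(seedsB, nm, "target seed")
    adj <- .adj1(x)
    pool <- list()
    capped <- 0L
    for (a in A) {
        bfs <- .bfsDag(adj, a)
        for (b in B) {
            if (b == a || bfs$dist[b] < 0L) next
            ps <- .expandGeodesics(bfs$preds, nm, a, b, perPairCap)
            if (length(ps) == perPairCap && bfs$sigma[b] > perPairCap)
                capped <- capped + 1L
            pool <- c(pool, lapply(ps, function(ix) nm[ix]))
        }
    }
    if (capped > 0L)
        message(sprintf("per-pair cap of %d bound for %d pair(s)",
                        perPairCap, capped))
    new("PathPool", paths = pool, provenance = "shortest",
        meta = list(perPairCap = perPairCap,
                    nPairsCapped = capped,
                    seedsA = nm[A], seedsB = nm[B]))
}

#' Select flow-central paths from a geodesic pool
#'
#' Keeps the paths whose every intermediate gene exceeds the FCS threshold
#' and participates in at least \code{minSupport} source-target geodesics.
#' The default rule is strict (\code{fcs > threshold}); set
#' \code{inclusive = TRUE} for \code{fcs >= threshold}. In relaxed mode an
#' intermediate also qualifies when the right-tailed empirical p-value of
#' its flow centrality is below 0.05, the sensitivity-maximizing rule used
#' for source-gene-focused path searches. Paths with no intermediate genes
#' carry no mediator information and are dropped, and duplicate gene
#' sequences are removed, so the result is a set of distinct central
#' paths.
#'
#' @param pool a [PathPool-class] of shortest paths.
#' @param fcsResult a [FlowCentralityResult-class] covering the pool genes.
#' @param fcsThreshold FCS cutoff (default 2).
#' @param minSupport minimum geodesic support for intermediates (default
#'   5).
#' @param relaxed if TRUE, intermediates pass with \code{fcs > threshold}
#'   or \code{empP < 0.05}.
#' @param inclusive if TRUE the FCS comparison is \code{>=} instead of
#'   \code{>}.
#' @return a [PathPool-class] with provenance \code{"fc"}.
#' @export
selectFcPaths <- function(pool, fcsResult, fcsThreshold = 2,
                          minSupport = 5L, relaxed = FALSE,
                          inclusive = FALSE) {
    stopifnot(is(pool, "PathPool"), is(fcsResult, "FlowCentralityResult"))
    tb <- fcTable(fcsResult)
    fcs <- stats::setNames(tb$fcs, tb$gene)
    empP <- stats::setNames(tb$empP, tb$gene)
    supp <- stats::setNames(tb$support, tb$gene)
    missing <- setdiff(unique(unlist(pool@paths, use.names = FALSE)), tb$gene)
    if (length(missing))
        stop("FCS result does not cover pool genes: ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    keep <- vapply(pool@paths, function(p) {
        n <- length(p)
        if (n < 3L) return(FALSE)
        mid <- p[2:(n - 1L)]
        passFcs <- if (inclusive) fcs[mid] >= fcsThreshold
                   else fcs[mid] > fcsThreshold
        if (relaxed) passFcs <- passFcs | (empP[mid] < 0.05)
        all(passFcs) && all(supp[mid] >= minSupport)
    }, NA)
    sel <- pool@paths[keep]
    sel <- sel[!duplicated(vapply(sel, paste, "", collapse = "\r"))]
    new("PathPool", paths = sel, provenance = "fc",
        meta = list(fcsThreshold = fcsThreshold, minSupport = minSupport,
                    relaxed = relaxed, inclusive = inclusive))
}

#' Empirical length histogram of a path pool
#'
#' @param pool a [PathPool-class].
#' @return integer vector of path lengths (number of genes per path).
#' @export
pathLengthHistogram <- function(pool) {
    stopifnot(is(pool, "PathPool"))
    lengths(pool@paths)
}

#' Sample length-preserved random paths (Type A)
#'
#' Each path is built by drawing a length \eqn{L} from the empirical
#' length distribution, starting at a uniformly random node and taking
#' uniform self-avoiding steps until the path holds \eqn{L} genes. A dead
#' end (no unused neighbour) restarts the whole path; after
#' \code{maxAttempts} failed walks the length is re-drawn. Each realized
#' path has exactly its drawn length, so the pool's length histogram
#' matches the multiset of draws.
#'
#' @param x an [Interactome-class].
#' @param lengthHist integer vector of observed path lengths (all >= 2) to
#'   draw from, e.g. [pathLengthHistogram()] of the flow-central pool.
#' @param nPaths number of paths to generate.
#' @param seed optional integer seed.
#' @param maxAttempts walk restarts before re-drawing a length (default
#'   100).
#' @return a [PathPool-class] with provenance \code{"typeA"}; its meta
#'   records the drawn lengths.
#' @export
sampleTypeA <- function(x, lengthHist, nPaths, seed = NULL,
                        maxAttempts = 100L) {
    stopifnot(is(x, "Interactome"))
    lengthHist <- as.integer(lengthHist)
    if (!length(lengthHist) || any(lengthHist < 2L))
        stop("length histogram must be non-empty with all lengths >= 2",
             call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    adj <- .adj1(x)
    n <- length(adj)
    nm <- genes(x)
    if (any(lengthHist > n))
        stop(sprintf("path length %d exceeds the network size",
                     max(lengthHist)), call. = FALSE)
    pool <- vector("list", nPaths)
    drawn <- integer(nPaths)
    for (i in seq_len(nPaths)) {
        path <- NULL
        redraws <- 0L
        while (is.null(path)) {
            L <- lengthHist[[sample.int(length(lengthHist), 1L)]]
            for (att in seq_len(maxAttempts)) {
                inPath <- logical(n)
                p <- integer(L)
                v <- sample.int(n, 1L)
                p[1L] <- v; inPath[v] <- TRUE
                ok <- TRUE
                for (stp in seq_len(L - 1L)) {
                    nb <- adj[[v]]
                    nb <- nb[!inPath[nb]]
                    if (!length(nb)) { ok <- FALSE; break }
                    v <- if (length(nb) == 1L) nb
                         else nb[[sample.int(length(nb), 1L)]]
                    p[stp + 1L] <- v; inPath[v] <- TRUE
                }
                if (ok) { path <- p; break }
            }
            if (is.null(path)) {
                redraws <- redraws + 1L
                if (redraws > 1000L)
                    stop(sprintf(
                        "cannot realize a self-avoiding path of length %d", L),
                        call. = FALSE)
            }
        }
        pool[[i]] <- nm[path]
        drawn[[i]] <- length(path)
    }
    new("PathPool", paths = pool, provenance = "typeA",
        meta = list(drawnLengths = drawn,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Sample endpoint-preserved random paths (Type B)
#'
#' Uniform draws, with replacement, from a pool of seed-to-seed geodesics.
#'
#' @param pool a non-empty [PathPool-class].
#' @param nPaths number of draws.
#' @param seed optional integer seed.
#' @return a [PathPool-class] with provenance \code{"typeB"}.
#' @export
sampleTypeB <- function(pool, nPaths, seed = NULL) {
    stopifnot(is(pool, "PathPool"))
    if (!length(pool@paths)) stop("path pool is empty", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    idx <- sample.int(length(pool@paths), nPaths, replace = TRUE)
    new("PathPool", paths = pool@paths[idx], provenance = "typeB",
        meta = list(sourceProvenance = pool@provenance, index = idx,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Sample shortest paths from one seed set to a phenotype gene set
#'
#' Repeatedly picks a uniform source from \code{seedsA} and a uniform
#' target from \code{phenotypeGenes}, then samples one geodesic uniformly
#' at random from that pair's geodesic set. Disconnected draws are redrawn
#' (bounded retries); an error is raised if no connected pair exists.
#'
#' @param x an [Interactome-class].
#' @param seedsA source seed gene set.
#' @param phenotypeGenes target gene set.
#' @param nPaths number of paths to sample.
#' @param seed optional integer seed.
#' @return a [PathPool-class] with provenance \code{"seed_to_set"}; draws
#'   with identical endpoints (\code{a == b}) are redrawn like disconnected
#'   pairs.
#' @export
sampleSeedToSetPaths <- function(x, seedsA, phenotypeGenes, nPaths,
                                 seed = NULL) {
    stopifnot(is(x, "Interactome"))
    nm <- genes(x)
    A <- .mapGenes(seedsA, nm, "source seed")
    B <- .mapGenes(phenotypeGenes, nm, "phenotype")
    if (!is.null(seed)) set.seed(seed)
    adj <- .adj1(x)
    bfsCache <- vector("list", length(A))
    pool <- vector("list", nPaths)
    for (i in seq_len(nPaths)) {
        got <- FALSE
        for (try in seq_len(100L)) {
            ai <- sample.int(length(A), 1L)
            a <- A[[ai]]
            b <- B[[sample.int(length(B), 1L)]]
            if (a == b) next
            if (is.null(bfsCache[[ai]])) bfsCache[[ai]] <- .bfsDag(adj, a)
            bfs <- bfsCache[[ai]]
            if (bfs$dist[b] < 0L) next
            pool[[i]] <- nm[.sampleGeodesic(bfs, a, b)]
            got <- TRUE
            break
        }
        if (!got)
            stop("no connected source-target pair could be drawn",
                 call. = FALSE)
    }
    new("PathPool", paths = pool, provenance = "seed_to_set",
        meta = list(seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Write a path pool as TSV (one path per line) with a JSON sidecar
#'
#' @param pool a [PathPool-class].
#' @param path output TSV path; metadata goes to \code{<path>.json}.
#' @return invisibly, \code{path}.
#' @export
writePathPool <- function(pool, path) {
    stopifnot(is(pool, "PathPool"))
    writeLines(vapply(pool@paths, paste, "", collapse = "\t"), path)
    meta <- pool@meta
    meta$provenance <- pool@provenance
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' Read a path pool written by [writePathPool()]
#'
#' @param path TSV path; \code{<path>.json} is read when present.
#' @return a [PathPool-class].
#' @export
readPathPool <- function(path) {
    lines <- readLines(path, warn = FALSE)
    pool <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
    meta <- list()
    prov <- "shortest"
    side <- paste0(path, ".json")
    if (file.exists(side)) {
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
        if (!is.null(meta$provenance)) {
            prov <- meta$provenance
            meta$provenance <- NULL
        }
    }
    new("PathPool", paths = pool, provenance = prov, meta = as.list(meta))
}
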