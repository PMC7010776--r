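## read a one-gene-per-line file, ignoring blanks and # comments
.readGeneList <- function(path) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines[nzchar(lines) & !startsWith(lines, "#")]
}

.asGeneSet <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x))
        .readGeneList(x) else as.character(x)
}

#' Run the full mediator-gene pipeline
#'
#' Orchestrates the analysis end to end: load and clean the interaction
#' network, build the two disease modules (DIAMOnD-expanded, or the flat
#' seed sets in \code{"degree_only"} mode), compute flow centrality scores
#' against the module-randomized null, enumerate seed-to-seed shortest
#' paths, select the flow-central paths, draw the Type A
#' (length-preserved) and Type B (endpoint-preserved) null path ensembles,
#' and — when an ontology and/or expression data are supplied — run the
#' sequential similarity and sequential coexpression comparisons. All
#' stage outputs are written as TSV/JSON to \code{outDir}, together with a
#' manifest recording every input path, parameter and derived stage seed;
#' rerunning from the manifest reproduces every result file byte for
#' byte.
#'
#' @param edges edge-list file path or an [Interactome-class].
#' @param seedsA,seedsB seed gene files (one id per line) or character
#'   vectors.
#' @param outDir output directory (created if missing).
#' @param nA,nB DIAMOnD iteration counts for the two modules (ignored in
#'   \code{"degree_only"} mode). Alternatively supply
#'   \code{referenceA}/\code{referenceB} to size the modules by reference
#'   enrichment.
#' @param referenceA,referenceB reference gene sets (files or vectors) for
#'   enrichment-based module sizing; used when \code{nA}/\code{nB} are
#'   NULL.
#' @param maxIter maximum DIAMOnD iterations scanned when sizing by
#'   reference (default 200).
#' @param obo,annotations ontology file (or [readOBO()] result / parent
#'   list) and annotation source for the similarity stage; both NULL skips
#'   it.
#' @param exprData expression \code{SummarizedExperiment}, or path to a
#'   matrix TSV, for the coexpression stage; NULL skips it.
#' @param exprMapping,exprClasses optional mapping/class files when
#'   \code{exprData} is a path.
#' @param mode null-module mode, \code{"diamond"} or \code{"degree_only"}.
#' @param nSamples null module pairs for the FCS (default 1000).
#' @param nNullPaths size of each null path ensemble (default 10000).
#' @param fcsThreshold,minSupport,relaxed flow-central path filters.
#' @param minBinSize degree bin occupancy (default 20).
#' @param perPairCap geodesic cap per seed pair (default 1000).
#' @param seed base integer seed; stage seeds are derived from it.
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(edges, seedsA, seedsB, outDir,
                        nA = NULL, nB = NULL,
                        referenceA = NULL, referenceB = NULL,
                        maxIter = 200L,
                        obo = NULL, annotations = NULL,
                        exprData = NULL, exprMapping = NULL,
                        exprClasses = NULL,
                        mode = c("diamond", "degree_only"),
                        nSamples = 1000L, nNullPaths = 10000L,
                        fcsThreshold = 2, minSupport = 5L, relaxed = FALSE,
                        minBinSize = 20L, perPairCap = 1000L, seed = 1L) {
    mode <- match.arg(mode)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(
        package = "flowCentral",
        version = as.character(utils::packageVersion("flowCentral")),
        parameters = list(mode = mode, nA = nA, nB = nB, maxIter = maxIter,
                          nSamples = nSamples, nNullPaths = nNullPaths,
                          fcsThreshold = fcsThreshold,
                          minSupport = minSupport, relaxed = relaxed,
                          minBinSize = minBinSize, perPairCap = perPairCap,
                          seed = seed),
        inputs = list(
            edges = if (is.character(edges)) normalizePath(edges) else "<in-memory>",
            seedsA = if (is.character(seedsA) && length(seedsA) == 1L &&
                         file.exists(seedsA)) normalizePath(seedsA) else "<in-memory>",
            seedsB = if (is.character(seedsB) && length(seedsB) == 1L &&
                         file.exists(seedsB)) normalizePath(seedsB) else "<in-memory>"),
        stages = character(0))
    stage <- function(name) {
        message("[flowCentral] stage: ", name)
        manifest$stages <<- c(manifest$stages, name)
    }

    stage("interactome")
    net <- if (is(edges, "Interactome")) edges else loadEdgeList(edges)
    bins <- buildDegreeBins(net, minBinSize)
    sA <- .asGeneSet(seedsA); sB <- .asGeneSet(seedsB)

    stage("modules")
    if (mode == "diamond") {
        sizeOf <- function(n, ref, seedsX) {
            if (!is.null(n)) return(as.integer(n))
            ref <- .asGeneSet(ref)
            if (is.null(ref))
                stop("supply nA/nB or referenceA/referenceB in diamond mode",
                     call. = FALSE)
            selectModuleSize(net, seedsX, ref, maxIter)$nStar
        }
        nA <- sizeOf(nA, referenceA, sA)
        nB <- sizeOf(nB, referenceB, sB)
        modA <- diamondExpand(net, sA, nA)
        modB <- diamondExpand(net, sB, nB)
        utils::write.table(modA@added, file.path(outDir, "module_a.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(modB@added, file.path(outDir, "module_b.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        modA <- sA
        modB <- sB
    }

    stage("fcs")
    fcs <- flowCentralityScore(net, modA, modB, nSamples = nSamples,
                               mode = mode, bins = bins, seed = seed + 1L)
    utils::write.table(fcTable(fcs), file.path(outDir, "fcs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage("paths")
    pool <- enumerateSeedShortestPaths(net, sA, sB, perPairCap = perPairCap)
    fcPaths <- selectFcPaths(pool, fcs, fcsThreshold = fcsThreshold,
                             minSupport = minSupport, relaxed = relaxed)
    writePathPool(fcPaths, file.path(outDir, "paths_fc.tsv"))
    if (!length(fcPaths@paths))
        warning("no flow-central path passes the filters", call. = FALSE)

    stage("null_paths")
    typeA <- typeB <- NULL
    if (length(fcPaths@paths)) {
        typeA <- sampleTypeA(net, pathLengthHistogram(fcPaths), nNullPaths,
                             seed = seed + 2L)
        typeB <- sampleTypeB(pool, nNullPaths, seed = seed + 3L)
        writePathPool(typeA, file.path(outDir, "paths_typea.tsv"))
        writePathPool(typeB, file.path(outDir, "paths_typeb.tsv"))
    }

    if (!is.null(obo) || !is.null(annotations)) {
        if (!is(obo, "AnnotationCorpus") &&
            (is.null(obo) || is.null(annotations)))
            stop("sequential similarity needs both 'obo' and 'annotations'",
                 call. = FALSE)
        stage("sequential_similarity")
        corpus <- if (is(obo, "AnnotationCorpus")) obo
                  else buildCorpus(obo, annotations)
        ss <- ssCompare(fcPaths, typeA, typeB, corpus)
        jsonlite::write_json(
            list(pA = ss$pA, pB = ss$pB, worstCase = ss$worstCase,
                 score = -log10(ss$worstCase),
                 nFcPaths = length(ss$ssFc)),
            file.path(outDir, "ss.json"), auto_unbox = TRUE, digits = NA)
    }

    if (!is.null(exprData)) {
        stage("sequential_coexpression")
        se <- if (is.character(exprData))
                  loadExpression(exprData, exprMapping, exprClasses)
              else exprData
        sc <- scCompare(fcPaths, typeA, typeB, se)
        jsonlite::write_json(
            list(perClass = sc$perClass, worstCase = sc$worstCase,
                 score = sc$score),
            file.path(outDir, "sc.json"), auto_unbox = TRUE, digits = NA,
            dataframe = "rows")
    }

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
}
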