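#' Load an expression matrix with probe-to-gene mapping and sample classes
#'
#' Reads a plain-TSV expression matrix (first column probe id, header row
#' sample ids), an optional probe-to-gene mapping TSV (probe, gene) and an
#' optional sample-class TSV (sample, class), and assembles a
#' \code{SummarizedExperiment}: probes as rows (with \code{rowData$gene}),
#' samples as columns (with \code{colData$class}). Probes without a gene
#' mapping are dropped with a warning; samples missing from the class file
#' are labelled \code{"unlabeled"} and excluded from class-restricted
#' analyses.
#'
#' @param matrixFile expression matrix TSV.
#' @param mappingFile probe-to-gene TSV; when NULL, probe ids are taken as
#'   gene ids.
#' @param classFile sample-class TSV; when NULL all samples share class
#'   \code{"all"}.
#' @param log2Transform apply \code{log2} to the values; an error names
#'   the first offending cell if any value is <= 0.
#' @return a \code{SummarizedExperiment} with assay \code{"exprs"}.
#' @export
loadExpression <- function(matrixFile, mappingFile = NULL, classFile = NULL,
                           log2Transform = FALSE) {
    df <- utils::read.table(matrixFile, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    probes <- as.character(df[[1L]])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- probes

    if (!is.null(mappingFile)) {
        mp <- utils::read.table(mappingFile, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
        geneOf <- stats::setNames(as.character(mp[[2L]]), as.character(mp[[1L]]))
        mapped <- probes %in% names(geneOf)
        if (!any(mapped)) stop("no probe maps to any gene", call. = FALSE)
        if (!all(mapped))
            warning(sprintf("%d unmapped probe(s) dropped", sum(!mapped)),
                    call. = FALSE)
        mat <- mat[mapped, , drop = FALSE]
        gene <- unname(geneOf[rownames(mat)])
    } else {
        gene <- probes
    }

    cls <- rep("all", ncol(mat))
    if (!is.null(classFile)) {
        cf <- utils::read.table(classFile, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
        classOf <- stats::setNames(as.character(cf[[2L]]), as.character(cf[[1L]]))
        cls <- ifelse(colnames(mat) %in% names(classOf),
                      classOf[colnames(mat)], "unlabeled")
    }

    if (log2Transform) {
        bad <- which(mat <= 0, arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf(
                "log2 transform impossible: value <= 0 at probe '%s', sample '%s'",
                rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]),
                call. = FALSE)
        mat <- log2(mat)
    }

    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        rowData = S4Vectors::DataFrame(gene = gene),
        colData = S4Vectors::DataFrame(class = unname(cls),
                                       row.names = colnames(mat)))
}

## internal: columns of `se` belonging to a class ("all" means every sample)
.classCols <- function(se, class) {
    cls <- SummarizedExperiment::colData(se)$class
    if (is.null(class) || identical(class, "all")) which(cls != "unlabeled")
    else which(cls == class)
}

## internal: precomputed per-class view of the expression data; avoids
## re-subsetting the SummarizedExperiment for every gene pair
.exprIndex <- function(se, class) {
    cols <- .classCols(se, class)
    if (length(cols) < 3L)
        stop("need at least 3 samples in the class", call. = FALSE)
    m <- SummarizedExperiment::assay(se, "exprs")[, cols, drop = FALSE]
    gv <- as.character(SummarizedExperiment::rowData(se)$gene)
    keep <- apply(m, 1L, stats::sd) > 0   # zero-variance probes skipped
    list(mat = t(m), rowsOf = split(seq_len(nrow(m)), gv),
         varying = keep)
}

## internal: max |cor| over the varying probe pairs of two genes; NA when a
## gene is missing or has only degenerate probes
.pairCorIdx <- function(idx, geneA, geneB, method = "pearson") {
    ra <- idx$rowsOf[[geneA]]
    rb <- idx$rowsOf[[geneB]]
    if (is.null(ra) || is.null(rb)) return(NA_real_)
    ra <- ra[idx$varying[ra]]
    rb <- rb[idx$varying[rb]]
    if (!length(ra) || !length(rb)) return(NA_real_)
    max(abs(stats::cor(idx$mat[, ra, drop = FALSE],
                       idx$mat[, rb, drop = FALSE], method = method)))
}

#' Coexpression of a gene pair: max absolute correlation over probe pairs
#'
#' Pearson correlation over the samples of one class, computed for every
#' pair of probes mapping to the two genes; zero-variance probes are
#' skipped and the maximum absolute correlation is returned. Returns
#' \code{NA} when a gene is absent from the matrix or when every probe
#' pair is degenerate.
#'
#' @param se a \code{SummarizedExperiment} from [loadExpression()] or
#'   [makeSyntheticExpression()].
#' @param geneA,geneB gene identifiers.
#' @param class sample class to restrict to (default all labelled
#'   samples).
#' @param method correlation method (default \code{"pearson"}).
#' @return max absolute correlation in [0, 1], or \code{NA}.
#' @export
genePairCoexpression <- function(se, geneA, geneB, class = NULL,
                                 method = "pearson") {
    .pairCorIdx(.exprIndex(se, class), geneA, geneB, method)
}

#' Sequential coexpression of a network path
#'
#' Mean absolute pairwise correlation of adjacent genes along a path
#' \eqn{(g_1, \ldots, g_n)}:
#' \deqn{SC = \frac{1}{n-1}\sum_{i=1}^{n-1}
#'   |\rho(e_{g_i}, e_{g_{i+1}})|}
#' where each pair correlation is maximized over the probes mapping to the
#' two genes. If any gene is absent from the expression data — or has only
#' zero-variance probes, the same information state — the path's SC is
#' null (\code{NA}) and the path is excluded from downstream comparisons.
#'
#' @param path character vector of >= 2 genes.
#' @param se expression \code{SummarizedExperiment}.
#' @param class sample class to restrict to.
#' @param cache optional environment memoizing pair correlations.
#' @param method correlation method.
#' @return SC in [0, 1], or \code{NA} for a null path.
#' @export
sequentialCoexpression <- function(path, se, class = NULL, cache = NULL,
                                   method = "pearson") {
    .seqCoexprIdx(as.character(path), .exprIndex(se, class), cache, method)
}

## internal workhorse on a precomputed expression index
.seqCoexprIdx <- function(path, idx, cache = NULL, method = "pearson") {
    n <- length(path)
    if (n < 2L) stop("path must hold at least two genes", call. = FALSE)
    vals <- numeric(n - 1L)
    for (i in seq_len(n - 1L)) {
        u <- path[[i]]; v <- path[[i + 1L]]
        key <- if (u < v) paste(u, v, sep = "\r") else paste(v, u, sep = "\r")
        r <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
             else {
                 r0 <- .pairCorIdx(idx, u, v, method)
                 if (!is.null(cache)) cache[[key]] <- r0
                 r0
             }
        if (is.na(r)) return(NA_real_)
        vals[[i]] <- r
    }
    mean(vals)
}

#' Sequential coexpression of every path in a pool
#'
#' @param pool a [PathPool-class].
#' @param se expression \code{SummarizedExperiment}.
#' @param class sample class.
#' @param method correlation method.
#' @return list with \code{sc} (values of the non-null paths),
#'   \code{nValid} and \code{nNull}; \code{nValid + nNull} equals the pool
#'   size.
#' @export
poolSequentialCoexpression <- function(pool, se, class = NULL,
                                       method = "pearson") {
    stopifnot(is(pool, "PathPool"))
    .poolSCIdx(pool, .exprIndex(se, class), method)
}

.poolSCIdx <- function(pool, idx, method = "pearson", cache = NULL) {
    if (is.null(cache)) cache <- new.env(parent = emptyenv())
    sc <- vapply(pool@paths, .seqCoexprIdx, 0.0,
                 idx = idx, cache = cache, method = method)
    list(sc = unname(sc[!is.na(sc)]), nValid = sum(!is.na(sc)),
         nNull = sum(is.na(sc)))
}

#' Compare flow-central path coexpression against both null path ensembles
#'
#' For each sample class, right-sided Mann-Whitney tests of the
#' flow-central paths' sequential coexpression against the Type A and
#' Type B pools; each class is summarized by \code{max(pA, pB)} and the
#' dataset by the maximum (least significant) worst case over classes,
#' reported alongside its \code{-log10} score.
#'
#' @param fcPool,typeAPool,typeBPool [PathPool-class] objects.
#' @param se expression \code{SummarizedExperiment}.
#' @param classes character vector of classes to analyze; defaults to all
#'   labelled classes in the data. Classes whose pools yield fewer than
#'   two non-null SC values are skipped with a warning.
#' @param method correlation method.
#' @return list with \code{perClass} (data.frame class/pA/pB/worstCase),
#'   \code{worstCase}, and \code{score} (\code{-log10} of the worst case).
#' @export
scCompare <- function(fcPool, typeAPool, typeBPool, se, classes = NULL,
                      method = "pearson") {
    if (is.null(classes)) {
        classes <- unique(SummarizedExperiment::colData(se)$class)
        classes <- setdiff(classes, "unlabeled")
    }
    rows <- list()
    for (cl in classes) {
        idx <- .exprIndex(se, cl)
        cache <- new.env(parent = emptyenv())
        f <- .poolSCIdx(fcPool, idx, method, cache)
        a <- .poolSCIdx(typeAPool, idx, method, cache)
        b <- .poolSCIdx(typeBPool, idx, method, cache)
        if (f$nValid < 2L || a$nValid < 2L || b$nValid < 2L) {
            warning(sprintf("class '%s' skipped: too few non-null paths", cl),
                    call. = FALSE)
            next
        }
        pA <- mannWhitneyRight(f$sc, a$sc)
        pB <- mannWhitneyRight(f$sc, b$sc)
        rows[[length(rows) + 1L]] <-
            data.frame(class = cl, pA = pA, pB = pB,
                       worstCase = worstCase(c(pA, pB)),
                       stringsAsFactors = FALSE)
    }
    if (!length(rows))
        stop("no class yielded enough non-null paths", call. = FALSE)
    perClass <- do.call(rbind, rows)
    wc <- worstCase(perClass$worstCase)
    list(perClass = perClass, worstCase = wc, score = -log10(wc))
}
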