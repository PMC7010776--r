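#' Read an OBO 1.2 ontology file
#'
#' Minimal reader for the `[Term]` stanzas of an OBO 1.2 file: `id`,
#' `name`, `namespace` and `is_a` lines are kept (trailing `!` comments
#' stripped); obsolete terms are dropped.
#'
#' @param path path to the OBO file.
#' @return list with \code{terms} (data.frame id/name/namespace) and
#'   \code{parents} (named list of is_a parent ids).
#' @export
readOBO <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    id <- name <- ns <- character(0)
    parents <- list()
    cur <- NULL
    flush <- function() {
        if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
            id <<- c(id, cur$id)
            name <<- c(name, if (is.null(cur$name)) NA_character_ else cur$name)
            ns <<- c(ns, if (is.null(cur$ns)) NA_character_ else cur$ns)
            parents[[cur$id]] <<- cur$isa
        }
    }
    inTerm <- FALSE
    for (ln in lines) {
        ln <- sub("\\s*!.*$", "", ln)
        ln <- trimws(ln)
        if (ln == "[Term]") {
            flush(); cur <- list(isa = character(0)); inTerm <- TRUE; next
        }
        if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
        if (!inTerm || !nzchar(ln)) next
        if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
        else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
        else if (startsWith(ln, "namespace:")) cur$ns <- trimws(sub("^namespace:", "", ln))
        else if (startsWith(ln, "is_a:")) cur$isa <- c(cur$isa, trimws(sub("^is_a:", "", ln)))
        else if (startsWith(ln, "is_obsolete:") && grepl("true", ln)) cur$obsolete <- TRUE
    }
    flush()
    list(terms = data.frame(id = id, name = name, namespace = ns,
                            stringsAsFactors = FALSE),
         parents = parents)
}

#' Build an annotation corpus: DAG, propagated annotations, information content
#'
#' Combines an is_a term hierarchy with direct gene annotations.
#' Annotations are propagated to all ancestors, and each term's
#' information content is
#' \code{ic(t) = -log(n_t / n_root)} (natural logarithm), where \code{n_t}
#' counts the genes annotated to \code{t} after propagation and
#' \code{n_root} the genes annotated to the term's namespace root. Any
#' other log base would rescale all similarities jointly and cannot change
#' rank-based comparisons.
#'
#' @param ontology the result of [readOBO()], a path to an OBO file, or a
#'   named list mapping each term to its parent terms.
#' @param annotations two-column data.frame (gene, term), a path to a
#'   two-column TSV, or a path to a GAF 2.x file (detected by the
#'   \code{.gaf} extension or \code{!gaf-version} header; columns 2 and 5
#'   used, qualifier "NOT" rows dropped). Annotations to unknown terms are
#'   dropped with a warning.
#' @param namespace optional namespace filter (e.g.
#'   \code{"biological_process"}); requires namespace metadata from an OBO
#'   source.
#' @return an [AnnotationCorpus-class].
#' @export
buildCorpus <- function(ontology, annotations, namespace = NULL) {
    if (is.character(ontology) && length(ontology) == 1L)
        ontology <- readOBO(ontology)
    if (is.list(ontology) && is.null(ontology$parents)) {
        parents <- ontology
        nsVec <- NULL
    } else {
        parents <- ontology$parents
        nsVec <- stats::setNames(ontology$terms$namespace, ontology$terms$id)
    }
    terms <- names(parents)
    if (!is.null(namespace)) {
        if (is.null(nsVec))
            stop("namespace filtering needs an OBO source", call. = FALSE)
        terms <- terms[!is.na(nsVec[terms]) & nsVec[terms] == namespace]
        parents <- lapply(parents[terms], function(p) intersect(p, terms))
    }
    nT <- length(terms)
    if (!nT) stop("ontology has no terms", call. = FALSE)
    tidx <- stats::setNames(seq_len(nT), terms)
    pidx <- lapply(parents, function(p) unname(tidx[p[p %in% terms]]))

    # Kahn topological order (parents before children); cycles are fatal.
    nParents <- lengths(pidx)
    children <- vector("list", nT)
    for (i in seq_len(nT)) for (p in pidx[[i]])
        children[[p]] <- c(children[[p]], i)
    queue <- which(nParents == 0L)
    topo <- integer(0)
    remaining <- nParents
    while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        topo <- c(topo, v)
        for (ch in children[[v]]) {
            remaining[[ch]] <- remaining[[ch]] - 1L
            if (remaining[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(topo) != nT)
        stop("is_a hierarchy contains a cycle", call. = FALSE)

    anc <- vector("list", nT)   # ancestors incl. self, as indices
    for (v in topo) {
        anc[[v]] <- unique(c(v, unlist(anc[pidx[[v]]], use.names = FALSE)))
    }

    ann <- .readAnnotations(annotations)
    known <- ann$term %in% terms
    if (!all(known)) {
        warning(sprintf("%d annotation(s) to unknown terms dropped",
                        sum(!known)), call. = FALSE)
        ann <- ann[known, , drop = FALSE]
    }
    if (!nrow(ann)) stop("no annotated genes remain", call. = FALSE)
    direct <- lapply(split(ann$term, ann$gene), unique)
    propagated <- lapply(direct, function(ts)
        terms[unique(unlist(anc[tidx[ts]], use.names = FALSE))])

    cnt <- table(factor(unlist(propagated, use.names = FALSE), levels = terms))
    cnt <- as.integer(cnt)

    roots <- terms[lengths(pidx) == 0L]
    # normalize each term by its own namespace root's propagated count
    rootOfIdx <- integer(nT)
    rootSet <- which(lengths(pidx) == 0L)
    for (v in seq_len(nT)) {
        rr <- intersect(anc[[v]], rootSet)
        # with several reachable roots take the best-populated one
        rootOfIdx[[v]] <- rr[which.max(cnt[rr])]
    }
    ic <- rep.int(0, nT)
    pos <- cnt > 0L & cnt[rootOfIdx] > 0L
    ic[pos] <- -log(cnt[pos] / cnt[rootOfIdx[pos]])
    ic[cnt == 0L] <- 0   # unannotated terms carry no information
    names(ic) <- terms

    new("AnnotationCorpus", terms = terms, parents = parents,
        ancestors = stats::setNames(lapply(anc, function(ix) terms[ix]), terms),
        direct = direct, propagated = propagated, ic = ic, roots = roots)
}

.readAnnotations <- function(annotations) {
    if (is.data.frame(annotations)) {
        df <- annotations[, 1:2]
        names(df) <- c("gene", "term")
        df$gene <- as.character(df$gene); df$term <- as.character(df$term)
        return(df)
    }
    stopifnot(is.character(annotations), length(annotations) == 1L)
    head1 <- readLines(annotations, n = 1L, warn = FALSE)
    isGaf <- grepl("\\.gaf(\\.|$)", annotations) || grepl("^!gaf-version", head1)
    if (isGaf) {
        lines <- readLines(annotations, warn = FALSE)
        lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
        f <- strsplit(lines, "\t", fixed = TRUE)
        keep <- vapply(f, function(x)
            length(x) >= 5L && !grepl("NOT", x[[4L]]), NA)
        f <- f[keep]
        data.frame(gene = vapply(f, `[[`, "", 2L),
                   term = vapply(f, `[[`, "", 5L), stringsAsFactors = FALSE)
    } else {
        df <- utils::read.table(annotations, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE,
                                comment.char = "#", quote = "")
        names(df)[1:2] <- c("gene", "term")
        df[, c("gene", "term")]
    }
}

#' Resnik similarity between two ontology terms
#'
#' Information content of the most informative common ancestor (MICA); 0
#' when the terms share only a root (or nothing).
#'
#' @param corpus an [AnnotationCorpus-class].
#' @param termA,termB term identifiers present in the DAG.
#' @return non-negative similarity.
#' @export
resnikSim <- function(corpus, termA, termB) {
    stopifnot(is(corpus, "AnnotationCorpus"))
    a <- corpus@ancestors[[termA]]
    b <- corpus@ancestors[[termB]]
    if (is.null(a) || is.null(b))
        stop("term(s) absent from the ontology", call. = FALSE)
    common <- intersect(a, b)
    if (!length(common)) return(0)
    max(corpus@ic[common])
}

#' Best-match-average Resnik similarity between two genes
#'
#' For genes \eqn{u}, \eqn{v} with direct annotation sets
#' \eqn{\mathcal{U}}, \eqn{\mathcal{V}}:
#' \deqn{s(u,v) = \frac{1}{|\mathcal{U}| + |\mathcal{V}|}\Big[
#'   \sum_{\alpha \in \mathcal{U}} \max_{\beta \in \mathcal{V}}
#'   sim(\alpha, \beta) +
#'   \sum_{\beta \in \mathcal{V}} \max_{\alpha \in \mathcal{U}}
#'   sim(\alpha, \beta)\Big]}
#' with \eqn{sim} the Resnik term similarity. The best-match sums run over
#' the direct annotation sets while the MICA search uses the propagated
#' DAG — the standard Resnik/BMA construction.
#'
#' @param corpus an [AnnotationCorpus-class].
#' @param geneU,geneV gene identifiers.
#' @return non-negative similarity; \code{NA} when either gene has no
#'   annotations (undefined-similarity signal).
#' @export
bmaSimilarity <- function(corpus, geneU, geneV) {
    U <- corpus@direct[[geneU]]
    V <- corpus@direct[[geneV]]
    if (is.null(U) || is.null(V) || !length(U) || !length(V))
        return(NA_real_)
    m <- matrix(0, length(U), length(V))
    for (i in seq_along(U)) for (j in seq_along(V))
        m[i, j] <- resnikSim(corpus, U[[i]], V[[j]])
    (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
        (length(U) + length(V))
}

#' Sequential similarity of a network path
#'
#' Mean best-match-average Resnik similarity of adjacent genes along a
#' path \eqn{(g_1, \ldots, g_n)}:
#' \deqn{SS = \frac{1}{n-1}\sum_{i=1}^{n-1} s(g_i, g_{i+1}).}
#' Adjacent pairs involving an unannotated gene contribute 0 and are
#' flagged.
#'
#' @param path character vector of >= 2 genes, or a single-path element of
#'   a [PathPool-class].
#' @param corpus an [AnnotationCorpus-class].
#' @param cache optional environment memoizing gene-pair similarities
#'   across calls (used when scoring whole pools).
#' @return list with \code{ss}, \code{pairValues} (length n-1) and
#'   \code{flagged} (logical, pairs involving unannotated genes).
#' @export
sequentialSimilarity <- function(path, corpus, cache = NULL) {
    stopifnot(is(corpus, "AnnotationCorpus"))
    path <- as.character(path)
    n <- length(path)
    if (n < 2L) stop("path must hold at least two genes", call. = FALSE)
    vals <- numeric(n - 1L)
    flag <- logical(n - 1L)
    for (i in seq_len(n - 1L)) {
        u <- path[[i]]; v <- path[[i + 1L]]
        key <- if (u < v) paste(u, v, sep = "\r") else paste(v, u, sep = "\r")
        s <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
             else {
                 s0 <- bmaSimilarity(corpus, u, v)
                 if (!is.null(cache)) cache[[key]] <- s0
                 s0
             }
        if (is.na(s)) { vals[[i]] <- 0; flag[[i]] <- TRUE }
        else vals[[i]] <- s
    }
    list(ss = mean(vals), pairValues = vals, flagged = flag)
}

#' Sequential similarity of every path in a pool
#'
#' @param pool a [PathPool-class].
#' @param corpus an [AnnotationCorpus-class].
#' @param dropUnannotated if TRUE, paths with any flagged (unannotated)
#'   adjacent pair are dropped instead of contributing zeros.
#' @return numeric vector of SS values (one per retained path).
#' @export
poolSequentialSimilarity <- function(pool, corpus, dropUnannotated = FALSE) {
    stopifnot(is(pool, "PathPool"))
    cache <- new.env(parent = emptyenv())
    out <- numeric(0)
    for (p in pool@paths) {
        r <- sequentialSimilarity(p, corpus, cache)
        if (dropUnannotated && any(r$flagged)) next
        out <- c(out, r$ss)
    }
    out
}

#' Compare flow-central path similarity against both null path ensembles
#'
#' Right-sided Mann-Whitney tests of the flow-central paths' sequential
#' similarities against the Type A (length-preserved) and Type B
#' (endpoint-preserved) null pools, aggregated by the worst case
#' \code{max(pA, pB)}.
#'
#' @param fcPool,typeAPool,typeBPool [PathPool-class] objects.
#' @param corpus an [AnnotationCorpus-class].
#' @param dropUnannotated see [poolSequentialSimilarity()].
#' @return list with \code{pA}, \code{pB}, \code{worstCase} and the three
#'   SS vectors (\code{ssFc}, \code{ssA}, \code{ssB}).
#' @export
ssCompare <- function(fcPool, typeAPool, typeBPool, corpus,
                      dropUnannotated = FALSE) {
    ssFc <- poolSequentialSimilarity(fcPool, corpus, dropUnannotated)
    ssA <- poolSequentialSimilarity(typeAPool, corpus, dropUnannotated)
    ssB <- poolSequentialSimilarity(typeBPool, corpus, dropUnannotated)
    if (length(ssFc) < 2L || length(ssA) < 2L || length(ssB) < 2L)
        stop("each pool must yield at least two similarity values",
             call. = FALSE)
    pA <- mannWhitneyRight(ssFc, ssA)
    pB <- mannWhitneyRight(ssFc, ssB)
    list(pA = pA, pB = pB, worstCase = worstCase(c(pA, pB)),
         ssFc = ssFc, ssA = ssA, ssB = ssB)
}

#' Rank ontology terms occurring along flow-central paths
#'
#' Reporting helper: for each term annotated (after propagation) to every
#' gene of at least one path, reports the number of supporting paths and
#' the term's information content, ordered by information content.
#'
#' @param pool a [PathPool-class].
#' @param corpus an [AnnotationCorpus-class].
#' @param topN number of terms to keep (default 50).
#' @return data.frame with columns \code{term}, \code{ic}, \code{nPaths}.
#' @export
rankPathTerms <- function(pool, corpus, topN = 50L) {
    stopifnot(is(pool, "PathPool"), is(corpus, "AnnotationCorpus"))
    tally <- integer(length(corpus@terms))
    names(tally) <- corpus@terms
    for (p in pool@paths) {
        sets <- corpus@propagated[p]
        if (any(vapply(sets, is.null, NA))) next
        shared <- Reduce(intersect, sets)
        tally[shared] <- tally[shared] + 1L
    }
    keep <- tally > 0L
    out <- data.frame(term = names(tally)[keep], ic = corpus@ic[keep],
                      nPaths = unname(tally[keep]),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(-out$ic, -out$nPaths, out$term), , drop = FALSE]
    utils::head(out, topN)
}
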