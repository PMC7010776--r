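# helper: write a small expression dataset to temp TSVs
writeExprFiles <- function(mat, mapping = NULL, classes = NULL) {
    mf <- tempfile(fileext = ".tsv")
    df <- data.frame(probe = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(matrix = mf, mapping = NULL, classes = NULL)
    if (!is.null(mapping)) {
        out$mapping <- tempfile(fileext = ".tsv")
        utils::write.table(mapping, out$mapping, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(classes)) {
        out$classes <- tempfile(fileext = ".tsv")
        utils::write.table(classes, out$classes, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    out
}

test_that("expression loading maps probes, labels samples and validates logs", {
    mat <- matrix(c(1, 2, 3, 4,
                    2, 4, 6, 8,
                    5, 5, 5, 5), nrow = 3, byrow = TRUE,
                  dimnames = list(c("p1", "p2", "p3"),
                                  c("s1", "s2", "s3", "s4")))
    fs <- writeExprFiles(mat,
                         mapping = data.frame(c("p1", "p2"), c("gA", "gB")),
                         classes = data.frame(c("s1", "s2", "s3"),
                                              c("case", "case", "ctrl")))
    expect_warning(se <- loadExpression(fs$matrix, fs$mapping, fs$classes),
                   "unmapped")
    expect_equal(nrow(se), 2L)   # p3 dropped
    expect_equal(SummarizedExperiment::rowData(se)$gene, c("gA", "gB"))
    expect_equal(SummarizedExperiment::colData(se)$class,
                 c("case", "case", "ctrl", "unlabeled"))

    fs2 <- writeExprFiles(mat)
    se2 <- loadExpression(fs2$matrix, log2Transform = TRUE)
    expect_equal(unname(SummarizedExperiment::assay(se2)["p1", "s2"]), 1)
    mat0 <- mat; mat0["p2", "s3"] <- 0
    fs3 <- writeExprFiles(mat0)
    expect_error(loadExpression(fs3$matrix, log2Transform = TRUE),
                 "p2.*s3")
    # mapping that matches nothing is fatal
    fs4 <- writeExprFiles(mat, mapping = data.frame("zz", "gZ"))
    expect_error(loadExpression(fs4$matrix, fs4$mapping), "no probe maps")
})

test_that("pair coexpression takes the best probe pair in absolute value", {
    x <- c(1, 2, 3, 4, 5)
    mat <- rbind(gA.1 = x, gA.2 = c(2, 1, 4, 3, 5),
                 gB.1 = -x, gB.2 = c(5, 5, 5, 5, 5))
    colnames(mat) <- paste0("s", 1:5)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        rowData = S4Vectors::DataFrame(gene = c("gA", "gA", "gB", "gB")),
        colData = S4Vectors::DataFrame(class = rep("all", 5),
                                       row.names = colnames(mat)))
    # perfectly anti-correlated probes: |rho| = 1; the flat probe is skipped
    expect_equal(genePairCoexpression(se, "gA", "gB"), 1)
    # hand-computed max over the (2 x 1) varying probe pairs
    want <- max(abs(stats::cor(x, -x)), abs(stats::cor(c(2, 1, 4, 3, 5), -x)))
    expect_equal(genePairCoexpression(se, "gA", "gB"), want)
    # identical vectors
    se2 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = rbind(u.1 = x, v.1 = x)),
        rowData = S4Vectors::DataFrame(gene = c("u", "v")),
        colData = S4Vectors::DataFrame(class = rep("all", 5),
                                       row.names = paste0("s", 1:5)))
    expect_equal(genePairCoexpression(se2, "u", "v"), 1)
    # absent gene or all-degenerate probes: undefined
    expect_true(is.na(genePairCoexpression(se, "gA", "gZ")))
    seFlat <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = rbind(u.1 = x, v.1 = rep(1, 5))),
        rowData = S4Vectors::DataFrame(gene = c("u", "v")),
        colData = S4Vectors::DataFrame(class = rep("all", 5),
                                       row.names = paste0("s", 1:5)))
    expect_true(is.na(genePairCoexpression(seFlat, "u", "v")))
})

test_that("sequential coexpression on a printed toy matrix", {
    m <- rbind(a.1 = c(1, 2, 3, 4),
               b.1 = c(1, 3, 2, 4),
               c.1 = c(4, 3, 2, 1))
    colnames(m) <- paste0("s", 1:4)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = m),
        rowData = S4Vectors::DataFrame(gene = c("a", "b", "c")),
        colData = S4Vectors::DataFrame(class = rep("all", 4),
                                       row.names = colnames(m)))
    want <- mean(c(abs(stats::cor(m[1, ], m[2, ])),
                   abs(stats::cor(m[2, ], m[3, ]))))
    expect_equal(sequentialCoexpression(c("a", "b", "c"), se), want,
                 tolerance = 1e-12)
    # a missing gene nullifies the whole path
    expect_true(is.na(sequentialCoexpression(c("a", "zz", "c"), se)))
    # perfectly correlated adjacent pairs
    expect_equal(sequentialCoexpression(c("a", "c"), se), 1)
})

test_that("coexpression is invariant to affine transforms and sample order", {
    set.seed(9)
    genesV <- paste0("g", 1:6)
    se <- makeSyntheticExpression(genesV, list(genesV[1:3]), nSamples = 12,
                                  seed = 31)
    path <- c("g1", "g2", "g3")
    base <- sequentialCoexpression(path, se, class = "disease")
    m <- SummarizedExperiment::assay(se)
    # affine: scale and shift every probe
    se2 <- se
    SummarizedExperiment::assay(se2) <- 3.7 * m + 11
    expect_equal(sequentialCoexpression(path, se2, class = "disease"), base,
                 tolerance = 1e-12)
    # permute samples (classes permuted consistently)
    perm <- sample(ncol(se))
    se3 <- se[, perm]
    expect_equal(sequentialCoexpression(path, se3, class = "disease"), base,
                 tolerance = 1e-12)
})

test_that("pool bookkeeping counts valid plus null paths", {
    genesV <- paste0("g", 1:8)
    se <- makeSyntheticExpression(genesV[1:6], list(), nSamples = 10,
                                  seed = 5)
    pool <- new("PathPool",
                paths = list(c("g1", "g2"), c("g3", "g7"), c("g5", "g6")),
                provenance = "typeA", meta = list())
    r <- poolSequentialCoexpression(pool, se)
    expect_equal(r$nValid + r$nNull, 3L)
    expect_equal(r$nNull, 1L)   # g7 is absent from the matrix
    expect_length(r$sc, r$nValid)
})

test_that("dataset comparison aggregates the least significant class", {
    sim <- smallFixture()
    net <- sim$interactome
    g <- genes(net)
    set.seed(17)
    fcp <- new("PathPool",
               paths = replicate(15, sample(g, 3L), simplify = FALSE),
               provenance = "fc", meta = list())
    nul <- new("PathPool",
               paths = replicate(30, sample(g, 3L), simplify = FALSE),
               provenance = "typeA", meta = list())
    se <- makeSyntheticExpression(g, list(), nSamples = 20, seed = 6)
    sc <- scCompare(fcp, nul, nul, se)
    expect_setequal(sc$perClass$class, c("disease", "control"))
    expect_equal(sc$perClass$worstCase,
                 pmax(sc$perClass$pA, sc$perClass$pB))
    expect_equal(sc$worstCase, max(sc$perClass$worstCase))
    expect_equal(sc$score, -log10(sc$worstCase))
})

test_that("coexpression comparisons are calibrated on white-noise data", {
    # independent walk pools on unstructured expression: right-sided MW
    # p-values are uniform (KS check); dependence caveats in the vignette
    net <- smallFixture()$interactome
    g <- genes(net)
    p <- numeric(100)
    for (i in seq_len(100)) {
        x <- sampleTypeA(net, c(3L, 4L), 40L, seed = i * 11 + 1L)
        y <- sampleTypeA(net, c(3L, 4L), 80L, seed = i * 11 + 2L)
        se0 <- makeSyntheticExpression(g, list(), factorLoading = 0,
                                       nSamples = 20, seed = i * 11 + 3L)
        p[i] <- mannWhitneyRight(
            poolSequentialCoexpression(x, se0, "disease")$sc,
            poolSequentialCoexpression(y, se0, "disease")$sc)
    }
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
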