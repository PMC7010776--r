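test_that("geodesic enumeration finds every shortest path deterministically", {
    # two parallel geodesics a-x-b and a-y-b
    par <- Interactome(cbind(c("a", "a", "x", "y"), c("x", "y", "b", "b")))
    pool <- enumerateSeedShortestPaths(par, "a", "b")
    expect_setequal(vapply(paths(pool), paste, "", collapse = "-"),
                    c("a-x-b", "a-y-b"))

    # direct edge: the 2-gene path
    direct <- Interactome(cbind(c("a", "b"), c("b", "c")))
    p2 <- enumerateSeedShortestPaths(direct, "a", "b")
    expect_equal(paths(p2), list(c("a", "b")))

    # 3x3 grid corner to corner: 6 geodesics, capped at 3, stable
    grid <- igraph::make_lattice(c(3, 3))
    igraph::V(grid)$name <- sprintf("v%02d", 1:9)
    gnet <- Interactome(grid)
    full <- enumerateSeedShortestPaths(gnet, "v01", "v09")
    expect_length(full, 6L)
    capped1 <- suppressMessages(
        enumerateSeedShortestPaths(gnet, "v01", "v09", perPairCap = 3L))
    capped2 <- suppressMessages(
        enumerateSeedShortestPaths(gnet, "v01", "v09", perPairCap = 3L))
    expect_length(capped1, 3L)
    expect_identical(paths(capped1), paths(capped2))
    expect_true(all(vapply(paths(capped1), paste, "", collapse = "-") %in%
                    vapply(paths(full), paste, "", collapse = "-")))
})

test_that("flow-central path selection equals a brute-force re-filter", {
    r <- studyReplicate(1L)
    tb <- fcTable(r$fcs)
    fcs <- stats::setNames(tb$fcs, tb$gene)
    supp <- stats::setNames(tb$support, tb$gene)
    want <- Filter(function(p) {
        if (length(p) < 3L) return(FALSE)
        mid <- p[-c(1L, length(p))]
        all(fcs[mid] > 2) && all(supp[mid] >= 5)
    }, paths(r$pool))
    want <- want[!duplicated(vapply(want, paste, "", collapse = "-"))]
    got <- paths(r$fcp)
    expect_setequal(vapply(got, paste, "", collapse = "-"),
                    vapply(want, paste, "", collapse = "-"))

    # order invariance
    shuffled <- new("PathPool", paths = rev(r$pool@paths),
                    provenance = "shortest", meta = list())
    got2 <- paths(selectFcPaths(shuffled, r$fcs))
    expect_setequal(vapply(got2, paste, "", collapse = "-"),
                    vapply(got, paste, "", collapse = "-"))
})

test_that("threshold strictness, intermediate-free paths and relaxed mode", {
    net <- Interactome(cbind(c("a", "m", "a"), c("m", "b", "b")))
    mkFcs <- function(fcsM, empM) new("FlowCentralityResult",
        table = data.frame(gene = c("a", "m", "b"), fc = c(0, 0.5, 0),
                           muNull = 0, sigmaNull = 1,
                           fcs = c(0, fcsM, 0), empP = c(1, empM, 1),
                           support = c(0, 10, 0)),
        nSamples = 10L, mode = "degree_only", seed = 1L,
        pooledNull = FALSE)
    pool <- enumerateSeedShortestPaths(net, "a", "b")  # direct a-b only
    pool3 <- new("PathPool", paths = list(c("a", "m", "b"), c("a", "b")),
                 provenance = "shortest", meta = list())
    # fcs exactly 2: excluded by the strict default, kept when inclusive
    expect_length(selectFcPaths(pool3, mkFcs(2, 0.5)), 0L)
    expect_length(selectFcPaths(pool3, mkFcs(2, 0.5), inclusive = TRUE), 1L)
    # 2-gene paths never qualify (no mediator information)
    expect_length(selectFcPaths(pool3, mkFcs(5, 0.5)), 1L)
    # relaxed mode admits significant empirical p even with low fcs
    expect_length(selectFcPaths(pool3, mkFcs(0, 0.01), relaxed = TRUE), 1L)
    expect_length(selectFcPaths(pool3, mkFcs(0, 0.2), relaxed = TRUE), 0L)
    # support below the minimum excludes the path
    lowSupp <- mkFcs(5, 0.5)
    lowSupp@table$support <- c(0, 3, 0)
    expect_length(selectFcPaths(pool3, lowSupp), 0L)
})

test_that("length-preserved walks realize each drawn length exactly", {
    net <- smallFixture()$interactome
    ta <- sampleTypeA(net, c(3L, 3L, 4L), 50L, seed = 31L)
    expect_length(ta, 50L)
    expect_true(all(pathLengthHistogram(ta) %in% c(3L, 4L)))
    expect_identical(pathLengthHistogram(ta), ta@meta$drawnLengths)
    # all 3s: every path has exactly 3 distinct adjacent genes
    t3 <- sampleTypeA(net, 3L, 20L, seed = 32L)
    expect_true(all(pathLengthHistogram(t3) == 3L))
    g <- interactomeGraph(net)
    for (p in paths(t3)) {
        expect_false(anyDuplicated(p) > 0L)
        for (i in seq_len(length(p) - 1L))
            expect_true(igraph::are_adjacent(g, p[i], p[i + 1L]))
    }
    # deterministic under the seed
    expect_identical(paths(sampleTypeA(net, c(3L, 4L), 10L, seed = 7L)),
                     paths(sampleTypeA(net, c(3L, 4L), 10L, seed = 7L)))
    # unrealizable length
    tiny <- Interactome(cbind(c("a", "b"), c("b", "c")))
    expect_error(sampleTypeA(tiny, 4L, 5L, seed = 1L), "length 4")
    expect_error(sampleTypeA(net, integer(0), 5L), "non-empty")
})

test_that("random-walk endpoints are uniform on a complete graph", {
    k5 <- Interactome(t(utils::combn(paste0("k", 1:5), 2L)))
    ta <- sampleTypeA(k5, 2L, 10000L, seed = 41L)
    ends <- table(vapply(paths(ta), paste, "", collapse = "-"))
    expect_length(ends, 20L)   # all ordered pairs occur
    chi <- stats::chisq.test(as.vector(ends))
    expect_gt(chi$p.value, 0.01)
})

test_that("endpoint-preserved draws are uniform with replacement", {
    one <- new("PathPool", paths = list(c("a", "b", "c")),
               provenance = "shortest", meta = list())
    tb1 <- sampleTypeB(one, 25L, seed = 5L)
    expect_true(all(vapply(paths(tb1), identical, NA, c("a", "b", "c"))))
    expect_identical(paths(sampleTypeB(one, 5L, seed = 2L)),
                     paths(sampleTypeB(one, 5L, seed = 2L)))
    expect_error(sampleTypeB(new("PathPool", paths = list(),
                                 provenance = "shortest", meta = list()),
                             5L), "empty")
})

test_that("seed-to-set sampling draws geodesics uniformly per pair", {
    # unique geodesic: all draws identical
    pathNet <- Interactome(cbind(c("a", "b"), c("b", "c")))
    sp <- sampleSeedToSetPaths(pathNet, "a", "c", 10L, seed = 3L)
    expect_true(all(vapply(paths(sp), identical, NA, c("a", "b", "c"))))

    # two geodesics: close to 50/50 within 3 sigma
    par <- Interactome(cbind(c("a", "a", "x", "y"), c("x", "y", "b", "b")))
    sp2 <- sampleSeedToSetPaths(par, "a", "b", 6000L, seed = 4L)
    fx <- mean(vapply(paths(sp2), function(p) p[2L] == "x", NA))
    expect_lt(abs(fx - 0.5), 3 * sqrt(0.25 / 6000))
    expect_identical(paths(sampleSeedToSetPaths(par, "a", "b", 20L, seed = 9L)),
                     paths(sampleSeedToSetPaths(par, "a", "b", 20L, seed = 9L)))
})

test_that("every generated pool satisfies the path invariants", {
    r <- studyReplicate(1L)
    g <- interactomeGraph(r$net)
    checkPool <- function(pool) {
        for (p in paths(pool)) {
            expect_gte(length(p), 2L)
            expect_false(anyDuplicated(p) > 0L)
            for (i in seq_len(length(p) - 1L))
                expect_true(igraph::are_adjacent(g, p[i], p[i + 1L]))
        }
    }
    checkPool(r$fcp)
    checkPool(r$typeA)
    checkPool(r$typeB)
    # fc pool paths are geodesics between seed genes
    d <- igraph::distances(g)
    for (p in paths(r$fcp)) {
        expect_true(p[1L] %in% r$sim$seedsA || p[1L] %in% r$sim$seedsB)
        expect_equal(d[p[1L], p[length(p)]], length(p) - 1)
    }
})

test_that("path pools round-trip through their TSV serialization", {
    r <- studyReplicate(1L)
    f <- withr::local_tempfile()
    writePathPool(r$fcp, f)
    back <- readPathPool(f)
    expect_identical(paths(back), paths(r$fcp))
    expect_identical(back@provenance, "fc")
})
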