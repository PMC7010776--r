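test_that("information content follows propagated annotation frequencies", {
    corp <- toyCorpus()
    # 8 annotated genes in total; every gene reaches the root
    expect_equal(unname(corp@ic["R"]), 0)
    # A1 is annotated (after propagation) to g1, g2, g8 -> ic = -log(3/8)
    expect_equal(unname(corp@ic["A1"]), -log(3 / 8), tolerance = 1e-12)
    # B1 -> g3, g4
    expect_equal(unname(corp@ic["B1"]), -log(2 / 8), tolerance = 1e-12)
    # propagation closes ancestor chains
    expect_setequal(corp@propagated$g1, c("A1", "A", "R"))
    expect_setequal(corp@propagated$g4, c("A2", "A", "B1", "B", "R"))
    # root-only annotations carry no information
    rootOnly <- buildCorpus(list(R = character(0)),
                            data.frame(gene = c("x", "y"), term = "R"))
    expect_true(all(rootOnly@ic == 0))
    # ic monotone from root to leaves along is_a chains
    for (t in corp@terms) for (p in corp@parents[[t]])
        expect_gte(corp@ic[[t]], corp@ic[[p]] - 1e-12)
})

test_that("corpus construction rejects cycles and unknown annotations", {
    expect_error(buildCorpus(list(a = "b", b = "a"),
                             data.frame(gene = "g", term = "a")), "cycle")
    expect_warning(
        c2 <- buildCorpus(list(R = character(0), A = "R"),
                          data.frame(gene = c("g", "g"),
                                     term = c("A", "NOPE"))),
        "unknown")
    expect_setequal(c2@propagated$g, c("A", "R"))
    expect_error(suppressWarnings(
        buildCorpus(list(R = character(0)),
                    data.frame(gene = "g", term = "X"))), "no annotated")
})

test_that("OBO stanzas parse into the term hierarchy", {
    f <- withr::local_tempfile(fileext = ".obo")
    writeLines(c(
        "format-version: 1.2", "",
        "[Term]", "id: T:1", "name: root", "namespace: nsA", "",
        "[Term]", "id: T:2", "name: mid", "namespace: nsA",
        "is_a: T:1 ! root", "",
        "[Term]", "id: T:3", "name: dead", "is_obsolete: true", "",
        "[Typedef]", "id: part_of"), f)
    obo <- readOBO(f)
    expect_setequal(obo$terms$id, c("T:1", "T:2"))
    expect_equal(obo$parents[["T:2"]], "T:1")
    corp <- buildCorpus(obo, data.frame(gene = "g", term = "T:2"),
                        namespace = "nsA")
    expect_setequal(corp@propagated$g, c("T:1", "T:2"))
})

test_that("Resnik similarity is the most informative common ancestor", {
    corp <- toyCorpus()
    expect_equal(resnikSim(corp, "A1", "A1"), unname(corp@ic["A1"]))
    # disjoint branches below the root share only R (ic 0)
    expect_equal(resnikSim(corp, "A1", "B1"), 0)
    expect_equal(resnikSim(corp, "A1", "A2"), unname(corp@ic["A"]))
    expect_error(resnikSim(corp, "A1", "Z9"), "absent")

    # random layered DAGs vs an exhaustive common-ancestor scan with an
    # independently recomputed ancestor closure
    for (s in 1:5) {
        rc <- makeSyntheticOntology(paste0("g", 1:20), nTerms = 25L,
                                    depth = 3L, seed = s)
        closure <- function(t) {
            out <- t
            frontier <- t
            while (length(frontier)) {
                ps <- unique(unlist(rc@parents[frontier], use.names = FALSE))
                frontier <- setdiff(ps, out)
                out <- c(out, frontier)
            }
            out
        }
        set.seed(s)
        for (k in 1:10) {
            ab <- sample(rc@terms, 2L)
            common <- intersect(closure(ab[1L]), closure(ab[2L]))
            want <- if (length(common)) max(rc@ic[common]) else 0
            expect_equal(resnikSim(rc, ab[1L], ab[2L]), want,
                         tolerance = 1e-12)
        }
    }
})

test_that("best-match-average matches exhaustive term-pair evaluation", {
    corp <- toyCorpus()
    # identical singleton annotation sets: similarity is the term's ic
    expect_equal(bmaSimilarity(corp, "g1", "g1"), unname(corp@ic["A1"]))
    # genes annotated only in disjoint root branches
    expect_equal(bmaSimilarity(corp, "g1", "g3"), 0)
    # |U| = 2, |V| = 1 case by hand: U = {A1, A2} (g2), V = {B1, A2} (g4)
    simM <- outer(c("A1", "A2"), c("A2", "B1"),
                  Vectorize(function(a, b) resnikSim(corp, a, b)))
    want <- (sum(apply(simM, 1, max)) + sum(apply(simM, 2, max))) / 4
    expect_equal(bmaSimilarity(corp, "g2", "g4"), want, tolerance = 1e-12)
    # unannotated gene signals undefined similarity
    expect_true(is.na(bmaSimilarity(corp, "g1", "unknown")))
    # symmetry on random annotated pairs
    gs <- names(corp@direct)
    set.seed(2)
    for (k in 1:10) {
        uv <- sample(gs, 2L)
        expect_equal(bmaSimilarity(corp, uv[1L], uv[2L]),
                     bmaSimilarity(corp, uv[2L], uv[1L]), tolerance = 1e-12)
    }
})

test_that("sequential similarity averages adjacent-pair similarities", {
    corp <- toyCorpus()
    # 2-gene path with identical singleton annotations
    r <- sequentialSimilarity(c("g1", "g8"), corp)   # both only A1
    expect_equal(r$ss, unname(corp@ic["A1"]))
    # root-only annotations give zero everywhere
    rootCorp <- buildCorpus(list(R = character(0)),
                            data.frame(gene = c("u", "v", "w"), term = "R"))
    expect_equal(sequentialSimilarity(c("u", "v", "w"), rootCorp)$ss, 0)
    # 3-gene path equals the mean of the two pair values
    r3 <- sequentialSimilarity(c("g1", "g2", "g4"), corp)
    expect_equal(r3$ss, mean(c(bmaSimilarity(corp, "g1", "g2"),
                               bmaSimilarity(corp, "g2", "g4"))),
                 tolerance = 1e-12)
    expect_length(r3$pairValues, 2L)
    # unannotated gene: pair contributes zero and is flagged
    rf <- sequentialSimilarity(c("g1", "zz"), corp)
    expect_equal(rf$ss, 0)
    expect_true(rf$flagged[1L])
    expect_error(sequentialSimilarity("g1", corp), "two genes")
})

test_that("similarity comparison aggregates by the least significant test", {
    corp <- toyCorpus()
    mkPool <- function(ps) new("PathPool", paths = ps,
                               provenance = "typeA", meta = list())
    hi <- mkPool(rep(list(c("g1", "g8")), 10))   # ss = ic(A1) each
    lo <- mkPool(rep(list(c("g1", "g3")), 10))   # ss = 0 each
    cmp <- suppressWarnings(ssCompare(hi, lo, lo, corp))
    # every value above every null value: maximally significant one-sided p
    # (tie-corrected normal here, since SS values tie within groups)
    expect_lt(cmp$pA, 1e-3)
    expect_equal(cmp$pA, mannWhitneyRight(poolSequentialSimilarity(hi, corp),
                                          poolSequentialSimilarity(lo, corp)),
                 tolerance = 1e-12)
    expect_equal(cmp$worstCase, max(cmp$pA, cmp$pB))
    same <- suppressWarnings(ssCompare(hi, hi, hi, corpus = corp))
    expect_gt(same$pA, 0.3)
    expect_lt(same$pA, 0.7)
})

test_that("similarity comparisons are calibrated for independent path groups", {
    # Pools of mutually independent self-avoiding walks under annotations
    # with no path-aligned structure: the right-sided MW p-value should be
    # uniform. (Geodesic ensembles sharing genes violate the independence
    # assumption and are overdispersed; see the vignette.)
    net <- smallFixture()$interactome
    g <- genes(net)
    p <- numeric(60)
    for (i in seq_len(60)) {
        x <- sampleTypeA(net, c(3L, 3L, 4L, 4L, 5L), 60L, seed = i * 7 + 1L)
        y <- sampleTypeA(net, c(3L, 3L, 4L, 4L, 5L), 120L, seed = i * 7 + 2L)
        corp0 <- makeSyntheticOntology(g, list(), seed = i * 7 + 3L)
        p[i] <- mannWhitneyRight(poolSequentialSimilarity(x, corp0),
                                 poolSequentialSimilarity(y, corp0))
    }
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("wilcox.test p-values cannot change under a joint ic rescaling", {
    corp <- toyCorpus()
    mkPool <- function(ps) new("PathPool", paths = ps,
                               provenance = "typeA", meta = list())
    set.seed(4)
    gs <- names(corp@direct)
    pl <- mkPool(replicate(8, sample(gs, 3L), simplify = FALSE))
    ql <- mkPool(replicate(12, sample(gs, 3L), simplify = FALSE))
    ssP <- poolSequentialSimilarity(pl, corp)
    ssQ <- poolSequentialSimilarity(ql, corp)
    # any log base rescales all similarities by one constant
    expect_equal(mannWhitneyRight(ssP, ssQ),
                 mannWhitneyRight(ssP / log(2), ssQ / log(2)),
                 tolerance = 1e-12)
})

test_that("term ranking reports shared high-information terms", {
    corp <- toyCorpus()
    pool <- new("PathPool", paths = list(c("g1", "g2"), c("g1", "g8")),
                provenance = "fc", meta = list())
    rk <- rankPathTerms(pool, corp)
    expect_true("A1" %in% rk$term)
    expect_equal(rk$nPaths[rk$term == "R"], 2L)
    expect_true(all(diff(rk$ic) <= 1e-12))
})
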