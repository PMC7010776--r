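# Shared study replicates on the planted-bridge benchmark, memoized so the
# acceptance blocks and module tests reuse the same (seeded, deterministic)
# computations instead of recomputing them. One replicate = graph + FCS at
# 200 null samples + seed-to-seed geodesic pool + flow-central paths +
# Type A / Type B ensembles of 200 paths each.

.studyCache <- new.env(parent = emptyenv())

studyReplicate <- function(i) {
    key <- paste0("r", i)
    if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
    sim <- makePlantedBridgeGraph(plantedBridgeSpec(), seed = i)
    net <- sim$interactome
    fcs <- flowCentralityScore(net, sim$moduleA, sim$moduleB,
                               nSamples = 200L, mode = "degree_only",
                               seed = i + 1000L)
    pool <- enumerateSeedShortestPaths(net, sim$seedsA, sim$seedsB)
    fcp <- selectFcPaths(pool, fcs)
    typeA <- sampleTypeA(net, pathLengthHistogram(fcp), 200L,
                         seed = i + 2000L)
    typeB <- sampleTypeB(pool, 200L, seed = i + 3000L)
    res <- list(sim = sim, net = net, fcs = fcs, pool = pool, fcp = fcp,
                typeA = typeA, typeB = typeB)
    .studyCache[[key]] <- res
    res
}

# a small, fast fixture for calibration-style property tests
smallFixture <- function() {
    if (is.null(.studyCache$small)) {
        spec <- plantedBridgeSpec(nA = 30L, nB = 30L, nBackground = 60L,
                                  pIn = 0.2, pBackground = 0.05,
                                  nSeeds = 6L)
        .studyCache$small <- makePlantedBridgeGraph(spec, seed = 99L)
    }
    .studyCache$small
}
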