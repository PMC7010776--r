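# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: path counting by exhaustive geodesic
# enumeration (igraph), hypergeometric tails by direct combinatorial
# summation, and rank tests by full enumeration of rank assignments.

# brute-force tail sum of the connectivity hypergeometric
bruteHyper <- function(k, ks, s, N) {
    ki <- ks:k
    sum(choose(s, ki) * choose(N - s, k - ki)) / choose(N, k)
}

# exhaustive flow centrality: enumerate every geodesic for every ordered
# (s, t) pair and count strictly-interior occurrences
fcEnumerate <- function(net, S, Tset) {
    g <- interactomeGraph(net)
    nm <- genes(net)
    fc <- stats::setNames(numeric(length(nm)), nm)
    for (s in S) {
        for (t in Tset) {
            if (s == t) next
            asp <- suppressWarnings(
                igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
            if (!length(asp)) next
            sigma <- length(asp)
            for (p in asp) {
                ids <- igraph::V(g)$name[as.integer(p)]
                inner <- ids[-c(1L, length(ids))]
                fc[inner] <- fc[inner] + 1 / sigma
            }
        }
    }
    fc / (length(S) * length(Tset))
}

# exact right-sided Mann-Whitney p by enumerating all rank assignments
mwEnumerate <- function(x, y) {
    m <- length(x); n <- length(y)
    r <- rank(c(x, y))
    wObs <- sum(r[seq_len(m)])
    combos <- utils::combn(m + n, m)
    wAll <- apply(combos, 2L, sum)   # rank sums: positions are the ranks
    mean(wAll >= wObs)
}

# random connected graph with named vertices
randomConnectedGraph <- function(n, p = 0.35, seed = 1) {
    set.seed(seed)
    repeat {
        g <- igraph::sample_gnp(n, p)
        if (igraph::is_connected(g) && igraph::ecount(g) > 0L) break
    }
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    Interactome(g)
}

# small hand-built annotation corpus:
#   R <- A <- A1, A2 ; R <- B <- B1
toyCorpus <- function() {
    parents <- list(R = character(0), A = "R", B = "R",
                    A1 = "A", A2 = "A", B1 = "B")
    ann <- data.frame(
        gene = c("g1", "g2", "g2", "g3", "g4", "g4", "g5", "g6", "g7", "g8"),
        term = c("A1", "A1", "A2", "B1", "A2", "B1", "R", "A", "B", "A1"))
    buildCorpus(parents, ann)
}
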