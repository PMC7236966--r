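twoCliqueBridge <- function() {
    netFromPairs(c(cliquePairs(c("a1", "a2", "a3", "a4")),
                   cliquePairs(c("b1", "b2", "b3", "b4")),
                   "a1-b1"), label = "planted")
}

test_that("greedy modularity recovers well-separated planted cliques", {
    part <- detectCommunities(twoCliqueBridge())
    expect_length(communities(part), 2L)
    expect_equal(canonicalSets(communities(part)),
                 canonicalSets(list(c("a1", "a2", "a3", "a4"),
                                    c("b1", "b2", "b3", "b4"))))
    # and matches the brute-force maximum-modularity partition
    best <- oracleMaxModularity(networkEdges(twoCliqueBridge()),
                                networkNodes(twoCliqueBridge()))
    expect_equal(canonicalSets(communities(part)),
                 canonicalSets(best$partition))
    expect_equal(modularityScore(part), best$q, tolerance = 1e-12)
})

test_that("a single clique stays one community", {
    k5 <- netFromPairs(cliquePairs(paste0("n", 1:5)), label = "k5")
    part <- detectCommunities(k5)
    expect_length(communities(part), 1L)
    best <- oracleMaxModularity(networkEdges(k5), networkNodes(k5))
    expect_equal(modularityScore(part), best$q, tolerance = 1e-12)
})

test_that("edgeless and isolated nodes become singletons", {
    edgeless <- Network(NULL, nodes = letters[1:4], label = "e")
    expect_warning(part <- detectCommunities(edgeless), "singleton")
    expect_length(communities(part), 4L)
    expect_equal(modularityScore(part), 0)

    iso <- Network(data.frame(from = "a", to = "b"),
                   nodes = c("a", "b", "z"), label = "iso")
    part2 <- detectCommunities(iso)
    expect_true(list("z") %in% communities(part2) ||
                any(vapply(communities(part2), identical, logical(1), "z")))
    expect_setequal(unlist(communities(part2)), c("a", "b", "z"))
})

test_that("partitions are disjoint covers and Q matches the direct formula", {
    set.seed(55)
    for (rep in 1:10) {
        nodes <- sprintf("v%02d", 1:25)
        net <- Network(randomEdgeDf(nodes, 45), nodes = nodes, label = "r")
        part <- detectCommunities(net)
        members <- unlist(communities(part))
        expect_setequal(members, networkNodes(net))
        expect_false(anyDuplicated(members) > 0)
        expect_equal(modularityScore(part),
                     directModularity(networkEdges(net), communities(part)),
                     tolerance = 1e-12)
        # size ordering with lexicographic tie-break
        sizes <- lengths(communities(part))
        expect_true(!is.unsorted(rev(sizes)))
    }
})

test_that("greedy Q never exceeds the brute-force maximum on tiny graphs", {
    set.seed(66)
    for (rep in 1:5) {
        nodes <- sprintf("v%d", 1:7)
        net <- Network(randomEdgeDf(nodes, sample(6:12, 1)),
                       nodes = nodes, label = "r")
        part <- detectCommunities(net)
        best <- oracleMaxModularity(networkEdges(net), networkNodes(net))
        expect_lte(modularityScore(part), best$q + 1e-12)
    }
})

test_that("community table interleaves networks strictly by size", {
    n1 <- twoCliqueBridge()
    n2 <- netFromPairs(cliquePairs(paste0("c", 1:5)), label = "k5")
    coll <- loadCollection(list(n1, n2))
    tab <- communityTable(coll)
    expect_true(!is.unsorted(rev(tab$size)))
    expect_equal(tab$network[1], "k5")  # largest community first
    expect_setequal(unique(tab$network), c("planted", "k5"))
    expect_false(anyNA(tab$color))
})

test_that("community queries support all/any semantics", {
    tab <- data.frame(network = "n", color = "#000000",
                      communityId = 1:2, size = c(3L, 2L),
                      stringsAsFactors = FALSE)
    tab$members <- list(c("a", "b", "c"), c("d", "e"))

    hit <- queryCommunities(tab, c("a", "b"), mode = "all")
    expect_equal(hit$communityId, 1L)
    expect_equal(nrow(queryCommunities(tab, c("a", "d"), mode = "all")), 0L)
    expect_equal(nrow(queryCommunities(tab, c("a", "d"), mode = "any")), 2L)
    expect_error(queryCommunities(tab, c("a", "nope")), "nope")
})

test_that("transition scoring reproduces hand-enumerated examples", {
    pa <- new("Partition", label = "A",
              communities = list(c("a", "b", "c"), c("d", "e", "f")),
              modularity = NA_real_)
    # identical partitions: diagonal jaccards 1, weighted = 2/4*100
    same <- communityTransitions(pa, pa)
    expect_equal(same@sumJaccard, 2)
    expect_equal(same@comparisons, 4)
    expect_equal(same@weightedSumJaccard, 50)

    pb <- new("Partition", label = "B",
              communities = list(c("c", "d", "e", "f"), c("a", "b")),
              modularity = NA_real_)
    tr <- communityTransitions(pa, pb)
    expect_equal(sort(as.numeric(tr@jaccard)), sort(c(2/3, 1/6, 0, 3/4)))
    expect_equal(tr@sumJaccard, 2/3 + 1/6 + 3/4)   # ~1.5833
    expect_equal(tr@weightedSumJaccard, (2/3 + 1/6 + 3/4) / 4 * 100,
                 tolerance = 1e-12)                 # ~39.58
    expect_equal(max(tr@intersections), 3L)

    # disjoint node sets: all scores zero
    pc <- new("Partition", label = "C",
              communities = list(c("x", "y"), c("z", "w")),
              modularity = NA_real_)
    zero <- communityTransitions(pa, pc)
    expect_equal(zero@sumJaccard, 0)
    expect_equal(zero@weightedSumJaccard, 0)
})

test_that("transition scores are invariant under relabeling and renaming", {
    pa <- new("Partition", label = "A",
              communities = list(c("a", "b", "c"), c("d", "e", "f")),
              modularity = NA_real_)
    pb <- new("Partition", label = "B",
              communities = list(c("c", "d", "e", "f"), c("a", "b")),
              modularity = NA_real_)
    base <- communityTransitions(pa, pb)

    # permute community order (relabeling; equal sizes keep the size order)
    p1 <- new("Partition", label = "P1",
              communities = list(c("a", "b", "c"), c("d", "e", "f")),
              modularity = NA_real_)
    p1Perm <- new("Partition", label = "P2",
                  communities = list(c("d", "e", "f"), c("a", "b", "c")),
                  modularity = NA_real_)
    expect_equal(communityTransitions(p1, pb)@sumJaccard,
                 communityTransitions(p1Perm, pb)@sumJaccard)
    expect_equal(communityTransitions(p1, pb)@weightedSumJaccard,
                 communityTransitions(p1Perm, pb)@weightedSumJaccard)

    # rename every node through a bijection
    ren <- function(x) chartr("abcdef", "uvwxyz", x)
    paR <- new("Partition", label = "A", modularity = NA_real_,
               communities = lapply(pa@communities, ren))
    pbR <- new("Partition", label = "B", modularity = NA_real_,
               communities = lapply(pb@communities, ren))
    renamed <- communityTransitions(paR, pbR)
    expect_equal(renamed@sumJaccard, base@sumJaccard)
    expect_equal(renamed@weightedSumJaccard, base@weightedSumJaccard)
})

test_that("splitting a community does not raise its best-match jaccard sum", {
    pa <- new("Partition", label = "A",
              communities = list(c("a", "b", "c", "d"), c("e", "f")),
              modularity = NA_real_)
    pb <- new("Partition", label = "B",
              communities = list(c("a", "b", "c", "d"), c("e", "f")),
              modularity = NA_real_)
    pbSplit <- new("Partition", label = "B",
                   communities = list(c("a", "b"), c("c", "d"), c("e", "f")),
                   modularity = NA_real_)
    bestBefore <- max(communityTransitions(pa, pb)@jaccard[1, ])
    bestAfter <- max(communityTransitions(pa, pbSplit)@jaccard[1, ])
    expect_lte(bestAfter, bestBefore)
})

test_that("transition flows give Sankey-ready node records", {
    pa <- new("Partition", label = "A",
              communities = list(c("a", "b", "c"), c("d", "e")),
              modularity = NA_real_)
    pb <- new("Partition", label = "B",
              communities = list(c("a", "d", "e"), c("b", "c")),
              modularity = NA_real_)
    fl <- transitionFlows(pa, pb)
    expect_equal(fl$fromCommunity[fl$node == "a"], 1L)
    expect_equal(fl$toCommunity[fl$node == "a"], 1L)
    expect_equal(fl$toCommunity[fl$node == "b"], 2L)
    expect_equal(nrow(fl), 5L)
})

test_that("rank embedding pools observations with average ranks", {
    # hand example: pooled values {1,2,2,5} -> ranks {1,2.5,2.5,4}
    expect_equal(rank(c(1, 2, 2, 5), ties.method = "average") / 4,
                 c(0.25, 0.625, 0.625, 1.0))

    n1 <- netFromPairs(c("h-x", "h-y", "h-z"), label = "n1")  # hub h deg 3
    n2 <- netFromPairs(c("x-y"), label = "n2")
    emb <- rankEmbedding(n1, n2)
    expect_equal(nrow(emb), numNodes(n1) + numNodes(n2))
    expect_true(all(emb$degree > 0 & emb$degree <= 1))
    # unique pooled maximum degree gets normalized rank 1
    expect_equal(emb$degree[emb$network == "n1" & emb$node == "h"], 1)

    # full tie: identical degree everywhere -> identical values
    c1 <- netFromPairs(c("a-b", "b-c", "c-a"), label = "c1")
    c2 <- netFromPairs(c("p-q", "q-r", "r-p"), label = "c2")
    embT <- rankEmbedding(c1, c2)
    expect_length(unique(embT$degree), 1L)
})

test_that("community exports round-trip", {
    part <- detectCommunities(twoCliqueBridge())
    js <- jsonlite::fromJSON(partitionToJSON(part), simplifyVector = FALSE)
    expect_equal(js$network, "planted")
    expect_length(js$communities, 2L)

    pa <- new("Partition", label = "A",
              communities = list(c("a", "b", "c"), c("d", "e", "f")),
              modularity = NA_real_)
    pb <- new("Partition", label = "B",
              communities = list(c("c", "d", "e", "f"), c("a", "b")),
              modularity = NA_real_)
    js2 <- jsonlite::fromJSON(transitionToJSON(communityTransitions(pa, pb)),
                              simplifyVector = FALSE)
    expect_equal(js2$comparisons, 4L)
    expect_length(js2$pair_scores, 3L)  # zero-overlap pair omitted
})
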