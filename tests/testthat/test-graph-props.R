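test_that("global properties match hand-computed values", {
    k3 <- netFromPairs(cliquePairs(c("a", "b", "c")))
    expect_equal(globalProperties(k3),
                 list(totalNodes = 3L, totalEdges = 3L,
                      clusterCoefficient = 1, density = 1))

    # path a-b-c: density 2*2/(3*2) = 2/3, no closed triples
    pth <- netFromPairs(c("a-b", "b-c"))
    gp <- globalProperties(pth)
    expect_equal(gp$clusterCoefficient, 0)
    expect_equal(gp$density, 2 / 3)

    edgeless <- Network(NULL, nodes = letters[1:5], label = "e")
    expect_equal(globalProperties(edgeless),
                 list(totalNodes = 5L, totalEdges = 0L,
                      clusterCoefficient = 0, density = 0))
})

test_that("cluster coefficient averages local values with degree<2 as zero", {
    # triangle a,b,c plus pendant d on a: cc(a)=1/3, cc(b)=cc(c)=1, cc(d)=0
    net <- netFromPairs(c("a-b", "b-c", "a-c", "a-d"))
    expect_equal(globalProperties(net)$clusterCoefficient,
                 mean(c(1 / 3, 1, 1, 0)))
    # global transitivity is the triangle ratio, a different statistic
    expect_equal(globalTransitivity(net), 3 * 1 / (3 + 2))
})

test_that("degree and betweenness follow raw-count conventions", {
    star <- netFromPairs(c("c-l1", "c-l2", "c-l3", "c-l4"))
    ct <- nodeCentralities(star, c("degree", "betweenness"))
    expect_equal(ct$degree[ct$node == "c"], 4)
    expect_equal(ct$betweenness[ct$node == "c"], choose(4, 2))

    pth <- netFromPairs(c("A-B", "B-C"))
    bw <- nodeCentralities(pth, "betweenness")
    expect_equal(setNames(bw$betweenness, bw$node),
                 c(A = 0, B = 1, C = 0))
})

test_that("betweenness agrees with brute-force path enumeration", {
    set.seed(42)
    for (rep in 1:12) {
        nodes <- sprintf("v%02d", seq_len(sample(6:10, 1)))
        ed <- randomEdgeDf(nodes, sample(5:14, 1))
        net <- Network(ed, nodes = nodes, label = "r")
        got <- nodeCentralities(net, "betweenness")
        expect_equal(setNames(got$betweenness, got$node),
                     oracleBetweenness(networkEdges(net), networkNodes(net)),
                     tolerance = 1e-10)
    }
})

test_that("degree sum equals twice the edge count", {
    set.seed(9)
    for (rep in 1:10) {
        nodes <- sprintf("v%02d", 1:20)
        net <- Network(randomEdgeDf(nodes, 35), nodes = nodes, label = "r")
        ct <- nodeCentralities(net, "degree")
        expect_equal(sum(ct$degree), 2 * numEdges(net))
    }
})

test_that("eigenvector centrality is constant on vertex-transitive graphs", {
    cyc <- netFromPairs(c("a-b", "b-c", "c-d", "d-e", "e-a"))
    ev <- nodeCentralities(cyc, "eigenvector")$eigenvector
    expect_equal(ev, rep(1, 5), tolerance = 1e-6)
    k4 <- netFromPairs(cliquePairs(letters[1:4]))
    expect_equal(nodeCentralities(k4, "eigenvector")$eigenvector,
                 rep(1, 4), tolerance = 1e-6)
})

test_that("HITS hub and authority coincide and are unit-max scaled", {
    set.seed(5)
    nodes <- sprintf("v%02d", 1:15)
    net <- Network(randomEdgeDf(nodes, 30), nodes = nodes, label = "r")
    ct <- nodeCentralities(net, c("hub", "authority", "eigenvector"))
    expect_identical(ct$hub, ct$authority)
    expect_equal(max(ct$hub), 1)
    expect_equal(ct$hub, ct$eigenvector)
    # bipartite structures must still converge (shifted iteration)
    bip <- netFromPairs(c("u1-w1", "u1-w2", "u2-w1", "u2-w2", "u3-w2"))
    expect_silent(ev <- nodeCentralities(bip, "eigenvector")$eigenvector)
    expect_equal(max(ev), 1)
})

test_that("eigenvector-family measures require at least one edge", {
    edgeless <- Network(NULL, nodes = c("a", "b"), label = "e")
    expect_error(nodeCentralities(edgeless, "hub"), "at least one edge")
    expect_silent(nodeCentralities(edgeless, c("degree", "coreness")))
})

test_that("eccentricity is computed within connected components", {
    k3 <- netFromPairs(cliquePairs(c("a", "b", "c")))
    expect_equal(nodeCentralities(k3, "eccentricity")$eccentricity,
                 rep(1, 3))
    two <- netFromPairs(c("a-b", "b-c", "x-y"))
    ecc <- nodeCentralities(two, "eccentricity")
    expect_equal(setNames(ecc$eccentricity, ecc$node),
                 c(a = 2, b = 1, c = 2, x = 1, y = 1))
})

test_that("delta centrality traces nodes across networks with ABSENT markers", {
    n1 <- netFromPairs(c("A-B", "A-C", "A-D"), label = "n1")
    n2 <- netFromPairs(c("A-B", "B-C"), label = "n2")
    coll <- loadCollection(list(n1, n2))

    dc <- deltaCentrality(coll, "degree")
    expect_equal(names(dc), c("node", "n1", "n2"))
    expect_true(is.na(dc$n2[dc$node == "D"]))  # absent, not zero
    # ordered by descending first-network value
    expect_equal(dc$node[1], "A")
    expect_true(!is.unsorted(rev(dc$n1), na.rm = TRUE))

    # identical networks give identical rows
    coll2 <- loadCollection(list(n1, netFromPairs(c("A-B", "A-C", "A-D"),
                                                  label = "copy")))
    dc2 <- deltaCentrality(coll2, "degree")
    expect_equal(dc2$n1, dc2$copy)

    expect_error(deltaCentrality(coll, "degree", nodes = c("A", "ZZZ")),
                 "ZZZ")
})

test_that("top-N delta centrality slices after sorting", {
    set.seed(2)
    nodes <- sprintf("v%02d", 1:20)
    n1 <- Network(randomEdgeDf(nodes, 40), nodes = nodes, label = "n1")
    n2 <- Network(randomEdgeDf(nodes, 40), nodes = nodes, label = "n2")
    coll <- loadCollection(list(n1, n2))
    dc <- deltaCentrality(coll, "degree", top = 10)
    expect_equal(nrow(dc), 10L)
    # sort-and-slice oracle on the first network's degrees
    full <- nodeCentralities(n1, "degree")
    expected <- sum(full$degree >= sort(full$degree, decreasing = TRUE)[10])
    expect_true(all(dc$n1 >= sort(full$degree, decreasing = TRUE)[10]))
})

test_that("centrality tables export with ABSENT markers", {
    n1 <- netFromPairs(c("A-B",  "B-C"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D"), label = "n2")
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCentralityTable(deltaCentrality(loadCollection(list(n1, n2)),
                                         "degree"), f)
    txt <- readLines(f)
    expect_match(txt[1], "node\tn1\tn2")
    expect_true(any(grepl("ABSENT", txt)))
})
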