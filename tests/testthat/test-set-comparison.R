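mkColl <- function(...) {
    nets <- list(...)
    loadCollection(nets)
}

test_that("regions follow exact set algebra", {
    n1 <- netFromPairs(c("A-B", "B-C"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D"), label = "n2")
    rm <- computeRegions(mkColl(n1, n2), elementKind = "edge")
    expect_equal(regionMembers(rm, c("n1", "n2")), "B--C")
    expect_equal(regionMembers(rm, "n1"), "A--B")
    expect_equal(regionMembers(rm, "n2"), "C--D")

    # identical networks: everything in the full-overlap region
    twin <- mkColl(netFromPairs(c("A-B", "B-C"), label = "x"),
                   netFromPairs(c("A-B", "B-C"), label = "y"))
    rmT <- computeRegions(twin, elementKind = "edge")
    expect_setequal(regionMembers(rmT, c("x", "y")), c("A--B", "B--C"))
    expect_length(regionMembers(rmT, "x"), 0L)
    expect_length(regionMembers(rmT, "y"), 0L)

    # disjoint node sets: empty shared region
    dis <- mkColl(netFromPairs("A-B", label = "p"),
                  netFromPairs("C-D", label = "q"))
    expect_length(regionMembers(computeRegions(dis, elementKind = "node"),
                                c("p", "q")), 0L)
})

test_that("regions are disjoint, cover the union and reconstruct each network", {
    set.seed(77)
    for (rep in 1:20) {
        k <- sample(3:5, 1)
        nodes <- sprintf("v%02d", 1:30)
        nets <- lapply(seq_len(k), function(i)
            Network(randomEdgeDf(nodes, sample(20:50, 1)),
                    label = paste0("n", i)))
        coll <- loadCollection(nets)
        for (kind in c("node", "edge")) {
            rm <- computeRegions(coll, elementKind = kind)
            members <- unlist(rm@members)
            expect_false(anyDuplicated(members) > 0)
            sets <- lapply(nets, function(nw)
                if (kind == "node") networkNodes(nw) else edgeKeys(nw))
            expect_setequal(members, unique(unlist(sets)))
            # each network = union of regions whose subset contains it
            for (i in seq_len(k)) {
                lab <- paste0("n", i)
                fromRegions <- unlist(rm@members[vapply(rm@subsets,
                    function(s) lab %in% s, logical(1))])
                expect_setequal(fromRegions, sets[[i]])
            }
        }
    }
})

test_that("upset rows sort by either cardinality with lexicographic ties", {
    n1 <- netFromPairs(c("A-B", "B-C", "C-D"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D", "D-E"), label = "n2")
    rm <- computeRegions(mkColl(n1, n2), elementKind = "edge")

    bySet <- upsetRows(rm, "set_cardinality")
    expect_true(!is.unsorted(rev(bySet$count)))
    byCombo <- upsetRows(rm, "combination_cardinality")
    expect_true(!is.unsorted(rev(byCombo$degree)))

    # equal counts resolved lexicographically by subset string
    ties <- bySet[bySet$count == 1, ]
    expect_equal(ties$subset, sort(ties$subset, method = "radix"))
})

test_that("inclusive counts derive from exclusive regions", {
    n1 <- netFromPairs(c("A-B", "B-C"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D"), label = "n2")
    rm <- computeRegions(mkColl(n1, n2), elementKind = "edge")
    inc <- inclusiveCounts(rm)
    expect_equal(inc$count[inc$subset == "n1"], 2L)   # all of n1's edges
    expect_equal(inc$count[inc$subset == "n1&n2"], 1L)
})

test_that("intersection graph keeps only shared edges and their endpoints", {
    n1 <- netFromPairs(c("A-B", "B-C"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D"), label = "n2")
    ig <- intersectionGraph(mkColl(n1, n2))
    expect_equal(edgeKeys(ig), "B--C")
    expect_equal(networkNodes(ig), c("B", "C"))

    twin <- mkColl(netFromPairs(c("A-B", "B-C"), label = "x"),
                   netFromPairs(c("A-B", "B-C"), label = "y"))
    expect_setequal(edgeKeys(intersectionGraph(twin)), c("A--B", "B--C"))

    dis <- mkColl(netFromPairs("A-B", label = "p"),
                  netFromPairs("C-D", label = "q"))
    expect_equal(numEdges(intersectionGraph(dis)), 0L)
})

test_that("exclusive graphs partition each network's edge set", {
    n1 <- netFromPairs(c("A-B", "B-C"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D"), label = "n2")
    coll <- mkColl(n1, n2)
    ex <- exclusiveGraphs(coll)
    expect_equal(edgeKeys(ex$n1), "A--B")
    expect_equal(edgeKeys(ex$n2), "C--D")

    # exclusive + shared = the network's full edge set
    shared <- edgeKeys(intersectionGraph(coll))
    expect_setequal(c(edgeKeys(ex$n1), shared), edgeKeys(n1))

    twin <- mkColl(netFromPairs(c("A-B", "B-C"), label = "x"),
                   netFromPairs(c("A-B", "B-C"), label = "y"))
    exT <- exclusiveGraphs(twin)
    expect_equal(numEdges(exT$x), 0L)
    expect_equal(numEdges(exT$y), 0L)
})

test_that("union graph membership reflects exact containment", {
    nets <- lapply(1:5, function(i)
        netFromPairs(c("A-hub", paste0("A-x", i)), label = paste0("net", i)))
    ug <- unionGraph(loadCollection(nets))
    expect_length(ug@nodeMembership[["A"]], 5L)       # in all five networks
    expect_length(ug@nodeMembership[["x3"]], 1L)
    expect_length(ug@edgeMembership[["A--hub"]], 5L)
    expect_length(ug@edgeMembership[["A--x2"]], 1L)

    # single shared node, no shared edge
    p <- netFromPairs("A-B", label = "p")
    q <- netFromPairs("B-C", label = "q")
    ug2 <- unionGraph(mkColl(p, q))
    expect_setequal(ug2@nodeMembership[["B"]], c("p", "q"))
    expect_equal(ug2@edgeMembership[["A--B"]], "p")

    # node membership contains the membership of every incident edge
    for (ek in names(ug2@edgeMembership)) {
        ends <- strsplit(ek, "--", fixed = TRUE)[[1]]
        for (nd in ends)
            expect_true(all(ug2@edgeMembership[[ek]] %in%
                            ug2@nodeMembership[[nd]]))
    }
})

test_that("union and intersection satisfy subset relations", {
    set.seed(13)
    nodes <- sprintf("v%02d", 1:20)
    nets <- lapply(1:3, function(i)
        Network(randomEdgeDf(nodes, 25), label = paste0("n", i)))
    coll <- loadCollection(nets)
    interKeys <- edgeKeys(intersectionGraph(coll))
    unionKeys <- names(unionGraph(coll)@edgeMembership)
    for (nw in nets) {
        expect_true(all(interKeys %in% edgeKeys(nw)))
        expect_true(all(edgeKeys(nw) %in% unionKeys))
    }
})

test_that("region exports carry counts and members", {
    n1 <- netFromPairs(c("A-B", "B-C"), label = "n1")
    n2 <- netFromPairs(c("B-C", "C-D"), label = "n2")
    rm <- computeRegions(mkColl(n1, n2), elementKind = "edge")
    js <- jsonlite::fromJSON(regionsToJSON(rm), simplifyVector = FALSE)
    expect_equal(js$elementKind, "edge")
    counts <- vapply(js$regions, `[[`, numeric(1), "count")
    expect_equal(sum(counts), 3)

    f <- withr::local_tempfile(fileext = ".tsv")
    writeRegionTable(rm, f)
    tab <- read.delim(f)
    expect_equal(sum(tab$count), 3L)

    expect_error(regionMembers(rm, c("n1", "nope")), "no region")
})
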