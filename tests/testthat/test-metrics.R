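test_that("hand-computed fixtures give the known metric values", {
    expect_equal(globalEfficiency(as_network(K4)), 1)
    expect_equal(globalEfficiency(as_network(P3)), 5 / 6)
    expect_equal(clusteringCoefficient(as_network(K4)), 1)
    expect_equal(clusteringCoefficient(as_network(P3)), 0)
    expect_equal(clusteringCoefficient(as_network(triPend)), 7 / 12)
    expect_equal(transitivity(as_network(K4)), 1)
    expect_equal(transitivity(as_network(star4)), 0)
    expect_equal(transitivity(as_network(triPend)), 0.6)
    expect_equal(nodeBetweenness(as_network(star4)), c(3, 0, 0, 0))
    expect_equal(nodeBetweenness(as_network(P3)), c(0, 1, 0))
})

test_that("shortest paths handle disconnection and match Floyd-Warshall", {
    d <- shortestPathLengths(as_network(P3))
    expect_equal(d[1, 3], 2)
    two <- matrix(0L, 4, 4); two[1, 2] <- two[2, 1] <- 1L
    expect_equal(shortestPathLengths(as_network(two))[1, 3], Inf)

    set.seed(10)
    for (i in 1:10) {
        A <- random_graph(10, runif(1, 0.1, 0.6))
        expect_equal(shortestPathLengths(as_network(A)),
                     oracle_floyd_warshall(A))
    }
})

test_that("all metrics agree exactly with brute-force oracles", {
    set.seed(11)
    atlas <- generateAtlas(12, seed = 3)
    D <- distances(atlas)
    for (i in 1:40) {
        n <- sample(4:12, 1)
        A <- random_graph(n, runif(1, 0.05, 0.9))
        net <- as_network(A)
        expect_equal(globalEfficiency(net), oracle_global_efficiency(A))
        expect_equal(clusteringCoefficient(net), oracle_clustering(A))
        expect_equal(transitivity(net), oracle_transitivity(A))
        expect_equal(edgeCount(net), oracle_edge_count(A))
        expect_equal(nodeBetweenness(net), oracle_betweenness(A),
                     tolerance = 1e-10)
        if (n == 12)
            expect_equal(longDistanceEdgeCount(net, atlas),
                         oracle_long_edges(A, D))
    }
})

test_that("betweenness agrees with an independent library implementation", {
    skip_if_not_installed("igraph")
    set.seed(12)
    for (i in 1:5) {
        A <- random_graph(15, 0.3)
        g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
        expect_equal(nodeBetweenness(as_network(A)),
                     igraph::betweenness(g), tolerance = 1e-10,
                     ignore_attr = TRUE)
    }
})

test_that("metrics are invariant under node relabeling", {
    set.seed(13)
    for (i in 1:10) {
        A <- random_graph(10, 0.4)
        p <- sample(10)
        B <- A[p, p]
        expect_equal(globalEfficiency(as_network(A)),
                     globalEfficiency(as_network(B)))
        expect_equal(clusteringCoefficient(as_network(A)),
                     clusteringCoefficient(as_network(B)))
        expect_equal(transitivity(as_network(A)),
                     transitivity(as_network(B)))
        expect_equal(sort(nodeBetweenness(as_network(A))),
                     sort(nodeBetweenness(as_network(B))),
                     tolerance = 1e-10)
    }
})

test_that("long-distance counting uses a strict cutoff", {
    atlas <- line_atlas(c(0, 50, 100))
    A <- matrix(0L, 3, 3)
    A[1, 2] <- A[2, 1] <- 1L
    A[1, 3] <- A[3, 1] <- 1L
    net <- as_network(A)
    expect_equal(longDistanceEdgeCount(net, atlas), 1L)
    # an edge exactly at the cutoff does not count
    atlas75 <- line_atlas(c(0, 75))
    B <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
    expect_equal(longDistanceEdgeCount(as_network(B), atlas75), 0L)
    expect_error(longDistanceEdgeCount(net, atlas75), "mismatch")
})

test_that("profiles and group means aggregate per-subject metrics", {
    atlas <- generateAtlas(6, seed = 5)
    netA <- as_network(random_graph(6, 0.5), threshold = 0.5, id = "a")
    netB <- as_network(random_graph(6, 0.9), threshold = 0.5, id = "b")
    pr <- rbind(topologyProfile(netA, atlas), topologyProfile(netB, atlas))
    expect_equal(pr$edge_count,
                 c(edgeCount(netA), edgeCount(netB)))
    gm <- groupMeanProfiles(pr)
    expect_equal(gm$edge_count, mean(pr$edge_count))
    expect_equal(gm$n_subjects, 2L)
    one <- groupMeanProfiles(pr[1, ])
    expect_equal(one$global_efficiency, pr$global_efficiency[1])
    expect_error(groupMeanProfiles(pr, group = "ad"), "no profiles")
})
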