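# Geometry with exact ratios: three collinear regions; betweenness
# supplied explicitly so only the pairs (1,2) and (1,3) carry weight,
# with equal K-sums at distances 10 and 20 mm.
twoPairAtlas <- line_atlas(c(0, 10, -20))
twoPairK <- c(1, 0, 0)

test_that("connection and disconnection weights follow the distance law", {
    A <- matrix(0L, 3, 3)
    A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- 1L
    net <- as_network(A)
    cp <- connectionWeights(net, twoPairAtlas, betweenness = twoPairK)
    expect_equal(cp[1, 2], 1)
    expect_equal(cp[1, 3], 0.25)          # (1/400) / (1/100)
    expect_equal(cp[2, 3], 0)
    dp <- disconnectionWeights(net, twoPairAtlas, betweenness = twoPairK)
    expect_equal(dp[1, 2], 0.25)          # 100 / 400
    expect_equal(dp[1, 3], 1)
    expect_equal(cp, t(cp))
    expect_equal(dp, t(dp))
    expect_true(all(cp >= 0 & cp <= 1) && all(dp >= 0 & dp <= 1))
})

test_that("zero betweenness gives all-zero weights", {
    net <- as_network(matrix(0L, 3, 3))
    expect_true(all(connectionWeights(net, twoPairAtlas,
                                      betweenness = rep(0, 3)) == 0))
    expect_true(all(disconnectionWeights(net, twoPairAtlas,
                                         betweenness = rep(0, 3)) == 0))
})

test_that("a single nonzero raw weight normalises to exactly 1", {
    A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- 1L
    dp <- disconnectionWeights(as_network(A), twoPairAtlas,
                               betweenness = twoPairK)
    expect_equal(dp[1, 2], 1)
})

test_that("coincident regions are rejected at construction", {
    expect_error(regionAtlas(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
                 "positive")
})

# A 30 x 40 mm rectangle wired as a 4-cycle (all coordinates Pythagorean,
# so every distance is exact): node betweenness is 1/2 everywhere, each
# edge has disconnection weight >= 0.5, and the diagonals have connection
# weight 900/2500 = 0.36, so single pair decisions can be forced through
# the random matrix with an explicit connection cut-off.
rect <- regionAtlas(rbind(c(0, 0, 0), c(30, 0, 0),
                          c(30, 40, 0), c(0, 40, 0)))
C4 <- matrix(0L, 4, 4)
C4[1, 2] <- C4[2, 3] <- C4[3, 4] <- C4[4, 1] <- 1L
C4 <- C4 + t(C4)

test_that("the step applies the CP/DP rules with the R gate", {
    net <- as_network(C4)
    cp <- connectionWeights(net, rect)
    expect_equal(cp[1, 3], 900 / 2500)
    dp <- disconnectionWeights(net, rect)
    expect_equal(dp[2, 3], 1)             # the longest edge
    expect_gte(min(dp[C4 == 1L]), 0.5)
    ones <- matrix(1, 4, 4)

    # R forced to 1 everywhere: r <= 0.03 never holds, nothing changes
    expect_identical(adjacency(evolutionStep(net, rect, rMatrix = ones)),
                     C4)

    # eligible non-edge (1,3) with r below the gate gains an edge
    pAdd <- evolutionParams(cp_threshold = 0.3)
    Radd <- ones; Radd[1, 3] <- Radd[3, 1] <- 0.01
    out <- adjacency(evolutionStep(net, rect, pAdd, rMatrix = Radd))
    expect_equal(out[1, 3], 1L)
    out[1, 3] <- out[3, 1] <- 0L
    expect_identical(out, C4)

    # eligible edge (1,2) with r below the gate is disconnected
    Rrem <- ones; Rrem[1, 2] <- Rrem[2, 1] <- 0.02
    out <- adjacency(evolutionStep(net, rect, rMatrix = Rrem))
    expect_equal(out[1, 2], 0L)
    out[1, 2] <- out[2, 1] <- 1L
    expect_identical(out, C4)
})

test_that("suppressed randomness makes evolution the identity", {
    atlas <- generateAtlas(30, seed = 2)
    net <- plantGroupAdjacency(atlas, 60, seed = 4)
    tr <- evolveNetwork(net, atlas,
                        evolutionParams(random_threshold = 0,
                                        n_steps = 17, seed = 5))
    expect_identical(adjacency(tr@final), adjacency(net))
    expect_true(all(tr@profiles$edge_count == edgeCount(net)))
})

test_that("an empty network never grows", {
    atlas <- generateAtlas(20, seed = 2)
    net <- as_network(matrix(0L, 20, 20))
    tr <- evolveNetwork(net, atlas, evolutionParams(n_steps = 30, seed = 6))
    expect_equal(edgeCount(tr@final), 0L)
})

test_that("traces are reproducible and structured per step", {
    atlas <- generateAtlas(30, seed = 2)
    net <- plantGroupAdjacency(atlas, 70, seed = 4)
    p <- evolutionParams(n_steps = 12, seed = 9)
    t1 <- evolveNetwork(net, atlas, p)
    t2 <- evolveNetwork(net, atlas, p)
    expect_identical(adjacency(t1@final), adjacency(t2@final))
    expect_identical(t1@profiles, t2@profiles)
    expect_equal(nrow(t1@profiles), 12L)
    expect_equal(t1@profiles$step, 1:12)
    expect_equal(subjectGroup(t1@final), "evolved")

    t0 <- evolveNetwork(net, atlas, evolutionParams(n_steps = 0, seed = 9))
    expect_identical(adjacency(t0@final), adjacency(net))
    expect_equal(nrow(t0@profiles), 0L)
})

test_that("evolveGroup derives reproducible per-network substreams", {
    atlas <- generateAtlas(30, seed = 2)
    nets <- lapply(1:3, function(i)
        plantGroupAdjacency(atlas, 60, seed = i, group = "healthy"))
    p <- evolutionParams(n_steps = 8, seed = 11)
    g1 <- evolveGroup(nets, atlas, p)
    g2 <- evolveGroup(nets, atlas, p)
    expect_length(g1, 3L)
    for (i in 1:3)
        expect_identical(adjacency(g1[[i]]@final), adjacency(g2[[i]]@final))
    # substreams differ between networks
    expect_false(identical(g1[[1]]@params$seed, g1[[2]]@params$seed))
    expect_length(evolveGroup(list(), atlas, p), 0L)
})

test_that("eligible pairs flip at close to the nominal rate", {
    atlas <- generateAtlas(30, seed = 3)
    net <- plantGroupAdjacency(atlas, 80, seed = 5)
    cp <- connectionWeights(net, atlas)
    dp <- disconnectionWeights(net, atlas)
    A <- adjacency(net)
    elig <- (A == 0L & cp >= 0.5) | (A == 1L & dp >= 0.5)
    diag(elig) <- FALSE
    nElig <- sum(elig) / 2
    expect_gt(nElig, 0)
    p <- evolutionParams()
    set.seed(77)
    flips <- 0
    reps <- 400
    for (i in seq_len(reps)) {
        B <- adjacency(evolutionStep(net, atlas, p))
        flips <- flips + sum(B != A) / 2
    }
    phat <- flips / (reps * nElig)
    se <- sqrt(0.03 * 0.97 / (reps * nElig))
    expect_lt(abs(phat - 0.03), 4 * se)
})
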