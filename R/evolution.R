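#' Parameters of the stochastic network evolution
#'
#' @param cp_threshold minimum connection weight for a new edge (default 0.5).
#' @param dp_threshold minimum disconnection weight for edge removal
#'   (default 0.5).
#' @param random_threshold acceptance cut-off on the uniform random matrix:
#'   an eligible pair flips only when its draw is at or below this value
#'   (default 0.03), so eligible pairs flip with exactly this probability
#'   per step.
#' @param n_steps number of evolution steps (default 100).
#' @param seed integer RNG seed.
#' @return a validated named list of class `"evolutionParams"`.
#' @examples
#' evolutionParams(n_steps = 10, seed = 2)$random_threshold
#' @export
evolutionParams <- function(cp_threshold = 0.5, dp_threshold = 0.5,
                            random_threshold = 0.03, n_steps = 100L,
                            seed = 1L) {
    p <- list(cp_threshold = cp_threshold, dp_threshold = dp_threshold,
              random_threshold = random_threshold,
              n_steps = as.integer(n_steps), seed = as.integer(seed))
    if (p$cp_threshold <= 0 || p$cp_threshold > 1 ||
        p$dp_threshold <= 0 || p$dp_threshold > 1)
        stop("cp_threshold and dp_threshold must lie in (0, 1]")
    if (p$random_threshold < 0 || p$random_threshold > 1)
        stop("random_threshold must lie in [0, 1]")
    if (p$n_steps < 0L) stop("n_steps must be non-negative")
    class(p) <- c("evolutionParams", "list")
    p
}

# Raw pair weight (K_i + K_j) combined with squared distance, then
# max-normalised to [0, 1] so the 0.5 decision thresholds are meaningful.
# The two weight families are referenced differently: a connection weight
# is normalised by the maximum affinity over all pairs (existing links
# included -- a new link must rival the strongest affinity realised in
# the network), while a disconnection weight is normalised by the maximum
# strain over the pairs removal can act on, i.e. the current edges
# (`mask`). Values outside the reference set are capped at 1.
.pairWeights <- function(K, D2, inverse, mask = NULL) {
    S <- outer(K, K, "+")
    w <- if (inverse) S / D2 else S * D2
    diag(w) <- 0
    mx <- if (is.null(mask) || !any(mask)) max(w) else max(w[mask])
    if (mx > 0) w <- pmin(w / mx, 1)
    w
}

.checkAtlasDistances <- function(D) {
    if (any(D[upper.tri(D)] == 0))
        stop("atlas has coincident regions (zero inter-node distance)")
}

#' Connection and disconnection weight matrices
#'
#' The evolution's control weights for every node pair. The raw connection
#' weight is (K_i + K_j) / D(i, j)^2 (propensity to wire: high joint
#' betweenness, short distance); the raw disconnection weight is
#' (K_i + K_j) * D(i, j)^2 (propensity to unwire: high joint betweenness,
#' long distance). The connection weights are normalised to \[0, 1\] by
#' the maximum raw affinity over all pairs; the disconnection weights by
#' the maximum raw strain over the connected pairs (values outside the
#' reference set are capped at 1). If all betweenness is zero the matrix
#' is all zero.
#'
#' @param net a [BinaryNetwork-class] (or 0/1 adjacency matrix).
#' @param betweenness betweenness vector computed on the same adjacency
#'   (default: computed internally via [nodeBetweenness()]).
#' @param atlas a [RegionAtlas-class]; its distances must be positive off
#'   the diagonal.
#' @return symmetric N x N matrix in \[0, 1\] with zero diagonal.
#' @export
connectionWeights <- function(net, atlas, betweenness = nodeBetweenness(net)) {
    A <- .asAdj(net)
    D <- distances(atlas)
    if (nrow(A) != nrow(D)) stop("network and atlas dimension mismatch")
    .checkAtlasDistances(D)
    .pairWeights(betweenness, D^2, inverse = TRUE)
}

#' @rdname connectionWeights
#' @export
disconnectionWeights <- function(net, atlas,
                                 betweenness = nodeBetweenness(net)) {
    A <- .asAdj(net)
    D <- distances(atlas)
    if (nrow(A) != nrow(D)) stop("network and atlas dimension mismatch")
    .checkAtlasDistances(D)
    .pairWeights(betweenness, D^2, inverse = FALSE, mask = A == 1L)
}

# Draw a symmetric uniform(0,1) matrix: one draw per unordered pair.
.symmetricUniform <- function(n) {
    R <- matrix(0, n, n)
    R[upper.tri(R)] <- runif(n * (n - 1) / 2)
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    R
}

# One synchronous step on a plain adjacency; uses the calling RNG stream.
.evolutionStep <- function(A, D2, params, rMatrix = NULL) {
    K <- .brandes_betweenness_cpp(A)
    cp <- .pairWeights(K, D2, inverse = TRUE)
    dp <- .pairWeights(K, D2, inverse = FALSE, mask = A == 1L)
    R <- if (is.null(rMatrix)) .symmetricUniform(nrow(A)) else rMatrix
    add <- (A == 0L) & cp >= params$cp_threshold & R <= params$random_threshold
    rem <- (A == 1L) & dp >= params$dp_threshold & R <= params$random_threshold
    diag(add) <- FALSE
    A[add] <- 1L
    A[rem] <- 0L
    A
}

#' One synchronous evolution step
#'
#' Recomputes betweenness and the connection/disconnection weights from the
#' current network, draws a fresh symmetric uniform random matrix R, and
#' applies the rules to every unordered pair using the step-entry state:
#' a non-edge is wired when CP >= `cp_threshold` and R <= `random_threshold`;
#' an edge is unwired when DP >= `dp_threshold` and R <= `random_threshold`;
#' otherwise the pair keeps its state.
#'
#' @param net a [BinaryNetwork-class].
#' @param atlas a [RegionAtlas-class].
#' @param params an [evolutionParams()] list.
#' @param rMatrix optional fixed symmetric random matrix (for tests); by
#'   default a fresh draw from the current RNG stream.
#' @return the updated [BinaryNetwork-class].
#' @export
evolutionStep <- function(net, atlas, params = evolutionParams(),
                          rMatrix = NULL) {
    stopifnot(is(net, "BinaryNetwork"), is(atlas, "RegionAtlas"))
    D <- distances(atlas)
    .checkAtlasDistances(D)
    A <- .evolutionStep(net@adjacency, D^2, params, rMatrix)
    new("BinaryNetwork", adjacency = A, threshold = net@threshold,
        subjectId = net@subjectId, group = net@group)
}

#' Evolve one network for a fixed number of steps
#'
#' Runs the stochastic rewiring from a seeded RNG for `params$n_steps`
#' steps, recording the full topology profile after every step. The final
#' network keeps its threshold and subject id but is labelled group
#' "evolved". Identical (network, params) give bit-identical traces.
#'
#' @param net the starting [BinaryNetwork-class].
#' @param atlas a [RegionAtlas-class].
#' @param params an [evolutionParams()] list; `params$seed` seeds the run.
#' @return an [EvolutionTrace-class].
#' @examples
#' atlas <- generateAtlas(30, seed = 1)
#' net <- plantGroupAdjacency(atlas, density = 60, seed = 2)
#' tr <- evolveNetwork(net, atlas, evolutionParams(n_steps = 5, seed = 3))
#' tr
#' @export
evolveNetwork <- function(net, atlas, params = evolutionParams()) {
    stopifnot(is(net, "BinaryNetwork"), is(atlas, "RegionAtlas"))
    if (nRegions(net) != nRegions(atlas))
        stop("network and atlas dimension mismatch")
    D <- distances(atlas)
    .checkAtlasDistances(D)
    D2 <- D^2
    set.seed(params$seed)
    A <- net@adjacency
    rows <- vector("list", params$n_steps)
    for (s in seq_len(params$n_steps)) {
        A <- .evolutionStep(A, D2, params)
        rows[[s]] <- .profileRow(A, D, net@subjectId, "evolved",
                                 net@threshold)
        rows[[s]]$step <- s
    }
    profiles <- if (params$n_steps > 0L) do.call(rbind, rows) else
        data.frame(subject_id = character(), group = character(),
                   threshold = numeric(), global_efficiency = numeric(),
                   clustering_coefficient = numeric(),
                   edge_count = integer(), transitivity = numeric(),
                   long_distance_edge_count = integer(), step = integer())
    final <- new("BinaryNetwork", adjacency = A, threshold = net@threshold,
                 subjectId = net@subjectId, group = "evolved")
    new("EvolutionTrace", initial = net, final = final,
        profiles = profiles, params = unclass(params))
}

#' Evolve a set of networks with per-network derived seeds
#'
#' One trace per input network; each network's RNG substream is derived
#' deterministically from the master seed and its position in the list, so
#' the whole set is reproducible from `params$seed`.
#'
#' @param networks list of [BinaryNetwork-class].
#' @param atlas a [RegionAtlas-class].
#' @param params an [evolutionParams()] list (master seed).
#' @return list of [EvolutionTrace-class], same length and order as the
#'   input.
#' @export
evolveGroup <- function(networks, atlas, params = evolutionParams()) {
    stopifnot(is.list(networks))
    lapply(seq_along(networks), function(i) {
        p <- params
        p$seed <- deriveSeed(params$seed, i)
        evolveNetwork(networks[[i]], atlas, p)
    })
}
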