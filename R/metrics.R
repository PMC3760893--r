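# Internal matrix-level kernels: the evolution loop calls these directly on
# plain adjacency matrices to avoid S4 construction costs per step.

.asAdj <- function(net) {
    if (is(net, "BinaryNetwork")) net@adjacency else {
        A <- as.matrix(net)
        storage.mode(A) <- "integer"
        A
    }
}

.globalEfficiency <- function(A) {
    n <- nrow(A)
    d <- .bfs_distances_cpp(A)
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (n * (n - 1))
}

.clusteringCoefficient <- function(A) {
    k <- rowSums(A)
    A2 <- A %*% A
    tri2 <- diag(A2 %*% A)                 # 2 * triangles through each node
    denom <- k * (k - 1)
    local <- ifelse(denom > 0, tri2 / denom, 0)
    mean(local)
}

.transitivity <- function(A) {
    k <- rowSums(A)
    triples <- sum(k * (k - 1)) / 2
    if (triples == 0) return(0)
    triangles <- sum(diag(A %*% A %*% A)) / 6
    3 * triangles / triples
}

.edgeCount <- function(A) sum(A) / 2

.longDistanceEdgeCount <- function(A, D, cutoff) {
    sum(A[upper.tri(A)][D[upper.tri(D)] > cutoff])
}

#' All-pairs shortest path lengths of a binary network
#'
#' Breadth-first-search hop counts between every pair of nodes; `Inf` where
#' no path exists, 0 on the diagonal.
#'
#' @param net a [BinaryNetwork-class] (or a plain 0/1 adjacency matrix).
#' @return numeric N x N matrix of hop counts.
#' @export
shortestPathLengths <- function(net) .bfs_distances_cpp(.asAdj(net))

#' Global efficiency
#'
#' Mean of 1/d(i, j) over all ordered pairs i != j, with disconnected pairs
#' contributing 0. Equals 1 on a complete graph.
#'
#' @inheritParams shortestPathLengths
#' @return scalar in \[0, 1\].
#' @examples
#' K4 <- matrix(1, 4, 4) - diag(4)
#' globalEfficiency(K4)   # 1
#' @export
globalEfficiency <- function(net) {
    A <- .asAdj(net)
    if (nrow(A) < 2L) stop("global efficiency needs at least 2 nodes")
    .globalEfficiency(A)
}

#' Average clustering coefficient
#'
#' Mean over all nodes of the fraction of a node's neighbour pairs that are
#' themselves connected; nodes of degree below 2 contribute 0 (they stay in
#' the denominator so the average is comparable across thresholds).
#'
#' @inheritParams shortestPathLengths
#' @return scalar in \[0, 1\].
#' @export
clusteringCoefficient <- function(net) .clusteringCoefficient(.asAdj(net))

#' Graph transitivity
#'
#' The ratio of triangles to triplets: 3 x (number of triangles) divided by
#' the number of connected triples (sum over nodes of k(k-1)/2); 0 when the
#' graph has no triples.
#'
#' @inheritParams shortestPathLengths
#' @return scalar in \[0, 1\].
#' @export
transitivity <- function(net) {
    A <- .asAdj(net)
    if (nrow(A) < 3L) stop("transitivity needs at least 3 nodes")
    .transitivity(A)
}

#' Edge count and long-distance edge count
#'
#' `edgeCount` counts each unordered edge once. `longDistanceEdgeCount`
#' counts edges whose endpoint separation in the atlas is strictly greater
#' than `cutoffMm` (default 75 mm).
#'
#' @inheritParams shortestPathLengths
#' @param atlas a [RegionAtlas-class] matching the network's node count.
#' @param cutoffMm distance cut-off in millimetres (default 75).
#' @return non-negative integer.
#' @export
edgeCount <- function(net) as.integer(.edgeCount(.asAdj(net)))

#' @rdname edgeCount
#' @export
longDistanceEdgeCount <- function(net, atlas, cutoffMm = 75) {
    A <- .asAdj(net)
    stopifnot(is(atlas, "RegionAtlas"))
    if (nrow(A) != nRegions(atlas))
        stop("network and atlas dimension mismatch")
    as.integer(.longDistanceEdgeCount(A, distances(atlas), cutoffMm))
}

#' Node betweenness centrality
#'
#' Unnormalised betweenness with fractional shortest-path credit (Brandes
#' convention): for each node v, the sum over unordered pairs (s, t) with
#' s != t != v of the fraction of shortest s-t paths passing through v.
#' Isolated nodes, and all nodes of an empty network, score 0.
#'
#' @inheritParams shortestPathLengths
#' @return numeric vector of length N.
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' nodeBetweenness(star)   # center 3, leaves 0
#' @export
nodeBetweenness <- function(net) .brandes_betweenness_cpp(.asAdj(net))

.profileRow <- function(A, D, subjectId, group, threshold, cutoffMm = 75) {
    data.frame(subject_id = subjectId, group = group, threshold = threshold,
               global_efficiency = .globalEfficiency(A),
               clustering_coefficient = .clusteringCoefficient(A),
               edge_count = .edgeCount(A),
               transitivity = .transitivity(A),
               long_distance_edge_count = .longDistanceEdgeCount(A, D, cutoffMm),
               stringsAsFactors = FALSE)
}

#' Topology profile of one network
#'
#' The per-network feature vector used throughout the pipeline: global
#' efficiency, average clustering coefficient, edge count, transitivity and
#' the number of long-distance (>75 mm) edges, together with the network's
#' subject id, group and threshold.
#'
#' @param net a [BinaryNetwork-class].
#' @param atlas a [RegionAtlas-class].
#' @param cutoffMm long-distance cut-off in mm (default 75).
#' @return one-row data.frame.
#' @export
topologyProfile <- function(net, atlas, cutoffMm = 75) {
    stopifnot(is(net, "BinaryNetwork"), is(atlas, "RegionAtlas"))
    if (nRegions(net) != nRegions(atlas))
        stop("network and atlas dimension mismatch")
    .profileRow(net@adjacency, distances(atlas), net@subjectId, net@group,
                net@threshold, cutoffMm)
}

#' Group-mean topology profiles
#'
#' Arithmetic mean of every profile feature over the subjects of each
#' (group, threshold) cell. Per-subject profiles are always computed first
#' and averaged after, never the other way around.
#'
#' @param profiles data.frame of per-network profiles (rows as produced by
#'   [topologyProfile()]).
#' @param group,threshold optional filters; if given, the selected cell
#'   must be non-empty.
#' @return data.frame with one row per (group, threshold) cell and columns
#'   `group`, `threshold`, `n_subjects`, and the mean of each feature.
#' @export
groupMeanProfiles <- function(profiles, group = NULL, threshold = NULL) {
    stopifnot(is.data.frame(profiles), nrow(profiles) > 0L)
    if (!is.null(group)) profiles <- profiles[profiles$group %in% group, ]
    if (!is.null(threshold))
        profiles <- profiles[!is.na(profiles$threshold) &
                             abs(profiles$threshold - threshold) < 1e-9, ]
    if (nrow(profiles) == 0L)
        stop("no profiles in the requested (group, threshold) cell")
    feats <- c("global_efficiency", "clustering_coefficient", "edge_count",
               "transitivity", "long_distance_edge_count")
    key <- interaction(profiles$group, profiles$threshold, drop = TRUE)
    out <- do.call(rbind, lapply(split(profiles, key), function(d) {
        cbind(data.frame(group = d$group[1], threshold = d$threshold[1],
                         n_subjects = nrow(d)),
              as.data.frame(as.list(colMeans(d[, feats]))))
    }))
    rownames(out) <- NULL
    out[order(out$group, out$threshold), , drop = FALSE]
}
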