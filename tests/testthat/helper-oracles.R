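# Independent brute-force oracles. Deliberately naive implementations on a
# different algorithmic route than the package (Floyd-Warshall instead of
# BFS, pair-by-pair path counting instead of Brandes, exhaustive scans
# instead of matrix algebra).

oracle_floyd_warshall <- function(A) {
    n <- nrow(A)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    d[A == 1] <- 1
    diag(d) <- 0
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j])
                    d[i, j] <- d[i, k] + d[k, j]
    d
}

oracle_global_efficiency <- function(A) {
    n <- nrow(A)
    d <- oracle_floyd_warshall(A)
    tot <- 0
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    tot / (n * (n - 1))
}

oracle_clustering <- function(A) {
    n <- nrow(A)
    vals <- numeric(n)
    for (v in seq_len(n)) {
        nb <- which(A[v, ] == 1)
        k <- length(nb)
        if (k < 2) next
        links <- 0
        for (i in seq_len(k - 1))
            for (j in (i + 1):k)
                if (A[nb[i], nb[j]] == 1) links <- links + 1
        vals[v] <- links / (k * (k - 1) / 2)
    }
    mean(vals)
}

oracle_transitivity <- function(A) {
    n <- nrow(A)
    tri <- 0
    triples <- 0
    for (i in seq_len(n)) {
        k <- sum(A[i, ])
        triples <- triples + k * (k - 1) / 2
        if (n >= 3)
            for (j in seq_len(n)) for (l in seq_len(n))
                if (i < j && j < l && A[i, j] && A[j, l] && A[i, l])
                    tri <- tri + 1
    }
    if (triples == 0) return(0)
    3 * tri / triples
}

oracle_edge_count <- function(A) {
    cnt <- 0
    n <- nrow(A)
    for (i in seq_len(n - 1))
        for (j in (i + 1):n) if (A[i, j] == 1) cnt <- cnt + 1
    cnt
}

oracle_long_edges <- function(A, D, cutoff = 75) {
    cnt <- 0
    n <- nrow(A)
    for (i in seq_len(n - 1))
        for (j in (i + 1):n)
            if (A[i, j] == 1 && D[i, j] > cutoff) cnt <- cnt + 1
    cnt
}

# Betweenness via the path-counting identity sigma_st(v) =
# sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t); sigma by dynamic
# programming over distance layers -- independent of Brandes' dependency
# accumulation.
oracle_betweenness <- function(A) {
    n <- nrow(A)
    d <- oracle_floyd_warshall(A)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        sigma[s, s] <- 1
        for (dist in 1:max(1, max(d[s, is.finite(d[s, ])]))) {
            for (t in which(d[s, ] == dist))
                sigma[s, t] <- sum(sigma[s, which(A[t, ] == 1 &
                                                  d[s, ] == dist - 1)])
        }
    }
    bc <- numeric(n)
    for (v in seq_len(n))
        for (s in seq_len(n - 1))
            for (t in (s + 1):n) {
                if (s == v || t == v || !is.finite(d[s, t])) next
                if (d[s, v] + d[v, t] == d[s, t])
                    bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
            }
    bc
}

# 1-D maximum-margin classifier: exhaustive search over midpoints.
# Returns labels for new points; ties to "ad".
oracle_margin_classify <- function(train_values, train_labels, new_values) {
    o <- order(train_values)
    v <- train_values[o]
    l <- as.character(train_labels)[o]
    best <- NULL
    bestMargin <- -Inf
    for (i in seq_len(length(v) - 1)) {
        if (l[i] == l[i + 1]) next
        thr <- (v[i] + v[i + 1]) / 2
        left <- l[v < thr]
        right <- l[v > thr]
        if (length(unique(left)) > 1 || length(unique(right)) > 1) next
        margin <- min(abs(v - thr))
        if (margin > bestMargin) {
            bestMargin <- margin
            best <- list(thr = thr, leftLabel = unique(left),
                         rightLabel = unique(right))
        }
    }
    if (is.null(best)) stop("training set not linearly separable")
    ifelse(new_values < best$thr, best$leftLabel,
           ifelse(new_values > best$thr, best$rightLabel, "ad"))
}

random_graph <- function(n, p) {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(runif(length(up)) < p)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    A
}

as_network <- function(A, threshold = NA_real_, id = "t", group = "healthy") {
    storage.mode(A) <- "integer"
    new("BinaryNetwork", adjacency = A, threshold = threshold,
        subjectId = id, group = group)
}

line_atlas <- function(xs) {
    regionAtlas(cbind(xs, 0, 0))
}

# Small named fixtures shared across test files.
K4 <- matrix(1L, 4, 4) - diag(4L)
P3 <- local({A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 1] <- 1L
             A[2, 3] <- A[3, 2] <- 1L; A})
star4 <- local({A <- matrix(0L, 4, 4); A[1, 2:4] <- A[2:4, 1] <- 1L; A})
triPend <- local({
    A <- matrix(0L, 4, 4)
    A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
    A[1, 3] <- A[3, 1] <- A[1, 4] <- A[4, 1] <- 1L
    A})
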