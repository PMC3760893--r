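#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic study. The generator
#' emulates the organisation of resting-state functional connectivity:
#' tightly correlated functional modules that spread across the spatial
#' extent of the brain (so that many within-module connections are long),
#' weakly integrated pendant regions, and a global background correlation
#' mimicking residual shared signal, whose shared component is
#' variance-standardised per subject the way global-signal normalisation
#' stabilises real preprocessing. The AD-like group differs from the
#' healthy-like group by a lower edge budget, spatially contracted
#' modules (the long-range edge deficit), a larger share of pendant
#' nodes, and a slightly weaker background synchrony.
#'
#' Densities below 1 are read as fractions of the N(N-1)/2 node pairs;
#' values of 1 or more are read as absolute edge counts.
#'
#' @param n_healthy,n_ad group sizes (defaults 11 and 10).
#' @param n_regions number of atlas regions (default 90).
#' @param n_timepoints signal length per region (default 240, i.e. 8 min
#'   at a 2 s sampling interval).
#' @param healthy_density,ad_density target edge density (fraction) or
#'   edge count of the planted group networks; `ad_density` must be below
#'   `healthy_density`.
#' @param long_range_retention_ad in \[0, 1\]: multiplicative selection
#'   weight applied to >75 mm candidate pairs during the AD-like
#'   network's module-membership sampling (default 0.1); it contracts the
#'   AD-like modules in space, the planted analogue of the long-distance
#'   edge deficit.
#' @param edge_correlation target Pearson correlation on planted edges.
#' @param background_correlation correlation shared by all region pairs
#'   (default 0.42), emulating residual global signal. At the study's
#'   signal length, sampling noise promotes a modest, threshold-dependent
#'   number of background pairs past the 0.50-0.60 cut-offs, which
#'   connects the modules the way real functional networks are connected,
#'   while staying far too weak to survive thresholding at long signal
#'   lengths.
#' @param ad_background_scale multiplier in (0, 1\] applied to the
#'   background level for AD-like subjects (default 1, i.e. disabled),
#'   the globally reduced functional synchrony of the AD-like phenotype.
#' @param subject_jitter fraction of the group network's edges resampled
#'   per subject (realised by node swaps between modules).
#' @param healthy_module_size,ad_module_size planted module (clique)
#'   sizes.
#' @param healthy_pendant_fraction,ad_pendant_fraction fraction of the
#'   edge budget spent on pendant (single-link partial-membership) edges.
#' @param seed master RNG seed.
#' @return a validated named list of class `"syntheticCohortConfig"`.
#' @examples
#' cfg <- syntheticCohortConfig(seed = 7)
#' cfg$healthy_density
#' @export
syntheticCohortConfig <- function(n_healthy = 11L, n_ad = 10L,
                                  n_regions = 90L, n_timepoints = 240L,
                                  healthy_density = 380,
                                  ad_density = 330,
                                  long_range_retention_ad = 0.1,
                                  edge_correlation = 0.6,
                                  background_correlation = 0.42,
                                  ad_background_scale = 0.985,
                                  subject_jitter = 0.04,
                                  healthy_module_size = 14L,
                                  ad_module_size = 14L,
                                  healthy_pendant_fraction = 0.04,
                                  ad_pendant_fraction = 0.07,
                                  seed = 1L) {
    cfg <- list(n_healthy = as.integer(n_healthy), n_ad = as.integer(n_ad),
                n_regions = as.integer(n_regions),
                n_timepoints = as.integer(n_timepoints),
                healthy_density = healthy_density, ad_density = ad_density,
                long_range_retention_ad = long_range_retention_ad,
                edge_correlation = edge_correlation,
                background_correlation = background_correlation,
                ad_background_scale = ad_background_scale,
                subject_jitter = subject_jitter,
                healthy_module_size = as.integer(healthy_module_size),
                ad_module_size = as.integer(ad_module_size),
                healthy_pendant_fraction = healthy_pendant_fraction,
                ad_pendant_fraction = ad_pendant_fraction,
                seed = as.integer(seed))
    if (cfg$n_healthy < 1L || cfg$n_ad < 1L)
        stop("group sizes must be positive")
    if (cfg$n_regions < 2L) stop("n_regions must be at least 2")
    if (cfg$n_timepoints < 3L) stop("n_timepoints must be at least 3")
    for (f in c("healthy_density", "ad_density"))
        if (cfg[[f]] <= 0) stop(f, " must be positive")
    if (cfg$healthy_density < 1 && cfg$ad_density < 1 &&
        cfg$ad_density >= cfg$healthy_density)
        stop("ad_density must be below healthy_density")
    if (cfg$long_range_retention_ad < 0 || cfg$long_range_retention_ad > 1)
        stop("long_range_retention_ad must lie in [0, 1]")
    if (abs(cfg$edge_correlation) >= 1)
        stop("edge_correlation must lie in (-1, 1)")
    if (cfg$background_correlation < 0 ||
        cfg$background_correlation >= max(cfg$edge_correlation, 1e-9))
        stop("need 0 <= background_correlation < edge_correlation")
    if (cfg$ad_background_scale <= 0 || cfg$ad_background_scale > 1)
        stop("ad_background_scale must lie in (0, 1]")
    if (cfg$subject_jitter < 0 || cfg$subject_jitter >= 1)
        stop("subject_jitter must lie in [0, 1)")
    for (f in c("healthy_pendant_fraction", "ad_pendant_fraction"))
        if (cfg[[f]] < 0 || cfg[[f]] > 0.5)
            stop(f, " must lie in [0, 0.5]")
    class(cfg) <- c("syntheticCohortConfig", "list")
    cfg
}

# Resolve a density spec (fraction < 1, count >= 1) to an edge target.
edgeTarget <- function(density, n) {
    npairs <- n * (n - 1) / 2
    m <- if (density < 1) round(density * npairs) else round(density)
    if (m < 0 || m > npairs)
        stop("infeasible edge target: ", m, " of ", npairs, " pairs")
    as.integer(m)
}

# Plan clique sizes and a pendant count that together realise exactly m
# edges on at most n nodes: t1 modules of `moduleSize`, up to two tail
# cliques (a, c), and P single-link pendants. Preference: pendant count
# close to pendantTarget, no oversize tail cliques, and as many nodes
# covered by modules as possible (coverage drives the average clustering
# of the planted group). Everything stays cliques plus distinct-host
# pendants, whose adjacency spectrum is bounded below by about -1.62 --
# the property that keeps the planted covariance nearly positive definite.
planModules <- function(m, n, moduleSize, pendantTarget) {
    ch2 <- function(s) s * (s - 1) / 2
    best <- NULL
    bestScore <- Inf
    for (t1 in seq(floor(min(m / ch2(moduleSize), n / moduleSize)), 0)) {
        b <- m - t1 * ch2(moduleSize)
        u <- n - t1 * moduleSize
        if (b < 0 || u < 0) next
        for (a in c(0L, if (u >= 2) 2:u else integer())) {
            ba <- b - ch2(a)
            if (ba < 0) break
            ua <- u - a
            for (cc in c(0L, if (ua >= 2) 2:ua else integer())) {
                p <- ba - ch2(cc)
                if (p < 0) break
                if (p > ua - cc) next                       # pendant nodes
                if (p > t1 * moduleSize + a + cc && p > 0) next  # hosts
                score <- 10 * abs(p - pendantTarget) +
                    5 * max(0, a - moduleSize) +
                    5 * max(0, cc - moduleSize) -
                    2 * (t1 * moduleSize + a + cc)
                if (score < bestScore) {
                    bestScore <- score
                    best <- list(sizes = c(rep(moduleSize, t1),
                                           a[a >= 2], cc[cc >= 2]),
                                 pendants = p)
                }
            }
        }
    }
    if (is.null(best))
        stop("could not realise the requested edge target (", m,
             ") on ", n, " nodes with module size ", moduleSize)
    best
}

# Sample one additional module member: candidates are weighted down by
# `retention` once per already-chosen member farther than 75 mm away.
sampleMember <- function(cand, members, long, retention) {
    if (length(cand) == 1L) return(cand)
    w <- retention ^ colSums(long[members, cand, drop = FALSE])
    if (sum(w) == 0) {             # retention 0 and every candidate is long
        nl <- colSums(long[members, cand, drop = FALSE])
        w <- as.numeric(nl == min(nl))
    }
    cand[sample.int(length(cand), 1L, prob = w)]
}

#' Plant a group-level modular network with a long-range edge control
#'
#' Builds a symmetric, hollow 0/1 adjacency with exactly `m` edges, where
#' `m` comes from `density` (fraction of pairs, or absolute count). Edges
#' are organised as disjoint modules (cliques of about `moduleSize`
#' nodes) plus single-link pendant nodes attached to distinct hosts;
#' module membership is sampled with a distance penalty: every
#' candidate's selection weight is multiplied by `longRangeRetention` for
#' each already-chosen member more than 75 mm away. With retention 1
#' modules spread over the whole atlas (many long-range edges); with
#' retention near 0 they are spatially compact and long-range edges are
#' rare.
#'
#' The clique-plus-pendant layout keeps the planted covariance used by
#' [sampleCohort()] close to positive definite, so the target edge
#' correlation survives the positive-definiteness repair essentially
#' unchanged (see the package vignette).
#'
#' @param atlas a [RegionAtlas-class].
#' @param density edge fraction in (0, 1) or absolute edge count.
#' @param longRangeRetention in \[0, 1\].
#' @param seed integer RNG seed.
#' @param moduleSize target clique size (default 14).
#' @param pendantFraction fraction of edges assigned as pendant links
#'   (default 0.04).
#' @param group group label stored on the result ("healthy" or "ad").
#' @return a [BinaryNetwork-class] with `threshold = NA` and exactly `m`
#'   edges.
#' @examples
#' atlas <- generateAtlas(90, seed = 1)
#' net <- plantGroupAdjacency(atlas, density = 200, seed = 2)
#' sum(adjacency(net)) / 2
#' @export
plantGroupAdjacency <- function(atlas, density, longRangeRetention = 1,
                                seed = 1L, moduleSize = 14L,
                                pendantFraction = 0.04,
                                group = "healthy") {
    stopifnot(is(atlas, "RegionAtlas"))
    n <- nRegions(atlas)
    m <- edgeTarget(density, n)
    long <- distances(atlas) > 75
    set.seed(as.integer(seed))
    A <- matrix(0L, n, n)
    if (m == 0L)
        return(new("BinaryNetwork", adjacency = A, threshold = NA_real_,
                   subjectId = paste0("planted_", group), group = group))

    plan <- planModules(m, n, min(moduleSize, n),
                        round(pendantFraction * m))
    unused <- seq_len(n)
    hosts <- integer()
    for (s in plan$sizes) {
        members <- unused[sample.int(length(unused), 1L)]
        while (length(members) < s) {
            cand <- setdiff(unused, members)
            members <- c(members,
                         sampleMember(cand, members, long, longRangeRetention))
        }
        A[members, members] <- 1L
        unused <- setdiff(unused, members)
        hosts <- c(hosts, members)
    }
    diag(A) <- 0L

    # Pendants: each pendant node gets one link to its own host; hosts
    # are distinct module members, chosen with the same distance penalty.
    if (plan$pendants > 0L) {
        pnodes <- if (length(unused) == plan$pendants) unused else
            sample(unused, plan$pendants)
        for (pn in pnodes) {
            w <- longRangeRetention ^ long[pn, hosts]
            if (sum(w) == 0) w <- rep(1, length(hosts))
            h <- if (length(hosts) == 1L) hosts else
                hosts[sample.int(length(hosts), 1L, prob = w)]
            A[pn, h] <- A[h, pn] <- 1L
            hosts <- setdiff(hosts, h)
        }
    }
    if (sum(A) / 2L != m)
        stop("internal error: planted ", sum(A) / 2L,
             " edges instead of ", m)
    new("BinaryNetwork", adjacency = A, threshold = NA_real_,
        subjectId = paste0("planted_", group), group = group)
}

# Per-subject resampling by node swaps. Exchanging the roles of two nodes
# from different modules removes every edge specific to one and re-creates
# it at the other (and vice versa), so about 2*(s-1) edges are resampled
# per swap while the total edge count and the adjacency spectrum are
# preserved exactly (a swap is a permutation similarity).
jitterAdjacency <- function(A, jitter) {
    m <- sum(A) / 2
    if (jitter == 0 || m == 0) return(A)
    deg <- rowSums(A)
    sbar <- mean(deg[deg > 1]) + 1        # typical module size
    nswap <- round(jitter * m / (2 * max(1, sbar - 1)))
    n <- nrow(A)
    for (i in seq_len(nswap)) {
        uv <- sample.int(n, 2L)
        u <- uv[1]; v <- uv[2]
        if (A[u, v] == 1L) next           # same module: swap is a no-op
        tmp <- A[u, ]; A[u, ] <- A[v, ]; A[v, ] <- tmp
        tmp <- A[, u]; A[, u] <- A[, v]; A[, v] <- tmp
        A[u, v] <- A[v, u] <- 0L
        diag(A) <- 0L
    }
    A
}

# Build the subject covariance the generator samples from:
# edge_correlation on connected pairs, background_correlation elsewhere;
# repaired by diagonal loading (smallest eigenvalue >= 0.05) and
# renormalised to unit diagonal. With the clique-plus-pendant planted
# structure (adjacency lambda_min >= -1.62) and a substantial background,
# the planted increment rho - delta is small and the repair is a no-op.
plantedCovariance <- function(A, rho, delta = 0) {
    n <- nrow(A)
    C <- matrix(delta, n, n) + (rho - delta) * A
    diag(C) <- 1
    lmin <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 0.05) {
        load <- 0.05 - lmin
        C <- (C + load * diag(n)) / (1 + load)
    }
    C
}

# Draw one subject's signal from the planted covariance, with the shared
# background component variance-standardised: the signal is sampled as
# sqrt(delta) * f + sqrt(1 - delta) * residual, where the common factor f
# is rescaled to unit sample variance. This is the generator's analogue
# of global-signal normalisation in resting-state preprocessing: without
# it, the realised background level (and with it the number of
# threshold-crossing background pairs) would swing by hundreds of edges
# from subject to subject.
sampleSignal <- function(C, delta, T) {
    n <- nrow(C)
    if (delta > 0) {
        Cres <- (C - delta) / (1 - delta)
        diag(Cres) <- 1
        R <- chol(Cres)
        f <- rnorm(T)
        f <- f / stats::sd(f)
        Z <- matrix(rnorm(T * n), T, n)
        sqrt(delta) * matrix(f, T, n) + sqrt(1 - delta) * (Z %*% R)
    } else {
        Z <- matrix(rnorm(T * n), T, n)
        Z %*% chol(C)
    }
}

#' Sample a synthetic two-group cohort of region time series
#'
#' Plants one modular network per group (the AD-like group sparser,
#' spatially contracted and more pendant-heavy), derives a per-subject
#' adjacency by resampling a fraction of edges via node swaps, builds a
#' covariance with `edge_correlation` on the connected pairs and the
#' background level elsewhere (made positive definite by diagonal loading
#' to a smallest eigenvalue of at least 0.05, then renormalised to unit
#' diagonal), and draws `n_timepoints` zero-mean Gaussian samples per
#' subject with the shared background component variance-standardised.
#' Fully reproducible from the config seed.
#'
#' @param config a [syntheticCohortConfig()].
#' @param atlas a [RegionAtlas-class] with `config$n_regions` regions.
#' @return a [SyntheticCohort-class]: subjects, per-subject planted truth,
#'   and the two group-level planted networks.
#' @examples
#' cfg <- syntheticCohortConfig(n_healthy = 2, n_ad = 2,
#'                              n_timepoints = 60, seed = 3)
#' atlas <- generateAtlas(90, seed = 1)
#' cohort <- sampleCohort(cfg, atlas)
#' cohort
#' @export
sampleCohort <- function(config, atlas) {
    stopifnot(inherits(config, "syntheticCohortConfig"),
              is(atlas, "RegionAtlas"))
    if (nRegions(atlas) != config$n_regions)
        stop("atlas size does not match config n_regions")
    n <- config$n_regions

    gtHealthy <- plantGroupAdjacency(atlas, config$healthy_density,
        longRangeRetention = 1, seed = deriveSeed(config$seed, 1L),
        moduleSize = config$healthy_module_size,
        pendantFraction = config$healthy_pendant_fraction,
        group = "healthy")
    gtAd <- plantGroupAdjacency(atlas, config$ad_density,
        longRangeRetention = config$long_range_retention_ad,
        seed = deriveSeed(config$seed, 2L),
        moduleSize = config$ad_module_size,
        pendantFraction = config$ad_pendant_fraction,
        group = "ad")

    groups <- c(rep("healthy", config$n_healthy), rep("ad", config$n_ad))
    subjects <- vector("list", length(groups))
    truth <- vector("list", length(groups))
    for (i in seq_along(groups)) {
        grp <- groups[i]
        set.seed(deriveSeed(config$seed, 100L + i))
        base <- if (grp == "healthy") adjacency(gtHealthy) else adjacency(gtAd)
        Ai <- jitterAdjacency(base, config$subject_jitter)
        delta <- config$background_correlation *
            (if (grp == "ad") config$ad_background_scale else 1)
        C <- plantedCovariance(Ai, config$edge_correlation, delta)
        X <- tryCatch(sampleSignal(C, delta, config$n_timepoints),
                      error = function(e)
            stop("subject covariance not positive definite after loading: ",
                 conditionMessage(e)))
        id <- sprintf("%s_%02d", grp, if (grp == "healthy") i
                      else i - config$n_healthy)
        subjects[[i]] <- new("SubjectTimeSeries", signal = t(X),
                             subjectId = id, group = grp)
        truth[[i]] <- new("BinaryNetwork", adjacency = Ai,
                          threshold = NA_real_, subjectId = id, group = grp)
    }
    new("SyntheticCohort", subjects = subjects, truth = truth,
        groupTruth = list(healthy = gtHealthy, ad = gtAd),
        config = unclass(config))
}
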