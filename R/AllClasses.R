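#' RegionAtlas: node identities, coordinates and pairwise distances
#'
#' Holds the node set of the network: one row per brain region with a label,
#' a 3-D coordinate in millimetres, and the full matrix of pairwise Euclidean
#' distances used by the long-distance edge count and the evolution rules.
#'
#' @slot coords numeric matrix, N x 3, columns x/y/z in mm.
#' @slot labels character vector of length N.
#' @slot distance numeric N x N matrix of pairwise Euclidean distances (mm).
#'
#' @seealso [generateAtlas()], [readAtlas()]
#' @export
setClass("RegionAtlas",
    representation(coords = "matrix", labels = "character",
                   distance = "matrix"),
    validity = function(object) {
        n <- nrow(object@coords)
        msg <- character()
        if (ncol(object@coords) != 3L)
            msg <- c(msg, "coords must have 3 columns (x, y, z)")
        if (length(object@labels) != n)
            msg <- c(msg, "labels length must equal number of regions")
        if (!all(dim(object@distance) == c(n, n)))
            msg <- c(msg, "distance must be N x N")
        else {
            if (max(abs(object@distance - t(object@distance))) > 1e-8)
                msg <- c(msg, "distance must be symmetric")
            if (any(diag(object@distance) != 0))
                msg <- c(msg, "distance diagonal must be zero")
            if (n > 1 && any(object@distance[upper.tri(object@distance)] <= 0))
                msg <- c(msg, "off-diagonal distances must be positive")
        }
        if (length(msg)) msg else TRUE
    })

#' BinaryNetwork: symmetric hollow 0/1 adjacency with provenance
#'
#' A binary functional network: an undirected simple graph on the atlas
#' nodes, tagged with the correlation threshold that produced it (`NA` for
#' planted or evolved networks), a subject identifier and a group label.
#'
#' @slot adjacency integer N x N matrix with entries 0/1, zero diagonal.
#' @slot threshold numeric scalar; correlation cut-off or `NA_real_`.
#' @slot subjectId character scalar.
#' @slot group character scalar, e.g. "healthy", "ad" or "evolved".
#'
#' @seealso [binarize()], [plantGroupAdjacency()]
#' @export
setClass("BinaryNetwork",
    representation(adjacency = "matrix", threshold = "numeric",
                   subjectId = "character", group = "character"),
    validity = function(object) {
        A <- object@adjacency
        msg <- character()
        if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
        if (!all(A %in% c(0L, 1L))) msg <- c(msg, "adjacency entries must be 0/1")
        if (nrow(A) == ncol(A)) {
            if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
            if (!isTRUE(all(A == t(A)))) msg <- c(msg, "adjacency must be symmetric")
        }
        if (length(object@threshold) != 1L) msg <- c(msg, "threshold must be scalar")
        if (length(msg)) msg else TRUE
    })

#' SubjectTimeSeries: one subject's regions x timepoints signal
#'
#' @slot signal numeric matrix, regions in rows, timepoints in columns.
#' @slot subjectId character scalar.
#' @slot group character scalar ("healthy", "ad" or "evolved").
#'
#' @seealso [sampleCohort()], [pearsonMatrix()]
#' @export
setClass("SubjectTimeSeries",
    representation(signal = "matrix", subjectId = "character",
                   group = "character"),
    validity = function(object) {
        msg <- character()
        if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
        if (anyNA(object@signal)) msg <- c(msg, "signal must not contain NA")
        if (length(msg)) msg else TRUE
    })

#' CorrelationMatrix: full Pearson correlation matrix of one subject
#'
#' @slot values numeric N x N symmetric matrix, unit diagonal, entries in
#'   \[-1, 1\].
#' @slot subjectId character scalar.
#'
#' @seealso [pearsonMatrix()], [binarize()]
#' @export
setClass("CorrelationMatrix",
    representation(values = "matrix", subjectId = "character"),
    validity = function(object) {
        V <- object@values
        msg <- character()
        if (nrow(V) != ncol(V)) msg <- c(msg, "values must be square")
        else {
            if (max(abs(V - t(V))) > 1e-8) msg <- c(msg, "values must be symmetric")
            if (any(abs(diag(V) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
            if (any(V < -1 - 1e-12 | V > 1 + 1e-12))
                msg <- c(msg, "entries must lie in [-1, 1]")
        }
        if (length(msg)) msg else TRUE
    })

#' SyntheticCohort: generated subjects plus their planted truth
#'
#' @slot subjects list of [SubjectTimeSeries-class] objects.
#' @slot truth list of [BinaryNetwork-class] objects (per-subject planted
#'   adjacency, threshold `NA`).
#' @slot groupTruth list of the two group-level planted
#'   [BinaryNetwork-class] objects, named "healthy" and "ad".
#' @slot config list, the [syntheticCohortConfig()] used.
#'
#' @seealso [sampleCohort()]
#' @export
setClass("SyntheticCohort",
    representation(subjects = "list", truth = "list", groupTruth = "list",
                   config = "list"),
    validity = function(object) {
        msg <- character()
        if (length(object@subjects) != length(object@truth))
            msg <- c(msg, "subjects and truth must have equal length")
        if (!all(vapply(object@subjects, is, logical(1), "SubjectTimeSeries")))
            msg <- c(msg, "subjects must contain SubjectTimeSeries")
        if (!all(vapply(object@truth, is, logical(1), "BinaryNetwork")))
            msg <- c(msg, "truth must contain BinaryNetwork")
        if (length(msg)) msg else TRUE
    })

#' EvolutionTrace: record of one network's stochastic evolution
#'
#' @slot initial the starting [BinaryNetwork-class].
#' @slot final the network after the last step, group label "evolved".
#' @slot profiles data.frame with one row per step: `step`,
#'   `global_efficiency`, `clustering_coefficient`, `edge_count`,
#'   `transitivity`, `long_distance_edge_count`.
#' @slot params list, the [evolutionParams()] used (including seed).
#'
#' @seealso [evolveNetwork()], [evolveGroup()]
#' @export
setClass("EvolutionTrace",
    representation(initial = "BinaryNetwork", final = "BinaryNetwork",
                   profiles = "data.frame", params = "list"),
    validity = function(object) {
        n <- object@params$n_steps
        if (!is.null(n) && nrow(object@profiles) != n)
            "profiles must have one row per evolution step"
        else TRUE
    })

setMethod("show", "RegionAtlas", function(object) {
    cat("RegionAtlas with", nrow(object@coords), "regions\n")
    cat("  coordinate ranges (mm): ",
        paste(sprintf("%s [%.1f, %.1f]", c("x", "y", "z"),
                      apply(object@coords, 2, min),
                      apply(object@coords, 2, max)), collapse = ", "), "\n")
    d <- object@distance[upper.tri(object@distance)]
    if (length(d))
        cat(sprintf("  pairwise distance: median %.1f mm, %.1f%% of pairs > 75 mm\n",
                    stats::median(d), 100 * mean(d > 75)))
})

setMethod("show", "BinaryNetwork", function(object) {
    cat(sprintf("BinaryNetwork '%s' (group %s): %d nodes, %d edges, threshold %s\n",
                object@subjectId, object@group, nrow(object@adjacency),
                sum(object@adjacency) / 2L,
                ifelse(is.na(object@threshold), "none",
                       format(object@threshold))))
})

setMethod("show", "SubjectTimeSeries", function(object) {
    cat(sprintf("SubjectTimeSeries '%s' (group %s): %d regions x %d timepoints\n",
                object@subjectId, object@group, nrow(object@signal),
                ncol(object@signal)))
})

setMethod("show", "CorrelationMatrix", function(object) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("CorrelationMatrix '%s': %d x %d, off-diagonal range [%.3f, %.3f]\n",
                object@subjectId, nrow(object@values), ncol(object@values),
                min(off), max(off)))
})

setMethod("show", "SyntheticCohort", function(object) {
    grp <- vapply(object@subjects, function(s) s@group, character(1))
    cat("SyntheticCohort:", length(object@subjects), "subjects (",
        paste(sprintf("%d %s", as.vector(table(grp)), names(table(grp))),
              collapse = ", "), ")\n")
})

setMethod("show", "EvolutionTrace", function(object) {
    cat(sprintf("EvolutionTrace '%s': %d steps, edges %d -> %d\n",
                object@initial@subjectId, nrow(object@profiles),
                sum(object@initial@adjacency) / 2L,
                sum(object@final@adjacency) / 2L))
})
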