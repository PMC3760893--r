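#' Pearson correlation matrix of one subject's region time series
#'
#' Computes the sample Pearson correlation between every pair of region
#' time series and forces the diagonal to exactly 1. A region with zero
#' variance is rejected by name: its correlation is undefined.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @return a [CorrelationMatrix-class].
#' @examples
#' sig <- matrix(rnorm(5 * 50), 5, 50)
#' ts <- new("SubjectTimeSeries", signal = sig, subjectId = "s1",
#'           group = "healthy")
#' pearsonMatrix(ts)
#' @export
pearsonMatrix <- function(ts) {
    stopifnot(is(ts, "SubjectTimeSeries"))
    sig <- ts@signal
    if (ncol(sig) < 3L)
        stop("at least 3 timepoints are required")
    v <- apply(sig, 1L, stats::var)
    if (any(v == 0))
        stop("zero-variance region(s): ",
             paste(which(v == 0), collapse = ", "))
    V <- stats::cor(t(sig))
    V[V > 1] <- 1; V[V < -1] <- -1
    diag(V) <- 1
    dimnames(V) <- NULL
    new("CorrelationMatrix", values = V, subjectId = ts@subjectId)
}

#' Threshold a correlation matrix into a binary network
#'
#' An edge joins regions i and j (i != j) when r(i, j) is at or above the
#' threshold on the signed correlation; the diagonal is forced to zero.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param threshold correlation cut-off in \[0, 1\].
#' @param group group label carried onto the network (default "unknown").
#' @return a [BinaryNetwork-class].
#' @examples
#' V <- diag(3); V[1, 2] <- V[2, 1] <- 0.55
#' cm <- new("CorrelationMatrix", values = V, subjectId = "s1")
#' adjacency(binarize(cm, 0.50))
#' @export
binarize <- function(corr, threshold, group = "unknown") {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold > 1)
        stop("threshold must be a scalar in [0, 1]")
    A <- (corr@values >= threshold) * 1L
    storage.mode(A) <- "integer"
    diag(A) <- 0L
    new("BinaryNetwork", adjacency = A, threshold = threshold,
        subjectId = corr@subjectId, group = group)
}

#' The standard threshold grid
#'
#' Eleven correlation cut-offs from 0.50 to 0.60 in steps of 0.01, built by
#' integer index to avoid floating-point accumulation.
#'
#' @param start,stop,step grid definition (defaults 0.50, 0.60, 0.01).
#' @return numeric vector of thresholds, inclusive of both endpoints.
#' @examples
#' thresholdGrid()
#' @export
thresholdGrid <- function(start = 0.50, stop = 0.60, step = 0.01) {
    if (step <= 0 || stop < start) stop("invalid threshold grid")
    k <- round((stop - start) / step)
    round(start + (0:k) * step, 10)
}

#' Binarize one correlation matrix at every grid threshold
#'
#' @param corr a [CorrelationMatrix-class].
#' @param grid numeric vector of thresholds (default [thresholdGrid()]).
#' @param group group label carried onto the networks.
#' @return list of [BinaryNetwork-class], ordered by threshold; edge counts
#'   are non-increasing along the list.
#' @export
thresholdSweep <- function(corr, grid = thresholdGrid(), group = "unknown") {
    lapply(grid, function(tau) binarize(corr, tau, group = group))
}
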