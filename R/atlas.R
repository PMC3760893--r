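#' Build a RegionAtlas from explicit coordinates
#'
#' @param coordMatrix numeric N x 3 matrix of x/y/z coordinates in mm.
#' @param labels optional character labels (default "R001", "R002", ...).
#' @return a [RegionAtlas-class] object with the pairwise Euclidean
#'   distance matrix precomputed.
#' @export
regionAtlas <- function(coordMatrix, labels = NULL) {
    coordMatrix <- as.matrix(coordMatrix)
    storage.mode(coordMatrix) <- "double"
    n <- nrow(coordMatrix)
    if (is.null(labels))
        labels <- sprintf("R%03d", seq_len(n))
    D <- as.matrix(stats::dist(coordMatrix))
    dimnames(D) <- NULL
    dimnames(coordMatrix) <- list(NULL, c("x", "y", "z"))
    new("RegionAtlas", coords = coordMatrix, labels = as.character(labels),
        distance = D)
}

#' Generate a synthetic region atlas
#'
#' Samples region centroids uniformly within a 140 x 170 x 120 mm box (a
#' brain-like spatial extent) and computes all pairwise Euclidean distances.
#' The atlas stands in for a real 90-region parcellation's centroid table;
#' a real coordinate table can be supplied instead via [readAtlas()].
#'
#' @param nRegions number of regions (default 90); must be at least 2.
#' @param seed integer RNG seed; identical seeds give bit-identical atlases.
#' @return a [RegionAtlas-class] object.
#' @examples
#' atlas <- generateAtlas(90, seed = 1)
#' mean(distances(atlas)[upper.tri(distances(atlas))] > 75)
#' @export
generateAtlas <- function(nRegions = 90L, seed = 1L) {
    if (!is.numeric(nRegions) || nRegions < 2)
        stop("nRegions must be at least 2")
    nRegions <- as.integer(nRegions)
    set.seed(as.integer(seed))
    xyz <- cbind(runif(nRegions, -70, 70),
                 runif(nRegions, -85, 85),
                 runif(nRegions, -60, 60))
    regionAtlas(xyz)
}

#' Read / write a region coordinate table
#'
#' Tab-delimited format with header `node_id label x y z`, coordinates in mm.
#'
#' @param path file path.
#' @param atlas a [RegionAtlas-class] object (for `writeAtlas`).
#' @return `readAtlas` returns a [RegionAtlas-class]; `writeAtlas` returns
#'   `path` invisibly.
#' @export
readAtlas <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("node_id", "label", "x", "y", "z")
    if (!all(need %in% names(tab)))
        stop("atlas file must have columns: ", paste(need, collapse = " "))
    tab <- tab[order(tab$node_id), , drop = FALSE]
    for (cc in c("x", "y", "z"))
        if (!is.numeric(tab[[cc]]))
            stop("non-numeric coordinate column '", cc, "' in ", path)
    regionAtlas(as.matrix(tab[, c("x", "y", "z")]), labels = tab$label)
}

#' @rdname readAtlas
#' @export
writeAtlas <- function(atlas, path) {
    stopifnot(is(atlas, "RegionAtlas"))
    tab <- data.frame(node_id = seq_len(nRegions(atlas)) - 1L,
                      label = regionLabels(atlas),
                      x = coords(atlas)[, 1], y = coords(atlas)[, 2],
                      z = coords(atlas)[, 3])
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
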