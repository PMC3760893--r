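#' Accessors for BrainNetEvo objects
#'
#' Small accessor generics: `nRegions` gives the node count, `distances`
#' the pairwise Euclidean distance matrix (mm), `coords` the N x 3
#' coordinate matrix, `regionLabels` the node labels, `adjacency` the 0/1
#' matrix of a network, and `subjectGroup` the group label.
#'
#' @param x a [RegionAtlas-class], [BinaryNetwork-class],
#'   [SubjectTimeSeries-class] or [CorrelationMatrix-class] object.
#' @return the requested component.
#' @name accessors
#' @aliases nRegions distances coords regionLabels adjacency subjectGroup
#' @examples
#' atlas <- generateAtlas(10, seed = 1)
#' nRegions(atlas)
#' range(distances(atlas))
NULL

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))

#' @rdname accessors
#' @export
setMethod("nRegions", "RegionAtlas", function(x) nrow(x@coords))
#' @rdname accessors
#' @export
setMethod("nRegions", "BinaryNetwork", function(x) nrow(x@adjacency))
#' @rdname accessors
#' @export
setMethod("nRegions", "SubjectTimeSeries", function(x) nrow(x@signal))
#' @rdname accessors
#' @export
setMethod("distances", "RegionAtlas", function(x) x@distance)
#' @rdname accessors
#' @export
setMethod("coords", "RegionAtlas", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionAtlas", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)
#' @rdname accessors
#' @export
setMethod("subjectGroup", "BinaryNetwork", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("subjectGroup", "SubjectTimeSeries", function(x) x@group)
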