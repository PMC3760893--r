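featureNames <- function() {
    c("global_efficiency", "clustering_coefficient", "edge_count",
      "transitivity")
}

#' Build a one-feature training set from group profiles
#'
#' Extracts one topology feature for every healthy and AD subject at a
#' given threshold and z-scores it with the training mean and standard
#' deviation (stored so evolved values can be transformed identically).
#'
#' @param profiles data.frame of per-network profiles ([topologyProfile()]
#'   rows) containing both groups.
#' @param feature one of `"global_efficiency"`, `"clustering_coefficient"`,
#'   `"edge_count"`, `"transitivity"` (or
#'   `"long_distance_edge_count"`).
#' @param threshold the correlation threshold the cell belongs to.
#' @return a list of class `"featureTrainingSet"` with elements `values`
#'   (z-scored), `labels` (factor healthy/ad), `center`, `scale`,
#'   `feature`, `threshold`.
#' @export
buildTrainingSet <- function(profiles, feature, threshold) {
    stopifnot(is.data.frame(profiles), feature %in% names(profiles))
    d <- profiles[!is.na(profiles$threshold) &
                  abs(profiles$threshold - threshold) < 1e-9 &
                  profiles$group %in% c("healthy", "ad"), ]
    if (!all(c("healthy", "ad") %in% d$group))
        stop("both groups must be present at threshold ", threshold)
    v <- d[[feature]]
    if (any(!is.finite(v))) stop("non-finite feature values")
    ctr <- mean(v)
    scl <- stats::sd(v)
    if (scl == 0)
        stop("degenerate feature '", feature, "': zero training variance")
    structure(list(values = (v - ctr) / scl,
                   labels = factor(d$group, levels = c("healthy", "ad")),
                   center = ctr, scale = scl, feature = feature,
                   threshold = threshold),
              class = c("featureTrainingSet", "list"))
}

#' Train a linear SVM and classify evolved feature values
#'
#' Fits a linear-kernel support vector machine (regularisation constant 1)
#' on the z-scored healthy vs AD training values, transforms the evolved
#' values with the stored training scaler, and labels each one. A value
#' exactly on the decision boundary is assigned to the AD class. Accuracy
#' is the fraction of evolved networks assigned to AD.
#'
#' @param train a `"featureTrainingSet"` from [buildTrainingSet()].
#' @param evolvedValues numeric vector of the same feature measured on
#'   evolved networks (raw scale).
#' @return a list of class `"classifierReport"`: `feature`, `threshold`,
#'   `n_evolved`, `n_classified_ad`, `accuracy`, `labels`.
#' @export
trainAndClassify <- function(train, evolvedValues) {
    stopifnot(inherits(train, "featureTrainingSet"),
              is.numeric(evolvedValues))
    if (min(table(train$labels)) < 2L)
        stop("need at least 2 training samples per class")
    if (length(unique(train$values)) == 1L)
        stop("degenerate feature: all training values identical")
    x <- matrix(train$values, ncol = 1)
    fit <- e1071::svm(x, train$labels, kernel = "linear", cost = 1,
                      scale = FALSE)
    z <- (evolvedValues - train$center) / train$scale
    dv <- attr(stats::predict(fit, matrix(z, ncol = 1),
                              decision.values = TRUE), "decision.values")
    # decision value > 0 means the first class named in the column label
    pos <- strsplit(colnames(dv), "/")[[1]][1]
    neg <- setdiff(c("healthy", "ad"), pos)
    labels <- ifelse(dv > 0, pos, ifelse(dv < 0, neg, "ad"))
    nAd <- sum(labels == "ad")
    structure(list(feature = train$feature, threshold = train$threshold,
                   n_evolved = length(evolvedValues),
                   n_classified_ad = nAd,
                   accuracy = if (length(evolvedValues)) nAd /
                       length(evolvedValues) else NA_real_,
                   labels = as.character(labels)),
              class = c("classifierReport", "list"))
}

#' Per-threshold, per-feature accuracy table
#'
#' Assembles classifier reports into the standard table: one row per
#' threshold plus an `average` row, one column per feature, accuracies as
#' percentages.
#'
#' @param reports list of `"classifierReport"` objects covering every
#'   (threshold, feature) cell of the grid.
#' @param grid threshold grid the table must cover (default
#'   [thresholdGrid()]).
#' @param features feature columns (default the four classification
#'   features).
#' @return data.frame with rownames `"0.50"` ... `"0.60"`, `"average"`,
#'   columns the features, values in percent.
#' @export
accuracyTable <- function(reports, grid = thresholdGrid(),
                          features = featureNames()) {
    stopifnot(is.list(reports))
    tab <- matrix(NA_real_, nrow = length(grid), ncol = length(features),
                  dimnames = list(sprintf("%.2f", grid), features))
    for (rep in reports) {
        i <- match(sprintf("%.2f", rep$threshold), rownames(tab))
        j <- match(rep$feature, features)
        if (!is.na(i) && !is.na(j)) tab[i, j] <- 100 * rep$accuracy
    }
    if (anyNA(tab))
        stop("missing accuracy cells: ",
             paste(which(is.na(tab), arr.ind = TRUE)[, 1], collapse = ", "))
    out <- rbind(tab, average = colMeans(tab))
    as.data.frame(out)
}
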