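#' Read / write square matrices as tab-delimited text
#'
#' Adjacency and correlation matrices are stored as square tab-delimited
#' numeric tables without header; adjacency files may carry the threshold
#' in a leading `# threshold=0.53` comment line, restored on reading as the
#' `"threshold"` attribute.
#'
#' @param path file path.
#' @param mat numeric square matrix (or [BinaryNetwork-class] /
#'   [CorrelationMatrix-class], written as its matrix).
#' @param threshold optional threshold recorded in the comment header.
#' @return `readMatrix` returns the matrix (with a `"threshold"` attribute
#'   when the file has one); `writeMatrix` returns `path` invisibly.
#' @export
readMatrix <- function(path) {
    lines <- readLines(path)
    thr <- NA_real_
    hdr <- grepl("^#", lines)
    if (any(hdr)) {
        m <- regmatches(lines[hdr], regexpr("threshold=[0-9.eE+-]+", lines[hdr]))
        if (length(m)) thr <- as.numeric(sub("threshold=", "", m[1]))
        lines <- lines[!hdr]
    }
    rows <- strsplit(lines, "\t", fixed = TRUE)
    n <- length(rows)
    if (n == 0L) stop("empty matrix file: ", path)
    out <- matrix(NA_real_, n, length(rows[[1]]))
    for (i in seq_len(n)) {
        if (length(rows[[i]]) != ncol(out))
            stop("ragged matrix at line ", i, " of ", path)
        v <- suppressWarnings(as.numeric(rows[[i]]))
        if (anyNA(v))
            stop("non-numeric cell at line ", i, ", column ",
                 which(is.na(v))[1], " of ", path)
        out[i, ] <- v
    }
    if (nrow(out) != ncol(out)) stop("matrix is not square: ", path)
    if (!is.na(thr)) attr(out, "threshold") <- thr
    out
}

#' @rdname readMatrix
#' @export
writeMatrix <- function(mat, path, threshold = NULL) {
    if (is(mat, "BinaryNetwork")) {
        if (is.null(threshold)) threshold <- mat@threshold
        mat <- mat@adjacency
    } else if (is(mat, "CorrelationMatrix")) mat <- mat@values
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(threshold) && !is.na(threshold))
        writeLines(sprintf("# threshold=%s", format(threshold)), con)
    utils::write.table(mat, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write topology profile tables
#'
#' CSV with columns `subject_id, group, threshold, global_efficiency,
#' clustering_coefficient, edge_count, transitivity,
#' long_distance_edge_count` (plus `step` for evolution traces).
#'
#' @param profiles data.frame of profiles.
#' @param path file path.
#' @return `readProfiles` returns the data.frame; `writeProfiles` returns
#'   `path` invisibly.
#' @export
readProfiles <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "threshold", "global_efficiency",
              "clustering_coefficient", "edge_count", "transitivity",
              "long_distance_edge_count")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("profile file missing columns: ", paste(miss, collapse = ", "))
    d
}

#' @rdname readProfiles
#' @export
writeProfiles <- function(profiles, path) {
    utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write / read a cohort of subject time series with a manifest
#'
#' Each subject's signal is a tab-delimited regions x timepoints matrix in
#' its own file; the manifest lists `subject_id group path` per line.
#'
#' @param cohort a [SyntheticCohort-class] (or list of
#'   [SubjectTimeSeries-class]).
#' @param dir output directory (created if needed).
#' @param manifestPath path of a manifest file.
#' @return `writeCohort` returns the manifest path invisibly; `readCohort`
#'   returns a list of [SubjectTimeSeries-class].
#' @export
writeCohort <- function(cohort, dir) {
    subjects <- if (is(cohort, "SyntheticCohort")) cohort@subjects else cohort
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- vapply(subjects, function(s) {
        f <- file.path(dir, paste0(s@subjectId, ".tsv"))
        utils::write.table(s@signal, f, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        paste(s@subjectId, s@group, basename(f))
    }, character(1))
    mf <- file.path(dir, "manifest.txt")
    writeLines(rows, mf)
    invisible(mf)
}

#' @rdname writeCohort
#' @export
readCohort <- function(manifestPath) {
    rows <- strsplit(readLines(manifestPath), "[[:space:]]+")
    base <- dirname(manifestPath)
    lapply(rows, function(r) {
        if (length(r) != 3L)
            stop("manifest line must be 'subject_id group path'")
        sig <- as.matrix(utils::read.table(file.path(base, r[3]), sep = "\t"))
        dimnames(sig) <- NULL
        new("SubjectTimeSeries", signal = sig, subjectId = r[1], group = r[2])
    })
}

#' Configuration of the full computational experiment
#'
#' @param cohort a [syntheticCohortConfig()] block.
#' @param evolution an [evolutionParams()] block.
#' @param grid threshold grid (default [thresholdGrid()]).
#' @param seed master seed; deterministically re-seeds the atlas, cohort
#'   and evolution blocks so one integer reproduces the whole experiment.
#' @param outDir optional output directory; when set, all result tables
#'   and a checksum manifest are written there.
#' @return a named list of class `"experimentConfig"`.
#' @export
experimentConfig <- function(cohort = syntheticCohortConfig(),
                             evolution = evolutionParams(),
                             grid = thresholdGrid(), seed = 1L,
                             outDir = NULL) {
    seed <- as.integer(seed)
    cohort$seed <- deriveSeed(seed, 1L)
    evolution$seed <- deriveSeed(seed, 2L)
    structure(list(cohort = cohort, evolution = evolution, grid = grid,
                   seed = seed, atlas_seed = deriveSeed(seed, 3L),
                   outDir = outDir),
              class = c("experimentConfig", "list"))
}

#' Run the full computational experiment
#'
#' Executes every stage in order: atlas generation, synthetic cohort
#' sampling, per-subject Pearson correlation and threshold sweep, topology
#' profiling, per-subject evolution of every healthy network at every
#' threshold, and per-feature SVM classification of the evolved networks
#' against the two groups. Identical configs give identical results.
#'
#' @param config an [experimentConfig()].
#' @param verbose print stage progress (default FALSE).
#' @return a list of class `"experimentResult"`: `atlas`, `profiles`
#'   (per-subject, per-threshold), `evolvedProfiles` (final-step profiles
#'   of each evolved network), `traceProfiles` (per-step profiles of every
#'   evolution), `groupMeans`, `accuracy` (the per-threshold x per-feature
#'   percentage table), `config`, and `manifest` when `outDir` is set.
#' @examples
#' \dontrun{
#' res <- runExperiment(experimentConfig(seed = 1))
#' res$accuracy
#' }
#' @export
runExperiment <- function(config = experimentConfig(), verbose = FALSE) {
    stopifnot(inherits(config, "experimentConfig"))
    say <- function(...) if (verbose) message(...)

    say("stage: atlas")
    atlas <- generateAtlas(config$cohort$n_regions, seed = config$atlas_seed)
    say("stage: cohort")
    cohort <- sampleCohort(config$cohort, atlas)

    say("stage: networks + profiles")
    nets <- list()   # nets[[subject]][[threshold index]]
    profiles <- list()
    for (s in cohort@subjects) {
        cm <- tryCatch(pearsonMatrix(s), error = function(e)
            stop("stage network_construction, subject ", s@subjectId, ": ",
                 conditionMessage(e)))
        sw <- thresholdSweep(cm, config$grid, group = s@group)
        nets[[s@subjectId]] <- sw
        profiles <- c(profiles, lapply(sw, topologyProfile, atlas = atlas))
    }
    profiles <- do.call(rbind, profiles)

    say("stage: evolution")
    healthyIds <- vapply(Filter(function(s) s@group == "healthy",
                                cohort@subjects),
                         function(s) s@subjectId, character(1))
    tracePieces <- list()
    evolvedPieces <- list()
    for (ti in seq_along(config$grid)) {
        tau <- config$grid[ti]
        hn <- lapply(healthyIds, function(id) nets[[id]][[ti]])
        p <- config$evolution
        p$seed <- deriveSeed(config$evolution$seed, 1000L + ti)
        traces <- evolveGroup(hn, atlas, p)
        for (tr in traces) {
            tracePieces[[length(tracePieces) + 1L]] <- tr@profiles
            evolvedPieces[[length(evolvedPieces) + 1L]] <-
                topologyProfile(tr@final, atlas)
        }
    }
    traceProfiles <- do.call(rbind, tracePieces)
    evolvedProfiles <- do.call(rbind, evolvedPieces)

    say("stage: classification")
    reports <- list()
    for (tau in config$grid) {
        ev <- evolvedProfiles[abs(evolvedProfiles$threshold - tau) < 1e-9, ]
        for (f in featureNames()) {
            tr <- tryCatch(buildTrainingSet(profiles, f, tau),
                           error = function(e)
                stop("stage classification, threshold ", tau, ", feature ",
                     f, ": ", conditionMessage(e)))
            reports[[length(reports) + 1L]] <- trainAndClassify(tr, ev[[f]])
        }
    }
    accuracy <- accuracyTable(reports, config$grid)
    groupMeans <- groupMeanProfiles(
        rbind(profiles, evolvedProfiles[, names(profiles)]))

    result <- structure(list(atlas = atlas, cohort = cohort,
                             profiles = profiles,
                             evolvedProfiles = evolvedProfiles,
                             traceProfiles = traceProfiles,
                             groupMeans = groupMeans, accuracy = accuracy,
                             config = config),
                        class = c("experimentResult", "list"))
    if (!is.null(config$outDir))
        result$manifest <- writeExperiment(result, config$outDir)
    result
}

#' Write all experiment result tables plus a checksum manifest
#'
#' @param result an `"experimentResult"` from [runExperiment()].
#' @param dir output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly also written to
#'   `manifest.csv` in `dir`.
#' @export
writeExperiment <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeAtlas(result$atlas, file.path(dir, "atlas.tsv"))
    writeProfiles(result$profiles, file.path(dir, "profiles.csv"))
    writeProfiles(result$evolvedProfiles,
                  file.path(dir, "evolved_profiles.csv"))
    writeProfiles(result$traceProfiles,
                  file.path(dir, "evolution_traces.csv"))
    utils::write.csv(result$groupMeans, file.path(dir, "group_means.csv"),
                     row.names = FALSE, quote = FALSE)
    acc <- cbind(threshold = rownames(result$accuracy),
                 round(result$accuracy, 2))
    utils::write.csv(acc, file.path(dir, "accuracy_table.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c("atlas.tsv", "profiles.csv", "evolved_profiles.csv",
               "evolution_traces.csv", "group_means.csv",
               "accuracy_table.csv")
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(file.path(dir, files))))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest
}
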