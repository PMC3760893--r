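fake_profiles <- function(healthy, ad, threshold = 0.55,
                          feature = "clustering_coefficient") {
    d <- data.frame(subject_id = c(sprintf("h%02d", seq_along(healthy)),
                                   sprintf("a%02d", seq_along(ad))),
                    group = c(rep("healthy", length(healthy)),
                              rep("ad", length(ad))),
                    threshold = threshold)
    d[[feature]] <- c(healthy, ad)
    d
}

test_that("training sets are z-scored with stored statistics", {
    pr <- fake_profiles(rnorm(11, 1), rnorm(10, -1))
    tr <- buildTrainingSet(pr, "clustering_coefficient", 0.55)
    expect_length(tr$values, 21L)
    expect_equal(mean(tr$values), 0, tolerance = 1e-12)
    expect_equal(sd(tr$values), 1, tolerance = 1e-12)
    raw <- c(pr$clustering_coefficient)
    expect_equal(tr$values, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
    expect_equal(as.character(tr$labels),
                 c(rep("healthy", 11), rep("ad", 10)))
})

test_that("degenerate training sets are rejected", {
    pr <- fake_profiles(rnorm(5), numeric(0))
    pr <- pr[pr$group == "healthy", ]
    expect_error(buildTrainingSet(pr, "clustering_coefficient", 0.55),
                 "both groups")
    pr2 <- fake_profiles(rep(1, 5), rep(1, 5))
    expect_error(buildTrainingSet(pr2, "clustering_coefficient", 0.55),
                 "zero training variance")
})

test_that("far-side evolved values get the expected labels", {
    pr <- fake_profiles(rnorm(11, 1, 0.05), rnorm(10, -1, 0.05))
    tr <- buildTrainingSet(pr, "clustering_coefficient", 0.55)
    repAd <- trainAndClassify(tr, rep(-0.9, 7))
    expect_equal(repAd$accuracy, 1)
    expect_equal(repAd$n_classified_ad, 7L)
    repH <- trainAndClassify(tr, rep(1, 7))
    expect_equal(repH$accuracy, 0)
})

test_that("labels match a brute-force 1-D margin maximizer", {
    pr <- fake_profiles(c(2, 3), c(-2, -3))
    tr <- buildTrainingSet(pr, "clustering_coefficient", 0.55)
    evolved <- c(-0.5, 0.5, -3, 3, 0.2)
    rep <- trainAndClassify(tr, evolved)
    oracle <- oracle_margin_classify(pr$clustering_coefficient, pr$group,
                                     evolved)
    expect_equal(rep$labels, oracle)
})

test_that("reports are invariant to feature scale and sample order", {
    set.seed(21)
    h <- rnorm(11, 0.6, 0.1); a <- rnorm(10, 0.35, 0.1)
    ev <- rnorm(8, 0.4, 0.1)
    pr <- fake_profiles(h, a)
    r1 <- trainAndClassify(buildTrainingSet(pr, "clustering_coefficient",
                                            0.55), ev)
    prS <- fake_profiles(5 * h, 5 * a)
    r2 <- trainAndClassify(buildTrainingSet(prS, "clustering_coefficient",
                                            0.55), 5 * ev)
    expect_equal(r1$labels, r2$labels)
    prP <- pr[sample(nrow(pr)), ]
    r3 <- trainAndClassify(buildTrainingSet(prP, "clustering_coefficient",
                                            0.55), ev)
    expect_equal(r1$labels, r3$labels)
})

test_that("the accuracy table has the Table-2 layout and exact averages", {
    reports <- list()
    set.seed(3)
    accs <- matrix(runif(44), 11, 4)
    for (ti in 1:11) for (fi in 1:4) {
        reports[[length(reports) + 1L]] <- structure(list(
            feature = featureNames()[fi],
            threshold = thresholdGrid()[ti],
            n_evolved = 11L,
            n_classified_ad = round(accs[ti, fi] * 11),
            accuracy = round(accs[ti, fi] * 11) / 11,
            labels = character()), class = c("classifierReport", "list"))
    }
    tab <- accuracyTable(reports)
    expect_equal(dim(tab), c(12L, 4L))
    expect_equal(rownames(tab)[12], "average")
    expect_equal(rownames(tab)[1], "0.50")
    for (f in featureNames())
        expect_equal(tab[12, f], sum(tab[1:11, f]) / 11)
    # all-perfect reports average to 100
    perfect <- lapply(reports, function(r) { r$accuracy <- 1; r })
    expect_true(all(accuracyTable(perfect)[12, ] == 100))
    expect_error(accuracyTable(reports[-1]), "missing")
})
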