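# The default computational experiment is expensive (121 evolutions of
# 100 steps), so the acceptance tests share one cached run at a fixed
# master seed.
.expCache <- new.env(parent = emptyenv())

defaultExperiment <- function() {
    if (is.null(.expCache$res))
        .expCache$res <- runExperiment(experimentConfig(seed = 1L))
    .expCache$res
}
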