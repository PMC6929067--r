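# The reference synthetic study (5 training + 5 test ERM volumes, 3
# ERM-free, 32 slices x 128 px, speckle sigma 0.1) with the feature-count
# sweep. Run once and cached: several acceptance tests examine different
# aspects of the same study.

.studyCache <- new.env(parent = emptyenv())

acceptanceStudy <- function() {
  if (is.null(.studyCache$res))
    .studyCache$res <- runStudy(ermConfig(), seed = 1L, sweep = TRUE,
                                verbose = FALSE)
  .studyCache$res
}
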