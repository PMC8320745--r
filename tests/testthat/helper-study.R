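# one full study run shared by the end-to-end assertions; computed lazily
# once per test session under a fixed seed
.studyCache <- new.env(parent = emptyenv())

studyRun <- function() {
  if (is.null(.studyCache$run))
    .studyCache$run <- runMaterialStudy(seed = 101)
  .studyCache$run
}
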