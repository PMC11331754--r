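# One shared synthetic cohort per test session, generated once on first use.
.simCache <- new.env(parent = emptyenv())

simFixture <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.simCache[[key]])) {
    dir <- file.path(tempdir(), paste0("simfix", seed))
    .simCache[[key]] <- suppressWarnings(
      generateCohortData(dir, simParams(), seed = seed))
  }
  .simCache[[key]]
}
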