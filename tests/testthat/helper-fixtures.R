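# shared fixtures; everything is generated in code under fixed seeds

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

# error-free reads tiling a genome evenly, edges included, two passes so every
# k-mer (including terminal ones) reaches the default abundance floor of 2
tiling_reads <- function(genome, read_length = 150L, step = 6L) {
  L <- nchar(genome)
  starts <- seq(1L, L - read_length + 1L, by = step)
  starts <- c(starts, L - read_length + 1L)
  rep(substring(genome, starts, starts + read_length - 1L), 2L)
}

# the standard seeded demo community + pipeline result, computed once per
# test session (acceptance criteria 4 and 5 share it)
demo_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(demo_config(seed = 42L))
    cache
  }
})
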