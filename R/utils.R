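# small shared helpers

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# derive a stage seed from a root seed, staying inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + k)
}

extdata_file <- function(name) {
  system.file("extdata", name, package = "ionopt", mustWork = TRUE)
}
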