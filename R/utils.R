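## Internal helpers: deterministic string hashing and named seed substreams.
## All randomness in the package flows through .deriveSeed(seed, tag) so that
## e.g. the naming stream of a cohort is independent of its geometry stream
## and partial regeneration is stable.

# polynomial rolling hash of a single string, result in [0, mod)
.strHash <- function(s, mod = 2147483647) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% mod
  as.integer(h)
}

# derive a child seed (< 2^31) from a base seed and a stream tag
.deriveSeed <- function(seed, tag) {
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + .strHash(tag, m)) %% m)
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite entries")
  invisible(x)
}
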