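# RNG bookkeeping: functions that consume randomness save and restore the
# global .Random.seed so that seeded package calls do not perturb the
# caller's RNG stream.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# derive a child seed from a base seed and counters, kept inside the
# signed 32-bit range required by set.seed
.child_seed <- function(base, ...) {
  ctr <- c(...)
  s <- as.double(base) %% 2147483647
  for (c_i in ctr) s <- (s * 48271 + as.double(c_i) + 1) %% 2147483647
  as.integer(s)
}

# extract an integer label vector from a parcellation / clustering / vector
.as_labels <- function(x) {
  if (inherits(x, "parcellation")) return(as.integer(x$labels))
  if (is.list(x) && !is.null(x$labels)) return(as.integer(x$labels))
  as.integer(x)
}
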