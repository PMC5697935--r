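# Internal helpers: seeded sub-streams, small numerics.

# Derive a reproducible child seed from a parent seed and a string key.
# Cheap FNV-style hash folded into [0, 2^31 - 2]; keeps every stage's
# randomness a pure function of (session seed, stage key).
derive_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Bin centers tiling [window[1], window[2]] with given width/step.
bin_starts <- function(window, bin_width, bin_step) {
  starts <- seq(window[1], window[2] - bin_width + 1e-12, by = bin_step)
  starts[starts + bin_width <= window[2] + 1e-9]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
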