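#' @include AllClasses.R
NULL

# Shortest decimal representation that reads back to the identical double:
# try 15 significant digits first (pretty for human-made values), fall back
# to 17 where needed so CSV round-trips are exact.
.fmtNum <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- suppressWarnings(as.numeric(s)) != x & !is.na(x)
  if (any(bad)) {
    s[bad] <- sprintf("%.17g", x[bad])
  }
  s
}

# Derive a reproducible sub-seed for a named pseudorandom stream from the
# master seed, keeping the result inside 32-bit integer range.
.streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Run code under a named, isolated RNG stream; restores the caller's RNG.
.withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(.streamSeed(seed, stream))
  expr
}
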