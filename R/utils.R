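## Internal helpers: seeded evaluation and deterministic id hashing.

## Evaluate expr under a local RNG stream; the caller's RNG state is
## untouched. All exported stochastic entry points funnel through this.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Polynomial string hash folded with a master seed, then avalanched with
## multiply/xor-shift rounds so that similar subject ids (e.g. consecutive
## numbering) map to well-separated RNG seeds -- parallel streams seeded
## with consecutive integers would be poorly decorrelated. All arithmetic
## is exact in double precision (intermediates stay below 2^47); result in
## [1, 2^31 - 2].
hashSubjectId <- function(subjectId, seed) {
  m <- 2147483647  # 2^31 - 1
  mulmod <- function(a, b) {  # (a * b) mod m, exact for a < 2^31, b < 2^31
    b1 <- b %/% 32768; b0 <- b %% 32768
    (((a * b1) %% m) * 32768 + a * b0) %% m
  }
  xorshift <- function(h, k)
    bitwXor(as.integer(h), bitwShiftR(as.integer(h), k))
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(subjectId))) {
    h <- (h * 31 + code) %% m
  }
  h <- mulmod(abs(xorshift(h, 16)), 2246822519)
  h <- mulmod(abs(xorshift(h, 13)), 1540483477)
  h <- abs(xorshift(h, 16))
  as.integer(h %% (m - 1)) + 1L
}

## Derive a fresh sub-seed from the current RNG stream.
drawSeed <- function() sample.int(2147483646L, 1L)

logMsg <- function(fmt, ...) message(sprintf(fmt, ...))
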