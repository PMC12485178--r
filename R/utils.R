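# Reproducibility helpers: named RNG streams built on R's Mersenne-Twister
# state, and a small string hash used to fan a root seed out to substreams
# and to fingerprint configurations.

.msssl <- new.env(parent = emptyenv())
.msssl$root_seed <- NULL
.msssl$deterministic <- TRUE

#' Create a resumable random-number stream
#'
#' A stream wraps a saved `.Random.seed`; every draw made through
#' [with_rng()] advances the stream and leaves the global RNG untouched.
#' Streams serialize with checkpoints, which is what makes interrupted
#' pretraining runs bit-exactly resumable.
#'
#' @param seed integer seed.
#' @return an object of class `msssl_rng`.
#' @export
msssl_rng <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  st <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  e <- new.env(parent = emptyenv())
  e$state <- st
  class(e) <- "msssl_rng"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param rng stream from [msssl_rng()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "msssl_rng"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# 32-bit FNV-1a over a character string, returned as 8 hex digits
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, kept exact in
    # doubles by splitting h into 16-bit halves
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# derive a substream seed (< 2^31) from a root seed and a stream name
substream_seed <- function(root, name) {
  h <- strtoi(substr(fnv1a32(name), 1, 7), 16L)
  as.integer((as.numeric(root) * 2654435761 + h) %% 2147483647) + 1L
}

#' Seed every randomness source from one root
#'
#' Records the root seed, seeds the global Mersenne-Twister generator, and
#' turns on deterministic mode (the package's numerical kernels are
#' deterministic by construction; the flag is recorded in checkpoints).
#'
#' @param seed integer root seed.
#' @param deterministic logical.
#' @export
set_global_determinism <- function(seed, deterministic = TRUE) {
  .msssl$root_seed <- as.integer(seed)
  .msssl$deterministic <- isTRUE(deterministic)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  invisible(NULL)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
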