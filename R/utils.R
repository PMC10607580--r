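#' Derive a child seed from a master seed and context values
#'
#' Deterministic integer mixing so every stage and every repeat of the
#' pipeline draws from an independent, reproducible stream. Keeps results in
#' `[1, 2^31 - 2]` so they are valid R seeds.
#'
#' @param master_seed integer master seed.
#' @param ... further numeric/character context values (e.g. gamma, beta,
#'   run index) folded into the hash in order.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  h <- as.double(master_seed) %% 2147483647
  for (x in list(...)) {
    if (is.character(x)) {
      x <- sum(utf8ToInt(paste(x, collapse = "/")))
    }
    # scale so fractional grid values (gamma, beta) map to distinct integers
    x <- floor(as.double(x[1]) * 1e6) %% 2147483647
    h <- (h * 48271 + x + 11) %% 2147483647
    h <- (h * 69621 + 7) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
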