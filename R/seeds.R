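#' Derive a reproducible sub-seed from a root seed
#'
#' Simulations draw from several logically independent random streams
#' (trial timelines, yoked cue onsets, safe-space layouts, agent behaviour).
#' `derive_seed()` maps a root seed plus a stream label (and optionally a
#' participant or block index) to a 31-bit seed through a deterministic
#' integer hash, so distinct labels get distinct, uncorrelated streams and
#' any single component of a run can be reproduced in isolation.
#'
#' The hash is FNV-1a over the bytes of `"<root>|<label>|<index>"` followed
#' by an avalanche finaliser, all in 32-bit arithmetic emulated in doubles
#' (exact below 2^53).
#'
#' @param root_seed Non-negative integer root seed.
#' @param label Character scalar naming the stream.
#' @param index Optional non-negative integer (participant, block, ...).
#' @return An integer in `[0, 2^31 - 1]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "timeline")
#' derive_seed(1, "timeline", 2)
#' @export
derive_seed <- function(root_seed, label, index = 0L) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, root_seed >= 0,
            is.character(label), length(label) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  key <- sprintf("%.0f|%s|%.0f", root_seed, label, index)
  h <- 2166136261 # FNV offset basis
  for (b in utf8ToInt(key)) {
    h <- mul32(bitwXor32(h, b), 16777619)
  }
  # avalanche (fmix-style) so short keys still differ in the high bits
  h <- bitwXor32(h, floor(h / 65536))
  h <- mul32(h, 2246822507)
  h <- bitwXor32(h, floor(h / 8192))
  h <- mul32(h, 3266489909)
  h <- bitwXor32(h, floor(h / 65536))
  as.integer(h %% 2147483648)
}

# 32-bit helpers on doubles ------------------------------------------------

mul32 <- function(a, b) {
  # (a * b) mod 2^32 without exceeding 2^53
  a <- a %% 4294967296; b <- b %% 4294967296
  ah <- floor(a / 65536); al <- a %% 65536
  (al * b + ((ah * b) %% 65536) * 65536) %% 4294967296
}

bitwXor32 <- function(a, b) {
  # xor of two non-negative < 2^32 values via 16-bit halves
  a <- a %% 4294967296; b <- b %% 4294967296
  hi <- bitwXor(as.integer(floor(a / 65536)), as.integer(floor(b / 65536)))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the
#' caller's RNG state afterwards, so seeded constructors are pure
#' functions of their arguments and never perturb surrounding randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}
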