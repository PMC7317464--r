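# Seed plumbing: one master seed spawns per-stage, per-replicate substream
# seeds through integer hashing, so adding a stage or replicate never
# perturbs the draws of another.

#' Derive a substream seed from a master seed
#'
#' Hashes a master seed together with stage labels and replicate indices
#' into a seed in \[1, 2^31 - 2\]. Deterministic; different label/index
#' combinations give effectively independent streams.
#'
#' @param master_seed Integer master seed.
#' @param ... Stage labels (character) and indices (numeric) identifying the
#'   substream.
#' @return A single integer seed.
#' @export
substream_seed <- function(master_seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      for (ch in utf8ToInt(paste(part, collapse = "/"))) {
        h <- (h * 131 + ch) %% m
      }
    } else {
      for (v in as.numeric(part)) {
        h <- (h * 131071 + v %% m + 7) %% m
      }
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# evaluate code under a seed, restoring the caller's RNG state afterwards
with_substream <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
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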