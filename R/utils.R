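#' @useDynLib exmloc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# classed condition helper so callers can distinguish failure modes
stop_exm <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "exmloc_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Derive a named random substream seed from a master seed
#'
#' All randomness in the package flows from one top-level seed; each stage
#' (geometry, placement, noise, annotation, ...) draws from its own substream
#' so that changing one stage's consumption does not perturb the others.
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
seed_stream <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (master %% 2147483647) * 48271) %% 2147483647)
}

# run expr under a locally-set seed without touching the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# physical center of 0-based voxel index i is (i + 0.5) * pitch
voxel_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

`%||%` <- function(a, b) if (is.null(a)) b else a
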