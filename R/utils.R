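# Internal helpers: structured errors and seed discipline.

tfs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tissueFS_error")))
}

#' Derive a per-stage seed from a global seed
#'
#' Hashes a stage name together with a global integer seed so that adding or
#' reordering pipeline stages never perturbs the random stream of another
#' stage. The result is a non-negative integer below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  # multiplicative string hash in double precision (exact below 2^53)
  acc <- 7
  for (v in utf8ToInt(paste0(stage, ":", format(seed)))) {
    acc <- (acc * 131 + v) %% 2147483647
  }
  as.integer((acc * 16807) %% 2147483629)
}

# Evaluate an expression under a local RNG state, restoring the caller's.
with_local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}
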