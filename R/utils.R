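#' Derive a reproducible child seed from a master seed and a label
#'
#' Per-pathway random draws use child seeds derived by a stable string hash of
#' the master seed and the pathway name, so results do not depend on the order
#' in which pathways are processed.
#'
#' @param master integer master seed.
#' @param label character label (e.g. a pathway name).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
child_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(label), length(label) == 1L)
  mod <- 2147483647 # 2^31 - 1, keeps the polynomial hash in exact-double range
  h <- abs(as.numeric(master)) %% mod
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  expr
}

# shared input check used by the statistical stages
check_probabilities <- function(p, what = "p-values") {
  if (!is.numeric(p)) stop(what, " must be numeric", call. = FALSE)
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) {
    stop(what, " outside [0, 1] at position ", which(!ok)[1L], call. = FALSE)
  }
  invisible(p)
}
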