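# Seeding utilities: every stochastic routine draws from its own RNG
# stream so module-level reproducibility never depends on call order,
# and the caller's global RNG state is left untouched.

local_rng <- function(seed) {
  state <- NULL
  with_state <- function(f, ...) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    out <- f(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
  list(
    runif = function(...) with_state(stats::runif, ...),
    rnorm = function(...) with_state(stats::rnorm, ...),
    rlnorm = function(...) with_state(stats::rlnorm, ...),
    sample = function(...) with_state(base::sample, ...)
  )
}

#' Derive a named sub-seed from a root seed
#'
#' All randomness in multi-stage runs flows from one root seed through
#' named substreams, so modules stay reproducible independently of call
#' order.
#'
#' @param root integer root seed. @param name substream name.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(root) * 7919 + h) %% 2147483647)
}

nrmse_range <- function(img, ref) {
  rng <- diff(range(ref))
  if (rng == 0) rng <- max(abs(ref), 1e-12)
  sqrt(mean((img - ref)^2)) / rng
}
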