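`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a deterministic sub-seed from a master seed and a stream tag
#'
#' One master seed governs synthesis, model initialization and batch order.
#' Named substreams keep the sources of randomness independent: adding exams to
#' a site never perturbs the noise of earlier exams, and model initialization
#' does not depend on how many exams were generated. The derived seed is a
#' 31-bit non-negative integer, safe for [set.seed()].
#'
#' @param seed Master seed (integer).
#' @param tag Character tag naming the stream (e.g. `"placement"`).
#' @param index Optional integer index within the stream (e.g. exam number).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 17
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  # splitmix-style mixing kept within double precision (< 2^53)
  s <- (abs(seed) %% m)
  s <- (s * 48271) %% m
  s <- (s + h * 69621) %% m
  s <- (s + (index %% m) * 16807) %% m
  as.integer((s * 48271) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Row-wise softmax of a matrix (R x K); stable against large logits.
softmax_rows <- function(u) {
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  m <- apply(u, 1L, max)
  e <- exp(u - m)
  e / rowSums(e)
}

# Channel-wise softmax of a (K, X, Y, Z) logit array.
softmax_channels <- function(u) {
  d <- dim(u)
  K <- d[1L]
  m <- matrix(u, nrow = K)
  mx <- m[1L, ]
  if (K > 1L) for (k in 2:K) mx <- pmax(mx, m[k, ])
  e <- exp(m - rep(mx, each = K))
  s <- .colSums(e, K, ncol(e))
  array(e / rep(s, each = K), dim = d)
}

stop_fl <- function(fmt, ..., class) {
  stop(structure(class = c(class, "fl_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
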