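#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the previous RNG state so that
#' seeded package functions do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a top-level seed
#'
#' A single pipeline seed fans out to one seed per stage through a stable
#' string hash, so each stage is individually reproducible and stages do not
#' share random streams.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name (e.g. `"generate"`, `"embed"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "generate")
#' derive_seed(1, "embed")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 2166136261
  for (b in utf8ToInt(stage)) {
    h <- ((h * 16777619) %% 2147483647 + b) %% 2147483647
  }
  as.integer((abs(seed) * 69069 + h) %% 2147483647)
}

# circular distance on [0, 2*pi): min(|a-b|, 2*pi - |a-b|)
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

wrap_angle <- function(theta) theta %% (2 * pi)

# stable, locale-independent ordering (C byte order)
order_c <- function(...) order(..., method = "radix")

# FNV-1a style hash of a config list, for artifact provenance stamps
config_hash <- function(config) {
  s <- paste(deparse(config[order_c(names(config))]), collapse = "")
  h <- 216613626
  for (b in utf8ToInt(s)) h <- ((h * 16777619) %% 2147483629 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}
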