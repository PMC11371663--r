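# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package funnel through this.
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
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Splits one master seed into independent, documented per-stage seeds so that
#' re-running a single analysis stage reproduces its slice of a full run.
#' The rule is a simple order-sensitive character hash folded into 31 bits.
#'
#' @param master Integer master seed.
#' @param ... Character labels (e.g. pair id, stage name).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), ...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- 0
  for (i in seq_along(codes)) h <- (h * 131 + codes[i]) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 * 1009 + h) %% 2147483647)
}

# Trapezoid-rule integral of y over x (x increasing).
trapezoid <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
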