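#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus an arbitrary set of string tags
#' (subject id, stage name, ...) to an integer seed below 2^31, so that
#' per-subject and per-stage random streams never collide and never depend
#' on iteration order.
#'
#' @param master integer master seed.
#' @param ... character tags identifying the stream.
#' @return a single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer((h + as.numeric(master)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
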