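# Internal helpers: argument checking and seed substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob_vector <- function(p, what) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop(sprintf("invalid config: %s must be a nonnegative numeric vector", what),
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop(sprintf("invalid config: %s must sum to 1 (got %.15f)", what, sum(p)),
         call. = FALSE)
  invisible(p)
}

check_positive_scalar <- function(x, what, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok)
    stop(sprintf("invalid config: %s must be a %s finite number",
                 what, if (strict) "positive" else "nonnegative"), call. = FALSE)
  invisible(x)
}

check_surv_vectors <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("events must be coded 0/1", call. = FALSE)
  invisible(NULL)
}

#' Derive a deterministic per-stage seed from a master seed
#'
#' One master seed spawns named substreams, so that adding or re-running one
#' pipeline stage (e.g. financial-toxicity label generation) cannot perturb
#' the random draws of another. The map is a simple 31-bit string hash mixed
#' with the master seed; it is stable across platforms and R sessions.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((h + (abs(master) %% m) * 48271) %% m)
}
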