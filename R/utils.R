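#' @keywords internal
"_PACKAGE"

# Derive a reproducible substream seed from a global seed and a stream name.
# Keeps derived seeds in [0, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("configuration error: '%s' must be a single finite number in [%s, %s]",
          name, format(lower), format(upper))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("configuration error: '%s' must be TRUE or FALSE", name)
  invisible(x)
}

#' Trend class labels
#'
#' The five-way classification used throughout: significant/non-significant
#' increase or decrease plus an exactly-flat class.
#' @export
TREND_CLASSES <- c("SIG_INC", "NONSIG_INC", "NONSIG_DEC", "SIG_DEC", "FLAT")
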