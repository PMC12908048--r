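# Shared internal helpers: rounding, seeded substreams, validation plumbing.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moved away from zero,
#' the convention used when tabulating clinical percentages (in contrast to
#' [base::round()]'s round-half-to-even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(0.5375 * 100, 1) # 53.8
#' round_half_away(-2.5) # -3
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, tabulation style
#'
#' `percent(n, total)` is `100 * n / total` rounded half away from zero to
#' one decimal, the format used in clinical characteristics tables.
#'
#' @param n Count (numerator).
#' @param total Denominator count.
#' @param digits Decimal places kept (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' percent(37, 80) # 46.3
#' @export
percent <- function(n, total, digits = 1) {
  stopifnot(all(total > 0))
  round_half_away(100 * n / total, digits)
}

# Deterministic substream seed derived from a global seed and a stream name.
# Keeps independent stages/variables on separate, reproducible streams so
# adding one draw does not shift another stream's draws.
derive_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((h + as.numeric(seed)) %% m)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
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

# Validation failure carrying a dedicated condition class so callers and
# tests can distinguish bad inputs from programming errors.
validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "strokedysbiosis_validation_error")
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) validation_error(msg, ...)
  invisible(TRUE)
}
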