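#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats median predict quantile rbinom rnorm runif sd setNames
#'   qbeta glm binomial loess fitted coef complete.cases
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                lowerOpen = FALSE, upperOpen = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lowerOpen) x > lower else x >= lower) &&
    (if (upperOpen) x < upper else x <= upper)
  if (!ok) .stopf("'%s' must be a single number in %s%s, %s%s",
                  name, if (lowerOpen) "(" else "[", format(lower),
                  format(upper), if (upperOpen) ")" else "]")
  invisible(x)
}

## Deterministic child seeds: every internal stochastic stage derives its own
## seed from the user-facing one so stages can be re-run in isolation.
## Kept below 2^31 - 1 (R integers are 32-bit).
.childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

.md5Object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  ## version = 2 keeps hashes stable across minor R serialization changes
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Percentage of a count within a total
#'
#' Small reporting helper used by cohort summaries: the percentage a count
#' represents of its total, rounded to a fixed number of decimals (one by
#' default, the convention of clinical baseline tables).
#'
#' @param x count (numerator).
#' @param n total (denominator), must be positive.
#' @param digits decimals to round to.
#' @return Numeric percentage on the 0-100 scale.
#' @examples
#' proportionPct(50, 119)  # 42.0
#' @export
proportionPct <- function(x, n, digits = 1) {
  if (any(n <= 0)) .stopf("total must be positive")
  round(100 * x / n, digits)
}
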