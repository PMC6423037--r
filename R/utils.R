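#' Geometric mean
#'
#' @param x Numeric vector, all values strictly positive.
#' @param na.rm Drop `NA` values first.
#' @return The geometric mean `exp(mean(log(x)))`.
#' @examples
#' geomMean(c(16, 25)) # 20
#' @export
geomMean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geomMean() requires strictly positive values")
  exp(mean(log(x)))
}

# significance stars for a two-sided p-value; thresholds 0.05 / 0.01 / 0.001
#' Star-code a p-value
#'
#' Pure step function of `p` with the conventional thresholds:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
starCode <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

# internal: stop unless all conditions named in ... are TRUE, with a readable message
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
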