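#' First-order summary statistics shared by all descriptor families
#'
#' Computes the five summary statistics used throughout the descriptor
#' blocks: mean, median, sample standard deviation (n - 1), Fisher skewness
#' `m3 / m2^1.5`, and excess kurtosis `m4 / m2^2 - 3` (central moments
#' `m_k`). Conventions for degenerate inputs: an empty vector yields all
#' zeros; constant input yields `(c, c, 0, 0, 0)`.
#'
#' @param v numeric vector (NAs are dropped).
#' @return Named numeric vector of length 5
#'   (`mean`, `median`, `sd`, `skewness`, `kurtosis`).
#' @examples
#' fiveStats(c(1, 2, 3))
#' fiveStats(rep(2, 10))
#' @export
fiveStats <- function(v) {
  v <- v[!is.na(v)]
  out <- setNames(numeric(5L), .STAT_NAMES)
  n <- length(v)
  if (n == 0L) return(out)
  m <- mean(v)
  out["mean"] <- m
  out["median"] <- median(v)
  if (n >= 2L) out["sd"] <- sd(v)
  m2 <- mean((v - m)^2)
  if (m2 > 1e-12 * max(1, m^2)) {
    out["skewness"] <- mean((v - m)^3) / m2^1.5
    out["kurtosis"] <- mean((v - m)^4) / m2^2 - 3
  }
  out
}
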