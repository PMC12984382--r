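#' Benjamini-Hochberg step-up false discovery rates
#'
#' Standard step-up adjustment: with order statistics \eqn{p_{(1)} \le \dots
#' \le p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} (m/j)\, p_{(j)}}, clipped at 1,
#' with ties preserved and the input order restored.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]; no missing values
#'   (callers exclude untested features before adjusting).
#' @return numeric vector of adjusted values (FDR), same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues)) stop_input("missing p-values are not allowed")
  if (any(pvalues < 0 | pvalues > 1)) stop_input("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q[order(o)]
}
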