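#' Beta-value to M-value conversion
#'
#' Methylation Beta values (methylated / total intensity, in \[0,1\]) are
#' compressed near 0 and 1; analysis is usually done on M-values, the base-2
#' logit \eqn{M = \log_2(\beta / (1 - \beta))}. Values are clipped to
#' `[eps, 1 - eps]` first so that fully (un)methylated probes map to finite
#' M-values.
#'
#' @param beta Numeric vector of Beta values in \[0,1\] (`NA` passed through).
#' @param eps Clip bound in (0, 0.5); default `1e-6`.
#' @return Numeric vector of M-values.
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5) {
    stop("`eps` must be a single value in (0, 0.5)", call. = FALSE)
  }
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("Beta values must lie in [0, 1]; offending value: ",
         format(beta[bad][1L]), call. = FALSE)
  }
  b <- clip(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' M-value to Beta-value conversion
#'
#' Inverse of [beta_to_m()]: \eqn{\beta = 2^M / (1 + 2^M)}. Round-trips
#' `beta_to_m()` within 1e-12 on the unclipped domain.
#'
#' @param m_value Numeric vector of finite M-values (`NA` passed through).
#' @return Numeric vector of proportions in (0, 1).
#' @examples
#' m_to_beta(c(0, 2)) # 0.5, 0.8
#' @export
m_to_beta <- function(m_value) {
  if (any(!is.na(m_value) & !is.finite(m_value))) {
    stop("M-values must be finite", call. = FALSE)
  }
  # 2^M/(1+2^M) = sigmoid(M log 2), numerically stable for large |M|
  sigmoid(m_value * log(2))
}
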