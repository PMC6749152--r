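#' Estimate the variance-prior hyperparameters (d0, s0^2)
#'
#' Method-of-moments fit of the scaled inverse chi-square prior underlying
#' the moderated t-statistic. Writing \eqn{e_g = \log s_g^2 -
#' \psi(d_g/2) + \log(d_g/2)} for each feature's log pooled variance
#' (bias-corrected so that \eqn{E[e_g] = \log \sigma_g^2} under the model),
#' the excess spread of \eqn{e_g} beyond the sampling contribution
#' \eqn{\psi'(d_g/2)} identifies the prior degrees of freedom:
#' \deqn{\psi'(d_0/2) = \mathrm{var}(e_g) - \overline{\psi'(d_g/2)}}
#' solved numerically via the inverse trigamma function, and then
#' \deqn{s_0^2 = \exp\{\overline{e_g} + \psi(d_0/2) - \log(d_0/2)\}.}
#' When the observed spread does not exceed the sampling contribution the
#' prior is degenerate: \code{d0 = Inf} and \code{s0Sq = exp(mean(e_g))}.
#'
#' Features with non-positive sample variance carry no information about the
#' spread of \eqn{\log \sigma^2} and are dropped from the fit (they are still
#' shrunk by [moderatedT()]).
#'
#' @param sSqValues numeric vector of per-feature pooled sample variances.
#' @param dG residual degrees of freedom, a single value or one per feature.
#' @return list with elements \code{d0} (possibly \code{Inf}) and
#'   \code{s0Sq}.
#' @examples
#' set.seed(1)
#' sigma2 <- 0.05 * 4 / rchisq(5000, df = 4)          # true variances
#' s2 <- sigma2 * rchisq(5000, df = 4) / 4            # observed pooled variances
#' estimatePrior(s2, dG = 4)
#' @seealso [moderatedT()]
#' @export
estimatePrior <- function(sSqValues, dG) {
    if (length(dG) == 1L) dG <- rep(dG, length(sSqValues))
    stopifnot(length(dG) == length(sSqValues))
    ok <- is.finite(sSqValues) & sSqValues > 0 & dG >= 1
    if (sum(ok) < 10L)
        stop("prior estimation needs at least 10 features with positive ",
             "variance and dG >= 1 (got ", sum(ok), ")")
    s2 <- sSqValues[ok]; df <- dG[ok]
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (!is.finite(evar) || evar <= 0) {
        return(list(d0 = Inf, s0Sq = exp(mean(e))))
    }
    d0 <- 2 * trigammaInverse(evar)
    s0Sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0Sq = s0Sq)
}

# Newton solve of trigamma(x) = y, monotone decreasing on (0, Inf).
trigammaInverse <- function(y) {
    stopifnot(is.finite(y), y > 0)
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
        x <- x + dif
        if (abs(dif / x) < 1e-10) break
    }
    x
}
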