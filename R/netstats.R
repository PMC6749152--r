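#' Per-node degrees of a tripartite network
#'
#' @param network a \linkS4class{TripartiteNetwork} (non-empty).
#' @return named integer vector, one entry per node (all three classes
#'   pooled).
#' @export
nodeDegrees <- function(network) {
    stopifnot(is(network, "TripartiteNetwork"))
    ed <- networkEdges(network)
    if (nrow(ed) == 0L) stop("network is empty")
    ends <- c(ed$mirna, ed$target)
    tab <- table(ends)
    stats::setNames(as.integer(tab), names(tab))
}

#' Degree distribution of a tripartite network
#'
#' Counts nodes at each degree, pooling all three node classes; the counts
#' sum to the node count. This is the histogram behind the scale-free
#' diagnostic of the ceRNA network.
#'
#' @param network a \linkS4class{TripartiteNetwork} (non-empty).
#' @return data.frame with columns \code{degree}, \code{nNodes}, ascending
#'   degree.
#' @export
degreeDistribution <- function(network) {
    deg <- nodeDegrees(network)
    tab <- table(deg)
    out <- data.frame(degree = as.integer(names(tab)),
                      nNodes = as.integer(tab))
    out[order(out$degree), , drop = FALSE]
}

#' Fit a power law to a degree sample
#'
#' Fits \eqn{P(k) \propto k^{-\alpha}} for \eqn{k \ge x_{min}}. The default
#' \code{method = "discrete"} maximizes the zeta-function likelihood
#' \eqn{-n \log \zeta(\alpha, x_{min}) - \alpha \sum \log x_i}, appropriate
#' for integer degrees (unbiased down to \eqn{x_{min} = 1}). The
#' \code{"continuous"} method is the closed-form continuous-MLE
#' approximation \eqn{\hat\alpha = 1 + n / \sum \ln(x_i / x_{min})}, which
#' is only accurate for integer data when \eqn{x_{min}} is large; it is
#' retained as a quick diagnostic. A least-squares fit of log frequency on
#' log degree over nonzero histogram bins (slope and \eqn{R^2}) accompanies
#' either estimate, mirroring the visual log-log check of scale-freeness.
#'
#' @param degrees integer vector of node degrees (e.g. [nodeDegrees()]).
#' @param xmin lower cutoff, default 1.
#' @param method \code{"discrete"} (default) or \code{"continuous"}.
#' @return a \linkS4class{PowerLawFit}.
#' @examples
#' deg <- simulatePowerLawDegrees(2000, alpha = 2.5, seed = 1)
#' fitPowerLaw(deg)
#' @export
fitPowerLaw <- function(degrees, xmin = 1,
                        method = c("discrete", "continuous")) {
    method <- match.arg(method)
    stopifnot(is.numeric(degrees), xmin >= 1)
    x <- degrees[degrees >= xmin]
    n <- length(x)
    if (n < 2L) stop("need at least 2 degrees >= xmin (got ", n, ")")
    if (all(x == xmin))
        stop("all degrees equal xmin; the exponent is undefined")
    alpha <- if (method == "continuous") {
        1 + n / sum(log(x / xmin))
    } else {
        negll <- function(a) n * log(hurwitzZeta(a, xmin)) + a * sum(log(x))
        stats::optimize(negll, interval = c(1 + 1e-4, 25))$minimum
    }
    # log-log least squares on the nonzero histogram bins of the tail
    tab <- table(x)
    k <- as.numeric(names(tab)); f <- as.numeric(tab)
    if (length(k) >= 2L) {
        fit <- stats::lm(log(f) ~ log(k))
        slope <- unname(stats::coef(fit)[2])
        r2 <- summary(fit)$r.squared
    } else {
        slope <- NA_real_; r2 <- NA_real_
    }
    new("PowerLawFit", alpha = alpha, method = method, xmin = as.numeric(xmin),
        nTail = as.integer(n), loglogSlope = slope, loglogR2 = r2)
}

# Hurwitz zeta sum_{k=xmin}^Inf k^-a, direct sum plus integral tail.
hurwitzZeta <- function(a, xmin = 1) {
    K <- 10000L
    ks <- seq.int(from = xmin, length.out = K)
    head <- sum(ks^(-a))
    tail <- (ks[K] + 0.5)^(1 - a) / (a - 1)
    head + tail
}

#' Draw integer degrees from a discrete power law
#'
#' Samples from \eqn{P(k) = k^{-\alpha} / \zeta(\alpha, x_{min})} for
#' \eqn{k \ge x_{min}} by inversion over a truncated support (upper cap
#' carrying < 1e-6 of the mass). Intended for calibrating and testing the
#' power-law fitter.
#'
#' @param n number of draws.
#' @param alpha exponent > 1.
#' @param xmin lower cutoff, default 1.
#' @param seed integer seed.
#' @return integer vector of length \code{n}.
#' @export
simulatePowerLawDegrees <- function(n, alpha = 2.5, xmin = 1, seed = 1) {
    stopifnot(alpha > 1, xmin >= 1, n >= 1)
    cap <- 100000L
    ks <- seq.int(from = xmin, to = cap)
    w <- ks^(-alpha)
    withSeed(componentSeed(seed, "powerlaw"), {
        ks[sample.int(length(ks), size = n, replace = TRUE, prob = w)]
    })
}

#' Log-log degree-distribution plot
#'
#' Writes (or draws) the degree histogram on log-log axes with the fitted
#' power-law slope overlaid — the standard visual check of a scale-free
#' (heavy-tailed) degree distribution.
#'
#' @param network a \linkS4class{TripartiteNetwork}.
#' @param fit optional \linkS4class{PowerLawFit} to overlay.
#' @param file optional path; when given, a PNG is written there.
#' @return invisibly, the degree distribution data.frame.
#' @export
plotDegreeDistribution <- function(network, fit = NULL, file = NULL) {
    dd <- degreeDistribution(network)
    if (!is.null(file)) {
        grDevices::png(file, width = 600, height = 600)
        on.exit(grDevices::dev.off())
    }
    graphics::plot(dd$degree, dd$nNodes, log = "xy",
                   xlab = "degree", ylab = "number of nodes",
                   pch = 19, col = "steelblue",
                   main = "Degree distribution")
    if (!is.null(fit)) {
        k <- range(dd$degree)
        kk <- exp(seq(log(k[1]), log(k[2]), length.out = 50))
        scale <- max(dd$nNodes)
        graphics::lines(kk, scale * (kk / k[1])^(-fit@alpha),
                        col = "firebrick", lwd = 2)
    }
    invisible(dd)
}
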