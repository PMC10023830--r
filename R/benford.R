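# Benford first-digit analysis of centrality distributions.

#' First significant decimal digit
#'
#' Extracts the first significant digit of positive finite values by
#' scaling with powers of 10 (no string formatting, so the result is
#' locale-independent). Zero, negative and non-finite values yield
#' \code{NA} -- Benford's law is defined on positive significands only --
#' and are counted as excluded by [benfordTest()].
#'
#' @param x Numeric vector.
#' @return Integer vector of digits in 1..9, \code{NA} for excluded values.
#' @examples
#' firstDigit(c(0.00042, 1252028, 9.9999))  # 4 1 9
#' @export
firstDigit <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- is.finite(x) & x > 0
    if (any(ok)) {
        v <- x[ok]
        e <- floor(log10(v))
        m <- v / 10^e
        # guard against floating dust around powers of 10
        low <- m < 1
        m[low] <- m[low] * 10
        high <- m >= 10
        m[high] <- m[high] / 10
        d <- as.integer(pmin(floor(m), 9))
        d[d < 1L] <- 1L
        out[ok] <- d
    }
    out
}

#' The Benford first-digit distribution
#'
#' \eqn{P(f) = \log_{10}(1 + 1/f)} for \eqn{f = 1, \dots, 9}; the nine
#' probabilities telescope to exactly 1.
#'
#' @return Numeric vector of length 9, named by digit.
#' @examples
#' benfordPmf()[1]  # log10(2) ~= 0.30103
#' @export
benfordPmf <- function() {
    p <- log10(1 + 1 / (1:9))
    names(p) <- as.character(1:9)
    p
}

#' Test a sample against Benford's law
#'
#' Compares the first-digit distribution of a positive sample (or of a
#' [CentralityTable-class]) with the Benford distribution using three
#' distances: Pearson's chi-squared statistic
#' \eqn{\chi^2 = \sum_f (O_f - n p_f)^2 / (n p_f)} (reported as a raw
#' distance, no p-value), the 1-D Wasserstein (earth-mover) distance on the
#' ordered digit support \eqn{\sum_k |F_{obs}(k) - F_{Benford}(k)|}, and
#' the sum of squared deviations \eqn{\sum_f (O_f/n - p_f)^2}. Zero and
#' non-finite values are excluded before digit extraction and the exclusion
#' count reported (zero centralities -- e.g. the betweenness of leaves --
#' carry no significand).
#'
#' @param values Numeric vector or [CentralityTable-class].
#' @return A [BenfordReport-class].
#' @examples
#' benfordTest(rlnorm(1000, sdlog = 4))
#' @export
benfordTest <- function(values) {
    if (is(values, "CentralityTable"))
        values <- values@values
    digits <- firstDigit(values)
    excluded <- sum(is.na(digits))
    digits <- digits[!is.na(digits)]
    n <- length(digits)
    if (n == 0)
        stop("no usable (positive, finite) values in the sample")
    counts <- tabulate(digits, nbins = 9L)
    pObs <- counts / n
    pB <- unname(benfordPmf())
    chi2 <- sum((counts - n * pB)^2 / (n * pB))
    wass <- sum(abs(cumsum(pObs) - cumsum(pB)))
    ssd <- sum((pObs - pB)^2)
    qq <- cbind(theoretical = cumsum(pB), observed = cumsum(pObs))
    rownames(qq) <- as.character(1:9)
    new("BenfordReport", digitCounts = counts, nUsed = n,
        nExcluded = excluded, pObserved = pObs, pBenford = pB,
        chi2 = chi2, wasserstein = wass, ssd = ssd, qqPoints = qq)
}

#' Per-digit table of a Benford report
#'
#' @param report A [BenfordReport-class].
#' @return A 9-row \code{data.frame} with observed counts/proportions and
#'   Benford proportions, ready for histogram or Q--Q plotting.
#' @export
benfordDigitTable <- function(report) {
    data.frame(digit = 1:9, observed_count = report@digitCounts,
               observed_p = report@pObserved, benford_p = report@pBenford,
               observed_cum = report@qqPoints[, "observed"],
               benford_cum = report@qqPoints[, "theoretical"])
}
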