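#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between a new measurement and a reference via
#' the paired differences `d = estimate - reference`: the bias is
#' `mean(d)`, the spread the sample standard deviation (n-1 divisor),
#' and the 95% limits of agreement are `bias +/- 1.96 * sd`.
#'
#' @param estimates numeric vector of new-method values.
#' @param references numeric vector of reference values, same length.
#' @return Object of class `bland_altman`: `n`, `bias`, `sd`, `loa_low`,
#'   `loa_high`, `inside_fraction`, and `pairs` (data frame of the
#'   per-pair mean and difference).
#' @examples
#' ba <- bland_altman(c(1.0, 2.1, 3.0), c(1.1, 2.0, 3.1))
#' ba$bias
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop("shape error: estimates and references must have equal length")
  n <- length(estimates)
  if (n < 2) stop("insufficient-data error: need at least 2 pairs")
  stopifnot(is.numeric(estimates), is.numeric(references))
  d <- estimates - references
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  inside <- mean(d >= loa[1] & d <= loa[2])
  structure(list(n = n, bias = bias, sd = s,
                 loa_low = loa[1], loa_high = loa[2],
                 inside_fraction = inside,
                 pairs = data.frame(mean = (estimates + references) / 2,
                                    difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d)\n  bias %.5g, SD of differences %.5g\n  95%% LOAs [%.5g, %.5g]; %.1f%% of pairs inside\n",
    x$n, x$bias, x$sd, x$loa_low, x$loa_high, 100 * x$inside_fraction))
  invisible(x)
}
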