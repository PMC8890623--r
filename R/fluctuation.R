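# Luria-Delbruck fluctuation-assay rate estimation by the Lea-Coulson method
# of the median, with 95% confidence intervals and the CI-overlap rule.

#' Estimate m (expected mutations per culture) by the method of the median
#'
#' Solves the Lea-Coulson median equation \eqn{\tilde r/m - \ln m = 1.24},
#' where \eqn{\tilde r} is the sample median mutant count, by bracketing
#' bisection to a relative tolerance of 1e-9. The median estimator needs a
#' sample median of at least one mutant; when at least half the cultures are
#' zero (median below 1) it is undefined and the p0 method
#' \eqn{m = -\ln(\mathrm{fraction\ of\ zero\ cultures})} is used instead
#' (flagged in the result).
#'
#' @param counts integer mutant counts, one per culture (>= 2 cultures).
#' @return list with \code{m}, \code{r_median}, \code{method}
#'   (\code{"lc-median"} or \code{"p0"}).
#' @examples
#' estimate_m_median(c(1, 1, 2, 2))$m  # median 1.5
#' @export
estimate_m_median <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 cultures")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  r_med <- stats::median(counts)
  if (r_med < 1) {
    p0 <- mean(counts == 0)
    return(list(m = -log(p0), r_median = r_med, method = "p0"))
  }
  f <- function(m) r_med / m - log(m) - 1.24
  lo <- 1e-9
  hi <- max(r_med, 1)
  while (f(hi) > 0) hi <- hi * 2
  # f is strictly decreasing on (0, Inf); bisect to relative tolerance 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-9) break
  }
  list(m = (lo + hi) / 2, r_median = r_med, method = "lc-median")
}

#' Estimate a mutation/recombination rate from one fluctuation experiment
#'
#' Point estimate: \code{rate = m / N_t} with m from
#' [estimate_m_median()] and \code{N_t} the viable cells per culture (the
#' mean of the supplied measurements when several are given). The 95% CI uses
#' the large-sample approximation on the log scale,
#' \eqn{\sigma_{\ln m} = 1.225\, m^{-0.315}/\sqrt{C}} for C cultures,
#' exponentiated and divided by \code{N_t}.
#'
#' @param counts mutant counts per culture.
#' @param n_total viable cells per culture (scalar or per-culture vector;
#'   averaged).
#' @return a \code{rate_estimate}: list with \code{m}, \code{rate},
#'   \code{ci_low}, \code{ci_high}, \code{n_cultures}, \code{n_total},
#'   \code{method}.
#' @export
estimate_rate <- function(counts, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  est <- estimate_m_median(counts)
  C <- length(counts)
  N_t <- mean(n_total)
  m <- est$m
  if (m > 0) {
    sigma <- 1.225 * m^(-0.315) / sqrt(C)
    ci <- exp(log(m) + c(-1.96, 1.96) * sigma) / N_t
  } else ci <- c(0, 0)
  structure(list(m = m, rate = m / N_t, ci_low = ci[1], ci_high = ci[2],
                 n_cultures = C, n_total = N_t, r_median = est$r_median,
                 method = est$method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Fluctuation rate estimate (%s, %d cultures):\n",
              x$method, x$n_cultures))
  cat(sprintf("  m = %.4g, rate = %.4g per cell [95%% CI %.4g - %.4g]\n",
              x$m, x$rate, x$ci_low, x$ci_high))
  invisible(x)
}

#' CI-overlap significance rule for two rates
#'
#' Two rates are called significantly different when their 95% confidence
#' intervals do not overlap.
#'
#' @param a,b \code{rate_estimate} objects.
#' @return TRUE iff the confidence intervals are disjoint.
#' @export
rates_differ <- function(a, b) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}

#' Estimate rates for every strain in a fluctuation-assay table
#'
#' @param x data.frame with columns \code{strain}, \code{mutant_count},
#'   \code{cells_plated} (one row per culture), or a path to such a TSV.
#' @return data.frame with one row per strain: \code{strain},
#'   \code{n_cultures}, \code{median_count}, \code{m}, \code{n_total},
#'   \code{rate}, \code{ci_low}, \code{ci_high}, \code{method}.
#' @export
fluctuation_rates <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("fluctuation table not found: ", x)
    x <- utils::read.delim(x, check.names = FALSE)
  }
  need <- c("strain", "mutant_count", "cells_plated")
  if (!all(need %in% names(x)))
    stop("fluctuation table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(x, x$strain), function(d) {
    est <- estimate_rate(d$mutant_count, d$cells_plated)
    data.frame(strain = d$strain[1], n_cultures = est$n_cultures,
               median_count = est$r_median, m = est$m, n_total = est$n_total,
               rate = est$rate, ci_low = est$ci_low, ci_high = est$ci_high,
               method = est$method, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
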