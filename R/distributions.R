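# Moment-matching of beta and gamma distributions to reported means and
# standard errors, the +/-25% range-to-SE convention, and samplers that
# degenerate gracefully to the mean when se = 0.

#' Beta shape parameters from a mean and standard error
#'
#' Method-of-moments: with `k = mean (1 - mean) / se^2 - 1`, the shapes are
#' `alpha = mean k` and `beta = (1 - mean) k`; the resulting distribution has
#' exactly the requested mean and standard deviation. `se = 0` is flagged
#' degenerate (samplers return the mean).
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean (1 - mean)`.
#' @return List with `alpha`, `beta`, `degenerate`, `mean`.
#' @export
#' @examples
#' beta_from_mean_se(0.065, 0.003)
beta_from_mean_se <- function(mean, se) {
  assert_scalar_number(se, "se", lower = 0)
  if (se == 0) {
    assert_scalar_number(mean, "mean", lower = 0, upper = 1)
    return(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE,
                mean = mean))
  }
  assert_scalar_number(mean, "mean")
  if (mean <= 0 || mean >= 1) {
    stop_foscea("beta moment matching needs mean in (0, 1)",
                "foscea_validation_error")
  }
  if (se^2 >= mean * (1 - mean)) {
    stop_foscea(
      sprintf("infeasible moments: se^2 = %g >= mean(1-mean) = %g",
              se^2, mean * (1 - mean)),
      "foscea_infeasible_moments_error")
  }
  k <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * k, beta = (1 - mean) * k, degenerate = FALSE,
       mean = mean)
}

#' Gamma shape and scale from a mean and standard error
#'
#' `shape = mean^2 / se^2`, `scale = se^2 / mean`, so that
#' `shape * scale = mean` and `shape * scale^2 = se^2`.
#'
#' @param mean Positive mean.
#' @param se Standard error (>= 0; 0 is flagged degenerate).
#' @return List with `shape`, `scale`, `degenerate`, `mean`.
#' @export
#' @examples
#' gamma_from_mean_se(100, 25)  # shape 16, scale 6.25
gamma_from_mean_se <- function(mean, se) {
  assert_scalar_number(mean, "mean", lower = .Machine$double.eps)
  assert_scalar_number(se, "se", lower = 0)
  if (se == 0) {
    return(list(shape = NA_real_, scale = NA_real_, degenerate = TRUE,
                mean = mean))
  }
  list(shape = mean^2 / se^2, scale = se^2 / mean, degenerate = FALSE,
       mean = mean)
}

#' Standard error implied by a +/- percentage variation
#'
#' Reads a stated `+/- pct` variation around a mean as the half-width of a
#' 95\% interval, so `se = pct * mean / 1.96`.
#'
#' @param mean Positive mean.
#' @param pct Fractional variation (default 0.25 for +/-25\%).
#' @return Implied standard error.
#' @export
#' @examples
#' se_from_pct_range(100)  # ~12.755
se_from_pct_range <- function(mean, pct = 0.25) {
  assert_scalar_number(mean, "mean", lower = .Machine$double.eps)
  assert_scalar_number(pct, "pct", lower = 0)
  pct * mean / 1.96
}

# Samplers: n draws with the requested moments; degenerate specs return
# the mean. Probability means of exactly 0 or 1 are treated as certain.
rbeta_mean_se <- function(n, mean, se) {
  if (se == 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  par <- beta_from_mean_se(mean, se)
  rbeta(n, par$alpha, par$beta)
}

rgamma_mean_se <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  if (mean == 0) return(rep(0, n))
  par <- gamma_from_mean_se(mean, se)
  rgamma(n, shape = par$shape, scale = par$scale)
}

# Beta rescaled to [low, high]: moments are mapped to the unit interval,
# matched there, and draws mapped back. Used for the discount rate, stated
# as beta with a 0%-5% range.
rbeta_scaled <- function(n, mean, se, low, high) {
  if (high <= low) {
    stop_foscea("`high` must exceed `low` for a scaled beta",
                "foscea_validation_error")
  }
  width <- high - low
  low + width * rbeta_mean_se(n, (mean - low) / width, se / width)
}
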