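# internal helpers

stop_domain <- function(msg, ...) abort(msg, class = "phenodelta_domain_error", ...)
stop_missing_marker <- function(marker) {
  abort(paste0("missing required marker: ", marker),
        class = "phenodelta_missing_marker", marker = marker)
}
stop_singular <- function(column) {
  abort(paste0("design matrix is rank deficient; offending column: ", column),
        class = "phenodelta_singular_error", column = column)
}

# truncated-normal mean for parent N(mu, sd) truncated to (low, high)
truncnorm_mean <- function(mu, sd, low, high) {
  a <- (low - mu) / sd
  b <- (high - mu) / sd
  denom <- pnorm(b) - pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / denom
}

# parent location whose truncated-normal mean equals `target`
truncnorm_parent_mean <- function(target, sd, low, high) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, low, high) - target,
                 interval = c(target - 3 * sd, target + 3 * sd),
                 tol = 1e-10)$root
}

#' Draw from a truncated normal distribution by inverse-CDF sampling
#'
#' @param n number of draws
#' @param mean,sd location and scale of the parent normal
#' @param low,high truncation bounds
#' @return numeric vector of length `n` in `[low, high]`
#' @keywords internal
rtruncnorm <- function(n, mean, sd, low = -Inf, high = Inf) {
  plo <- pnorm(low, mean, sd)
  phi <- pnorm(high, mean, sd)
  u <- runif(n, plo, phi)
  pmin(pmax(qnorm(u, mean, sd), low), high)
}

# round to the printed precision used in the tables (half away from zero,
# matching how percentages are printed)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
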