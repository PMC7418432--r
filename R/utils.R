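`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Currency-style rounding: .005 always rounds up in magnitude, unlike
#' [base::round()] which rounds to even (and is floating-point sensitive,
#' e.g. `round(19.41 * 59.5, 2)` gives 1154.89). A small relative epsilon
#' absorbs binary representation error in products of 2 d.p. inputs.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' round2(19.41 * 59.5) # 1154.90
#' @export
round2 <- function(x, digits = 2) {
  p <- 10^digits
  xp <- abs(x) * p
  eps <- .Machine$double.eps^0.5 * pmax(1, xp)
  sign(x) * floor(xp + 0.5 + eps) / p
}

# Fixed seed fan-out so the simulation, missingness, imputation and bootstrap
# stages draw from independent, independently reproducible streams.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, missing = 211, impute = 307, bootstrap = 401,
               scenario = 503, states = 601)
  if (!stage %in% names(offsets)) stopf("unknown seed stage '%s'", stage)
  as.integer((as.numeric(seed) %% 65011 + 1) * 32261 %% 2147483629 +
               offsets[[stage]])
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Mean of min(max(X, lo), hi) for X ~ N(mu, sigma): two-sided censoring.
# Used by the synthetic generator to record analytic utility means.
cens_norm_mean <- function(mu, sigma, lo, hi) {
  if (sigma <= 0) return(clip(mu, lo, hi))
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) - sigma * (dnorm(b) - dnorm(a))
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("configuration error: %s must lie in [0, 1]", what)
  invisible(x)
}
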