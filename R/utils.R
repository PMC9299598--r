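# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code under a fixed RNG seed without disturbing the caller's stream
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Stable 31-bit hash of a string, for keyed random-number substreams
#'
#' Polynomial rolling hash modulo 2^31 - 1. Used to give every forest type its
#' own reproducible stream so that adding or removing other strata never
#' changes the draws of an existing one.
#' @noRd
string_seed <- function(key) {
  codes <- utf8ToInt(key)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Mean of a Normal(mu, sd) censored from below at zero
#'
#' E[max(0, X)] = mu * pnorm(mu/sd) + sd * dnorm(mu/sd). Reduces to max(0, mu)
#' as sd -> 0. Used for closed-form generator ground truth.
#' @noRd
censored_normal_mean <- function(mu, sd) {
  n <- max(length(mu), length(sd))
  mu <- rep_len(mu, n)
  sd <- rep_len(sd, n)
  out <- pmax(0, mu)
  pos <- sd > 0
  out[pos] <- mu[pos] * pnorm(mu[pos] / sd[pos]) +
    sd[pos] * dnorm(mu[pos] / sd[pos])
  out
}

#' Weighted (class-support) F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall), averaged with weights
#' proportional to the class support in `truth`. Classes never predicted get
#' precision 0 by convention; classes with zero support are ignored.
#' @noRd
weighted_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Coefficient of determination of y against x (identity-line-free OLS R^2)
#' @noRd
r_squared <- function(observed, predicted) {
  if (length(observed) < 2 || stats::var(observed) == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
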