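# Extract a chains-by-draws matrix from a fit object or pass a matrix through
draws_matrix <- function(x, parameter = NULL) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && !is.null(x$draws)) {
    if (is.null(parameter)) stop_fmt("`parameter` is required for fit objects")
    m <- x$draws[[parameter]]
    if (is.null(m)) stop_fmt("unknown parameter '%s'", parameter)
    return(m)
  }
  stop_fmt("expected a chains-by-draws matrix or a fit object with $draws")
}

#' Split-chain Gelman-Rubin convergence diagnostic (R-hat)
#'
#' Each chain is split in half before comparing between- and within-chain
#' variance, so slow drift within single chains is also detected. Values
#' near 1 indicate mixing; runs in this package warn above 1.01. When every
#' chain is the same constant, 1.0 is returned by the zero-variance
#' convention.
#'
#' @param x a chains-by-draws matrix, or a fit object with a `draws` list.
#' @param parameter parameter name when `x` is a fit object.
#' @return the potential scale reduction factor (unitless, >= 1 up to
#'   floating tolerance).
#' @export
rhat <- function(x, parameter = NULL) {
  m <- draws_matrix(x, parameter)
  if (nrow(m) < 2L) stop_fmt("rhat requires >= 2 chains")
  if (ncol(m) < 4L) stop_fmt("rhat requires >= 4 draws per chain")
  half <- ncol(m) %/% 2L
  split <- rbind(m[, seq_len(half), drop = FALSE],
                 m[, (ncol(m) - half + 1L):ncol(m), drop = FALSE])
  n <- ncol(split)
  w <- mean(apply(split, 1L, stats::var))
  b <- n * stats::var(rowMeans(split))
  if (w == 0) return(if (b == 0) 1.0 else Inf)
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based effective sample size with Geyer's initial positive
#' (and monotone) sequence truncation: lagged autocovariances are averaged
#' across chains, paired into successive sums, and summation stops at the
#' first non-positive pair. Degenerate (zero-variance) chains return the
#' floor value 1 with a warning.
#'
#' @inheritParams rhat
#' @return estimated number of effectively independent draws, capped at the
#'   total draw count and floored at 1.
#' @export
ess <- function(x, parameter = NULL) {
  m <- draws_matrix(x, parameter)
  if (nrow(m) < 1L) stop_fmt("ess requires >= 1 chain")
  if (ncol(m) < 4L) stop_fmt("ess requires >= 4 draws per chain")
  n_chain <- nrow(m); n <- ncol(m)
  total <- n_chain * n
  mu <- rowMeans(m)
  centered <- m - mu
  chain_var <- rowSums(centered^2) / (n - 1)
  w <- mean(chain_var)
  var_plus <- (n - 1) / n * w
  if (n_chain > 1L) var_plus <- var_plus + stats::var(mu)
  if (var_plus == 0 || w == 0) {
    warn_fmt("zero-variance draws: effective sample size floored at 1")
    return(1)
  }
  autocov <- function(lag) {
    mean(vapply(seq_len(n_chain), function(c) {
      sum(centered[c, seq_len(n - lag)] * centered[c, (1L + lag):n]) / n
    }, numeric(1)))
  }
  # rho_0 and rho_1 seed the first Geyer pair
  rho <- function(lag) 1 - (w - autocov(lag)) / var_plus
  # Geyer: tau = -1 + 2 * sum of positive monotone pair sums P_k
  pair_prev <- rho(0) + rho(1)
  if (pair_prev <= 0) return(total)
  tau <- 2 * pair_prev - 1
  lag <- 2L
  while (lag + 1L < n) {
    pair <- rho(lag) + rho(lag + 1L)
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, pair_prev)  # enforce monotone decrease
    tau <- tau + 2 * pair
    pair_prev <- pair
    lag <- lag + 2L
  }
  max(1, min(total, total / tau))
}

#' Equal-tailed posterior credible interval
#'
#' Quantile interval over draws pooled across chains.
#'
#' @inheritParams rhat
#' @param level interval mass, in (0, 1); default 0.95.
#' @return named numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(x, parameter = NULL, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_fmt("`level` must be in (0, 1)")
  }
  m <- draws_matrix(x, parameter)
  q <- stats::quantile(as.vector(m), probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Convergence diagnostics for every parameter of a fit
#'
#' @param fit a fit object with a `draws` list of chains-by-draws matrices.
#' @return data frame with columns `parameter`, `rhat`, `ess`.
#' @export
convergence_report <- function(fit) {
  pars <- names(fit$draws)
  data.frame(parameter = pars,
             rhat = vapply(pars, function(p) rhat(fit, p), numeric(1)),
             ess = vapply(pars, function(p) ess(fit, p), numeric(1)),
             row.names = NULL)
}
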