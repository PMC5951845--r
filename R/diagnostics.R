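#' Effective sample size of an MCMC series
#'
#' Initial-positive-sequence estimator: the integrated autocorrelation time
#' is `-1 + 2 * sum(Gamma_m)` over successive autocorrelation pairs
#' `Gamma_m = rho(2m) + rho(2m+1)`, truncated at the first non-positive pair;
#' ESS = n / tau, capped at n.
#'
#' @param trace_series Numeric vector (length >= 10) of posterior draws, or
#'   an `mcmc_trace` together with `parameter`.
#' @param parameter Column name when `trace_series` is an `mcmc_trace`.
#' @return Effective sample size (single number, `<= length(series)`).
#' @export
effective_sample_size <- function(trace_series, parameter = NULL) {
  if (inherits(trace_series, "mcmc_trace"))
    trace_series <- trace_series$samples[[parameter %||% trace_series$rate_names[1]]]
  x <- as.numeric(trace_series)
  n <- length(x)
  if (n < 10L)
    stop_nestevo("series too short for an ESS estimate (need >= 10)",
                 "nestevo_invalid_parameter")
  if (var(x) == 0)
    stop_nestevo("zero-variance series: ESS undefined", "nestevo_undefined_ess")
  rho <- as.numeric(acf(x, lag.max = n - 1L, plot = FALSE,
                        demean = TRUE)$acf)
  n_pairs <- floor(length(rho) / 2)
  tau <- -1
  for (m in seq_len(n_pairs)) {
    g <- rho[2 * m - 1] + rho[2 * m]  # rho at lags 2(m-1) and 2m-1
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  min(n, n / max(tau, 1e-12))
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Standard split R-hat: each chain is halved, the between- and within-half
#' variances are compared, and values near 1 indicate convergence (the
#' package's programmatic gate is R-hat < 1.05 together with ESS > 500).
#'
#' @param multi_chain_trace An `mcmc_trace` with at least two chains, or a
#'   list/matrix of chains (columns = chains).
#' @param parameter Column name when given an `mcmc_trace` (default: all
#'   sampled rates).
#' @return Named numeric vector of R-hat values (one per parameter).
#' @export
convergence_diagnostic <- function(multi_chain_trace, parameter = NULL) {
  if (inherits(multi_chain_trace, "mcmc_trace")) {
    tr <- multi_chain_trace
    pars <- parameter %||% tr$rate_names
    chains <- split(tr$samples, tr$samples$chain)
    if (length(chains) < 2L)
      stop_nestevo("need >= 2 chains for R-hat", "nestevo_insufficient_chains")
    out <- vapply(pars, function(p)
      split_rhat(vapply(chains, function(cc) cc[[p]],
                        numeric(nrow(chains[[1]])))), numeric(1))
    return(setNames(out, pars))
  }
  m <- if (is.list(multi_chain_trace)) {
    len <- unique(lengths(multi_chain_trace))
    if (length(len) != 1L)
      stop_nestevo("chains must have equal length", "nestevo_input_error")
    do.call(cbind, multi_chain_trace)
  } else as.matrix(multi_chain_trace)
  if (ncol(m) < 2L)
    stop_nestevo("need >= 2 chains for R-hat", "nestevo_insufficient_chains")
  split_rhat(m)
}

split_rhat <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  halves <- cbind(m[seq_len(half), , drop = FALSE],
                  m[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(halves, 2, var))
  if (!is.finite(W) || W == 0)
    stop_nestevo("zero within-chain variance: R-hat undefined",
                 "nestevo_undefined_rhat")
  B <- half * var(colMeans(halves))
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}
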