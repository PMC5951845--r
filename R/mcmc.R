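#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings samplers. The `"desk"` profile is
#' sized for interactive work and the test suite; the `"paper"` profile
#' mirrors a full-scale analysis (20 million iterations, 2 million burn-in,
#' thinning every 10,000, three chains) and the `"paper_discrete"` profile a
#' full-scale correlated-evolution run (200M / 20M / 10,000).
#'
#' @param n_iter Total iterations per chain.
#' @param burn_in Iterations discarded (and used for proposal tuning);
#'   must be `< n_iter`.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param prior_mean Mean of the exponential prior on each rate (default 0.1).
#' @param target_accept_low,target_accept_high Acceptance band the proposal
#'   width is tuned into during burn-in (defaults 0.2 and 0.4).
#' @param n_chains Number of independent chains.
#' @param seed Optional integer seed (chain `i` uses a sub-seed derived from it).
#' @param profile Optional profile name; overrides the iteration counts.
#' @return An object of class `mcmc_config`.
#' @examples
#' mcmc_config(profile = "desk", seed = 1)
#' @export
mcmc_config <- function(n_iter = 20000L, burn_in = 5000L, thin = 30L,
                        prior_mean = 0.1, target_accept_low = 0.2,
                        target_accept_high = 0.4, n_chains = 3L, seed = NULL,
                        profile = NULL) {
  if (!is.null(profile)) {
    p <- match.arg(profile, c("desk", "paper", "paper_discrete"))
    if (p == "paper") {
      n_iter <- 22e6; burn_in <- 2e6; thin <- 10000L
    } else if (p == "paper_discrete") {
      n_iter <- 220e6; burn_in <- 20e6; thin <- 10000L
    }
  }
  if (burn_in >= n_iter)
    stop_nestevo("burn_in must be < n_iter", "nestevo_invalid_parameter")
  if (!(target_accept_low > 0 && target_accept_low < target_accept_high &&
        target_accept_high < 1))
    stop_nestevo("need 0 < target_accept_low < target_accept_high < 1",
                 "nestevo_invalid_parameter")
  if (prior_mean <= 0)
    stop_nestevo("prior_mean must be > 0", "nestevo_invalid_parameter")
  if (thin < 1 || (n_iter - burn_in) %% thin != 0)
    stop_nestevo("thin must divide n_iter - burn_in", "nestevo_invalid_parameter")
  structure(list(n_iter = as.numeric(n_iter), burn_in = as.numeric(burn_in),
                 thin = as.integer(thin), prior_mean = prior_mean,
                 target_accept_low = target_accept_low,
                 target_accept_high = target_accept_high,
                 n_chains = as.integer(n_chains), seed = seed),
            class = "mcmc_config")
}

# Shared Metropolis-Hastings engine over log-rates, with the tree index as an
# additional sampled parameter (uniform proposal over the tree set).
#
# `loglik_fun(rates, tree_i)` returns the log-likelihood. Proposals are
# sliding windows on the log scale, tuned multiplicatively during burn-in to
# the configured acceptance band and frozen afterwards.
run_mh_chains <- function(loglik_fun, n_rates, n_trees, config, rate_names) {
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    with_seed(derive_seed(config$seed, ch),
              run_mh_one(loglik_fun, n_rates, n_trees, config, ch))
  })
  samples <- do.call(rbind, lapply(chains, `[[`, "samples"))
  colnames(samples) <- c("chain", "iteration", rate_names, "log_lik", "tree_index")
  trace <- as.data.frame(samples)
  structure(list(samples = trace,
                 rate_names = rate_names,
                 acceptance = vapply(chains, `[[`, numeric(1), "acceptance"),
                 tuning = lapply(chains, `[[`, "tuning"),
                 window = lapply(chains, `[[`, "window"),
                 config = config),
            class = "mcmc_trace")
}

run_mh_one <- function(loglik_fun, n_rates, n_trees, config, chain_id) {
  n_iter <- config$n_iter
  burn_in <- config$burn_in
  thin <- config$thin
  prior_rate <- 1 / config$prior_mean
  # start from the prior mean; window of 1 log-unit is a neutral start
  x <- rep(config$prior_mean, n_rates)
  w <- rep(1, n_rates)
  tree_i <- 1L
  ll <- loglik_fun(x, tree_i)
  lp <- ll + sum(dexp(x, prior_rate, log = TRUE))
  n_keep <- (n_iter - burn_in) / thin
  out <- matrix(NA_real_, n_keep, 4L + n_rates - 1L + 1L)
  out_row <- 0L
  acc_tune <- 0L; n_tune <- 0L       # window for tuning decisions
  acc_post <- 0L; n_post <- 0L       # post-burn-in acceptance bookkeeping
  tune_interval <- 100L
  tuning_log <- list()
  for (iter in seq_len(n_iter)) {
    j <- if (n_rates == 1L) 1L else sample.int(n_rates, 1L)
    prop <- x
    prop[j] <- exp(log(x[j]) + runif(1, -w[j], w[j]))
    ll_p <- loglik_fun(prop, tree_i)
    lp_p <- ll_p + sum(dexp(prop, prior_rate, log = TRUE))
    # symmetric proposal in log space: Jacobian contributes x'_j / x_j
    log_alpha <- (lp_p - lp) + (log(prop[j]) - log(x[j]))
    accepted <- is.finite(log_alpha) && log(runif(1)) < log_alpha
    if (accepted) {
      x <- prop; ll <- ll_p; lp <- lp_p
    }
    if (iter <= burn_in) {
      n_tune <- n_tune + 1L
      acc_tune <- acc_tune + accepted
      if (n_tune == tune_interval) {
        rate <- acc_tune / n_tune
        if (rate > config$target_accept_high) w <- w * 1.4
        else if (rate < config$target_accept_low) w <- w / 1.4
        tuning_log[[length(tuning_log) + 1L]] <-
          c(iteration = iter, acceptance = rate, window = w[1])
        acc_tune <- 0L; n_tune <- 0L
      }
    } else {
      n_post <- n_post + 1L
      acc_post <- acc_post + accepted
    }
    if (n_trees > 1L) {
      tree_p <- sample.int(n_trees, 1L)
      if (tree_p != tree_i) {
        ll_t <- loglik_fun(x, tree_p)
        if (is.finite(ll_t) && log(runif(1)) < (ll_t - ll)) {
          tree_i <- tree_p
          lp <- lp + (ll_t - ll)
          ll <- ll_t
        }
      }
    }
    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      out_row <- out_row + 1L
      out[out_row, ] <- c(chain_id, iter, x, ll, tree_i)
    }
  }
  acceptance <- if (n_post > 0L) acc_post / n_post else NA_real_
  if (is.finite(acceptance) &&
      (acceptance < config$target_accept_low ||
       acceptance > config$target_accept_high))
    warning(sprintf(
      "chain %d: post-burn-in acceptance %.2f outside the [%.2f, %.2f] band",
      chain_id, acceptance, config$target_accept_low, config$target_accept_high),
      call. = FALSE)
  list(samples = out, acceptance = acceptance,
       tuning = do.call(rbind, tuning_log), window = w)
}

#' Bayesian MCMC for an Mk model over a set of trees
#'
#' Metropolis-Hastings sampling of the transition rate(s) of a k-state Mk
#' model, with independent exponential priors (mean `prior_mean`) on each
#' rate. Tree uncertainty is integrated over by treating the tree index as a
#' sampled parameter with a uniform proposal over the tree set. Proposal
#' windows are auto-adjusted during burn-in into the configured acceptance
#' band (by default 20--40%) and frozen afterwards.
#'
#' @param tree_set A `multiPhylo` (or list) of trees sharing one tip set, or
#'   a single `phylo`.
#' @param tip_state_sets Named list of state sets (see
#'   [tree_log_likelihood()]).
#' @param model_spec An [mk_model()]; its rates are the parameters sampled.
#' @param config An [mcmc_config()].
#' @return An object of class `mcmc_trace`: `$samples` holds one row per
#'   retained sample (chain, iteration, rates, log-likelihood, tree index);
#'   `$acceptance` the post-burn-in acceptance fraction per chain.
#' @export
mcmc_sample <- function(tree_set, tip_state_sets, model_spec, config = mcmc_config()) {
  stopifnot(inherits(model_spec, "mk_model"), inherits(config, "mcmc_config"))
  tree_set <- as_tree_set(tree_set)
  preps <- prep_tree_set(tree_set, tip_state_sets, model_spec$states)
  er <- model_spec$rate_model == "ER"
  k <- model_spec$k
  root_prior <- model_spec$root_prior
  n_rates <- if (er) 1L else k * (k - 1L)
  rate_names <- if (er) "rate" else sprintf("rate_%d", seq_len(n_rates))
  loglik_fun <- function(rates, tree_i) {
    pp <- preps[[tree_i]]
    Q <- if (er) matrix(0, k, k) else
      mk_generator(mk_model(model_spec$states, "ARD", rates))
    C_mk_loglik(pp$edge, pp$elen, pp$tipL, pp$n_node, Q, root_prior,
                er, if (er) rates[1] else 0)
  }
  trace <- run_mh_chains(loglik_fun, n_rates, length(preps), config, rate_names)
  trace$model <- model_spec
  trace$kind <- "mk"
  trace
}

as_tree_set <- function(tree_set) {
  if (inherits(tree_set, "phylo")) tree_set <- list(tree_set)
  if (!length(tree_set)) stop_nestevo("empty tree set", "nestevo_input_error")
  labs <- tree_set[[1]]$tip.label
  for (tr in tree_set) {
    if (!inherits(tr, "phylo")) stop_nestevo("not a phylo tree", "nestevo_input_error")
    if (!setequal(tr$tip.label, labs))
      stop_nestevo("trees do not share one tip set", "nestevo_input_error")
  }
  tree_set
}

prep_tree_set <- function(tree_set, tip_state_sets, states) {
  lapply(tree_set, prep_tree, tip_state_sets = tip_state_sets, states = states)
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("MCMC trace (%s): %d samples, %d chain(s)\n", x$kind,
              nrow(x$samples), length(unique(x$samples$chain))))
  for (rn in x$rate_names)
    cat(sprintf("  %s: posterior mean %.4g\n", rn, mean(x$samples[[rn]])))
  cat("  post-burn-in acceptance:",
      paste(sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary of a trace
#'
#' Posterior mean and central credible interval for each sampled rate,
#' averaged across chains.
#'
#' @param trace An `mcmc_trace`.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame with one row per rate.
#' @export
posterior_summary <- function(trace, prob = 0.95) {
  stopifnot(inherits(trace, "mcmc_trace"))
  a <- (1 - prob) / 2
  do.call(rbind, lapply(trace$rate_names, function(rn) {
    x <- trace$samples[[rn]]
    data.frame(rate = rn, mean = mean(x), median = median(x),
               lower = unname(quantile(x, a)), upper = unname(quantile(x, 1 - a)))
  }))
}
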