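#' Pagel's model of correlated evolution of two binary traits
#'
#' The joint state of two binary traits A and B evolves over the four-state
#' space 1=00, 2=01, 3=10, 4=11 (A is the first digit). The *independent*
#' model has four free rates (each trait's gain and loss, unaffected by the
#' other trait); the *dependent* model has eight context-dependent rates.
#' Simultaneous double transitions (00<->11, 01<->10) have rate zero in both.
#'
#' @param kind `"independent"` or `"dependent"`.
#' @param rates Four rates (`a_gain, a_loss, b_gain, b_loss`) or eight rates
#'   (`q12, q13, q21, q24, q31, q34, q42, q43`); `NA` for a model to be
#'   fitted.
#' @return An object of class `pagel_model`.
#' @export
pagel_model <- function(kind = c("independent", "dependent"), rates = NA_real_) {
  kind <- match.arg(kind)
  n_rates <- if (kind == "independent") 4L else 8L
  if (all(is.na(rates))) rates <- rep(NA_real_, n_rates)
  if (length(rates) != n_rates || any(rates < 0, na.rm = TRUE))
    stop_nestevo(sprintf("%s model needs %d non-negative rates", kind, n_rates),
                 "nestevo_invalid_parameter")
  structure(list(kind = kind, rates = as.numeric(rates),
                 states = c("00", "01", "10", "11"),
                 rate_names = pagel_rate_names(kind)),
            class = "pagel_model")
}

pagel_rate_names <- function(kind) {
  if (kind == "independent") c("a_gain", "a_loss", "b_gain", "b_loss")
  else c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
}

# 4x4 generator over joint states 00,01,10,11; double transitions are 0.
pagel_generator <- function(rates, kind) {
  if (kind == "independent") {
    a_gain <- rates[1]; a_loss <- rates[2]
    b_gain <- rates[3]; b_loss <- rates[4]
    rates <- c(q12 = b_gain, q13 = a_gain, q21 = b_loss, q24 = a_gain,
               q31 = a_loss, q34 = b_gain, q42 = a_loss, q43 = b_loss)
  }
  Q <- matrix(0, 4, 4, dimnames = list(c("00", "01", "10", "11"),
                                       c("00", "01", "10", "11")))
  Q[1, 2] <- rates[1]; Q[1, 3] <- rates[2]
  Q[2, 1] <- rates[3]; Q[2, 4] <- rates[4]
  Q[3, 1] <- rates[5]; Q[3, 4] <- rates[6]
  Q[4, 2] <- rates[7]; Q[4, 3] <- rates[8]
  diag(Q) <- -rowSums(Q)
  Q
}

# Joint-state indicator matrix (4 x Ntip) from a two-column 0/1/NA matrix.
pagel_tip_partials <- function(tree, pair) {
  labs <- tree$tip.label
  absent <- setdiff(labs, rownames(pair))
  if (length(absent))
    stop_nestevo(paste("tips absent from the trait data:",
                       paste(absent, collapse = ", ")), "nestevo_missing_taxon")
  L <- matrix(0, 4, length(labs))
  a <- pair[labs, 1]
  b <- pair[labs, 2]
  for (i in seq_along(labs)) {
    ok_a <- if (is.na(a[i])) c(0L, 1L) else a[i]
    ok_b <- if (is.na(b[i])) c(0L, 1L) else b[i]
    for (ai in ok_a) for (bi in ok_b) L[1L + 2L * ai + bi, i] <- 1
  }
  L
}

#' Joint log-likelihood of two binary traits under a Pagel model
#'
#' The four-state pruning likelihood of the joint character (A,B) under an
#' independent or dependent model with the given rates; tips with one trait
#' missing enter as indicators over the compatible joint states. With
#' context-free rates this factorizes into the product of the two
#' single-trait likelihoods.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param binary_pair_data Two-column 0/1/`NA` matrix with family row names.
#' @param model A [pagel_model()] with rates set.
#' @return The log-likelihood.
#' @export
pagel_log_likelihood <- function(tree, binary_pair_data, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "pagel_model"))
  if (anyNA(model$rates))
    stop_nestevo("model rates are unset", "nestevo_invalid_parameter")
  po <- ape::reorder.phylo(tree, "postorder")
  pair <- as.matrix(binary_pair_data)
  C_mk_loglik(po$edge, po$edge.length, pagel_tip_partials(po, pair),
              length(po$tip.label) + po$Nnode,
              pagel_generator(model$rates, model$kind), rep(0.25, 4), FALSE, 0)
}

#' Fit a Pagel independent or dependent model by MCMC over a tree set
#'
#' Metropolis-Hastings sampling of the four (independent) or eight
#' (dependent) transition rates under independent exponential priors, with
#' the joint four-state pruning likelihood (double transitions fixed at rate
#' zero) and the tree index sampled uniformly over the tree set, as in
#' [mcmc_sample()].
#'
#' @param tree_set A `multiPhylo` (or single `phylo`) sharing one tip set.
#' @param binary_pair_data Two-column matrix (columns = traits A and B) of
#'   0/1/`NA` values with family row names, e.g. from [binary_pair()].
#' @param kind `"independent"` or `"dependent"`.
#' @param config An [mcmc_config()].
#' @return An `mcmc_trace` with `kind = "pagel_independent"` or
#'   `"pagel_dependent"`.
#' @export
fit_pagel_model <- function(tree_set, binary_pair_data,
                            kind = c("independent", "dependent"),
                            config = mcmc_config()) {
  kind <- match.arg(kind)
  tree_set <- as_tree_set(tree_set)
  pair <- as.matrix(binary_pair_data)
  if (ncol(pair) != 2L || is.null(rownames(pair)))
    stop_nestevo("binary_pair_data must be a 2-column matrix with family row names",
                 "nestevo_input_error")
  for (j in 1:2) {
    obs <- unique(pair[!is.na(pair[, j]), j])
    if (length(obs) < 2L)
      warning(sprintf("trait %s has %d observed state(s): model unidentifiable",
                      c("A", "B")[j], length(obs)), call. = FALSE)
  }
  preps <- lapply(tree_set, function(tr) {
    po <- ape::reorder.phylo(tr, "postorder")
    list(edge = po$edge, elen = po$edge.length,
         tipL = pagel_tip_partials(po, pair),
         n_node = length(po$tip.label) + po$Nnode)
  })
  n_rates <- if (kind == "independent") 4L else 8L
  root_prior <- rep(0.25, 4)
  loglik_fun <- function(rates, tree_i) {
    pp <- preps[[tree_i]]
    C_mk_loglik(pp$edge, pp$elen, pp$tipL, pp$n_node,
                pagel_generator(rates, kind), root_prior, FALSE, 0)
  }
  trace <- run_mh_chains(loglik_fun, n_rates, length(preps), config,
                         pagel_rate_names(kind))
  trace$model <- pagel_model(kind)
  trace$kind <- paste0("pagel_", kind)
  trace
}

#' Harmonic-mean estimate of the log marginal likelihood
#'
#' The marginal likelihood is estimated as the harmonic mean of the sampled
#' likelihoods, computed stably in log space:
#' `lnML = log(n) - logsumexp(-loglik)`. The estimator is simple but
#' high-variance; it never exceeds the maximum sampled log-likelihood.
#'
#' @param trace An `mcmc_trace`, or a numeric vector of sampled
#'   log-likelihoods.
#' @return The estimated log marginal likelihood.
#' @export
log_marginal_harmonic_mean <- function(trace) {
  ll <- if (inherits(trace, "mcmc_trace")) trace$samples$log_lik
        else as.numeric(trace)
  if (!length(ll))
    stop_nestevo("empty trace: cannot estimate a marginal likelihood",
                 "nestevo_insufficient_samples")
  if (length(ll) < 100L)
    warning(sprintf("only %d retained samples; the harmonic-mean estimate will be unstable",
                    length(ll)), call. = FALSE)
  log(length(ll)) - logsumexp(-ll)
}

#' Bayes factor between dependent and independent models
#'
#' `BF = 2 * (lnML_dependent - lnML_independent)`, with `BF > 5` read as
#' strong support for the dependent model.
#'
#' @param dep_result,indep_result Log marginal likelihoods (numbers) or
#'   `mcmc_trace` objects (the harmonic-mean estimate is taken).
#' @return A `bayes_factor_result` with elements `lnml_dep`, `lnml_indep`,
#'   `bf` and `support_call` (`"strong"` or `"weak"`).
#' @export
bayes_factor <- function(dep_result, indep_result) {
  lnml <- function(x) if (inherits(x, "mcmc_trace")) log_marginal_harmonic_mean(x)
                      else as.numeric(x)
  d <- lnml(dep_result)
  i <- lnml(indep_result)
  if (!is.finite(d) || !is.finite(i))
    stop_nestevo("non-finite marginal likelihood", "nestevo_propagation_error")
  bf <- 2 * (d - i)
  structure(list(lnml_dep = d, lnml_indep = i, bf = bf,
                 support_call = if (bf > 5) "strong" else "weak"),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("BF = %.2f (%s support for the dependent model)\n  lnML dep = %.3f, lnML indep = %.3f\n",
              x$bf, x$support_call, x$lnml_dep, x$lnml_indep))
  invisible(x)
}

#' Directionality of contingent transition rates
#'
#' Posterior summaries of the eight contextual rates of a dependent-model
#' trace, plus posterior probabilities of the orderings that express
#' directionality: whether B's gain is contingent on A (`q34 > q12`),
#' whether A's gain is contingent on B (`q24 > q13`), and whether B's change
#' in the derived background of A is faster than A's change in the derived
#' background of B (`q34 > q24`), i.e. whether A drives B.
#'
#' @param dep_trace An `mcmc_trace` from a dependent fit.
#' @return List with `rates` (posterior summary data frame) and `orderings`
#'   (named probabilities).
#' @export
transition_asymmetry <- function(dep_trace) {
  stopifnot(inherits(dep_trace, "mcmc_trace"))
  if (!identical(dep_trace$kind, "pagel_dependent"))
    stop_nestevo("transition_asymmetry needs a dependent-model trace",
                 "nestevo_wrong_model")
  s <- dep_trace$samples
  list(rates = posterior_summary(dep_trace),
       orderings = c(
         p_b_gain_contingent_on_a = mean(s$q34 > s$q12),
         p_a_gain_contingent_on_b = mean(s$q24 > s$q13),
         p_a_drives_b = mean(s$q34 > s$q24)))
}

#' Assemble a two-trait 0/1 matrix from binary recodings
#'
#' @param a,b Named label vectors from [binary_recode()] (`NA` = missing),
#'   over the same families.
#' @param derived_a,derived_b The labels coded as 1 in each trait.
#' @return Two-column 0/1/`NA` matrix with family row names, ready for
#'   [fit_pagel_model()].
#' @export
binary_pair <- function(a, b, derived_a, derived_b) {
  fams <- names(a)
  if (!setequal(fams, names(b)))
    stop_nestevo("the two recodings cover different families", "nestevo_input_error")
  out <- cbind(A = ifelse(is.na(a), NA_integer_, as.integer(a == derived_a)),
               B = ifelse(is.na(b[fams]), NA_integer_,
                          as.integer(b[fams] == derived_b)))
  rownames(out) <- fams
  out
}
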