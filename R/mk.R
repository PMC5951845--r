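#' Construct a k-state Markov (Mk) model of discrete character evolution
#'
#' An Mk model is a continuous-time Markov chain over `k` character states.
#' Under the equal-rates (`"ER"`) variant every transition shares one rate
#' `q`; the all-rates-different (`"ARD"`) variant has `k*(k-1)` free
#' off-diagonal rates. Rates are in expected transitions per unit branch
#' length.
#'
#' @param states Character vector of state labels (length k >= 2), or a
#'   single integer k (labels `s1..sk`).
#' @param rate_model `"ER"` or `"ARD"`.
#' @param rates Single rate `q` (ER) or `k*(k-1)` off-diagonal rates filling
#'   the generator row by row (ARD). May be `NA` for a model to be fitted.
#' @param root_prior Probability vector of length k (default uniform).
#' @return An object of class `mk_model`.
#' @examples
#' mk_model(4, "ER", rates = 0.1)
#' @export
mk_model <- function(states, rate_model = c("ER", "ARD"), rates = NA_real_,
                     root_prior = NULL) {
  rate_model <- match.arg(rate_model)
  if (is.numeric(states) && length(states) == 1L)
    states <- sprintf("s%d", seq_len(states))
  states <- as.character(states)
  k <- length(states)
  if (k < 2 || anyDuplicated(states))
    stop_nestevo("need >= 2 unique states", "nestevo_invalid_parameter")
  n_rates <- if (rate_model == "ER") 1L else k * (k - 1L)
  if (!all(is.na(rates))) {
    if (length(rates) != n_rates || any(rates < 0, na.rm = TRUE))
      stop_nestevo(sprintf("%s model with k=%d needs %d non-negative rate(s)",
                           rate_model, k, n_rates), "nestevo_invalid_parameter")
  } else {
    rates <- rep(NA_real_, n_rates)
  }
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  if (length(root_prior) != k || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8)
    stop_nestevo("root_prior must be a length-k probability vector",
                 "nestevo_invalid_parameter")
  structure(list(states = states, k = k, rate_model = rate_model,
                 rates = as.numeric(rates), root_prior = root_prior),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Mk model (%s), %d states: %s\n", x$rate_model, x$k,
              paste(x$states, collapse = ", ")))
  if (all(is.na(x$rates))) cat("  rates: unset\n")
  else cat("  rates:", format(x$rates, digits = 4), "\n")
  invisible(x)
}

# Generator matrix Q of an mk_model (rows sum to zero).
mk_generator <- function(model) {
  k <- model$k
  Q <- matrix(0, k, k)
  if (model$rate_model == "ER") {
    Q[] <- model$rates
  } else {
    Q[row(Q) != col(Q)] <- 0  # fill row-wise below
    idx <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- model$rates[idx]
      idx <- idx + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability matrix of an Mk model
#'
#' For equal-rates models the closed form is used:
#' `P_same(t) = 1/k + (k-1)/k * exp(-k q t)` and
#' `P_diff(t) = (1 - exp(-k q t))/k`; all-rates-different models use the
#' matrix exponential of the generator.
#'
#' @param model An [mk_model()] with rates set.
#' @param t Branch length (>= 0).
#' @return A `k x k` stochastic matrix (rows sum to 1).
#' @examples
#' transition_probability(mk_model(4, "ER", rates = 0.1), 1)
#' @export
transition_probability <- function(model, t) {
  stopifnot(inherits(model, "mk_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop_nestevo("t must be a non-negative number", "nestevo_invalid_parameter")
  if (anyNA(model$rates))
    stop_nestevo("model rates are unset", "nestevo_invalid_parameter")
  k <- model$k
  if (model$rate_model == "ER") {
    et <- exp(-k * model$rates * t)
    P <- matrix((1 - et) / k, k, k)
    diag(P) <- 1 / k + (k - 1) / k * et
  } else {
    P <- C_expm_Q(mk_generator(model), t)
  }
  dimnames(P) <- list(model$states, model$states)
  P
}

# Tip partial-likelihood matrix (k x Ntip) in the tree's tip order.
# A polymorphic tip has a 1 on each observed state; a missing tip (empty set
# or NA) is all ones. `tip_state_sets` is a named list of label vectors or a
# named character vector of single states.
tip_partials <- function(tree, tip_state_sets, states) {
  if (is.character(tip_state_sets) || is.factor(tip_state_sets))
    tip_state_sets <- lapply(as.list(as.character(tip_state_sets)), identity) |>
      setNames(names(tip_state_sets))
  labs <- tree$tip.label
  absent <- setdiff(labs, names(tip_state_sets))
  if (length(absent))
    stop_nestevo(paste("tips absent from the character data:",
                       paste(absent, collapse = ", ")), "nestevo_missing_taxon")
  k <- length(states)
  L <- matrix(0, k, length(labs))
  for (i in seq_along(labs)) {
    s <- tip_state_sets[[labs[i]]]
    s <- s[!is.na(s)]
    if (length(s) == 0L) {
      L[, i] <- 1
    } else {
      idx <- match(s, states)
      if (anyNA(idx))
        stop_nestevo(sprintf("unknown state label(s) for tip '%s': %s", labs[i],
                             paste(s[is.na(idx)], collapse = ", ")),
                     "nestevo_vocabulary_error")
      L[idx, i] <- 1
    }
  }
  L
}

# Precompute what the C likelihood kernel needs for one tree.
prep_tree <- function(tree, tip_state_sets, states) {
  if (is.null(tree$edge.length))
    stop_nestevo("tree has no branch lengths", "nestevo_invalid_parameter")
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, elen = po$edge.length,
       tipL = tip_partials(po, tip_state_sets, states),
       n_node = length(po$tip.label) + po$Nnode,
       tree = po)
}

#' Phylogenetic log-likelihood of set-valued tip data under an Mk model
#'
#' Computes the pruning (post-order dynamic programming) likelihood with
#' per-node scaling. Polymorphic tips enter as indicator vectors with a 1 on
#' each observed state; missing tips as all-ones vectors; the root partial is
#' combined with the model's root prior.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tip_state_sets Named list mapping every tip label to a character
#'   vector of observed states (empty or `NA` = missing), or a named
#'   character vector of single states.
#' @param model An [mk_model()] with rates set.
#' @return The log-likelihood (a single number).
#' @export
tree_log_likelihood <- function(tree, tip_state_sets, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"))
  if (anyNA(model$rates))
    stop_nestevo("model rates are unset", "nestevo_invalid_parameter")
  pp <- prep_tree(tree, tip_state_sets, model$states)
  er <- model$rate_model == "ER"
  Q <- if (er) matrix(0, model$k, model$k) else mk_generator(model)
  C_mk_loglik(pp$edge, pp$elen, pp$tipL, pp$n_node, Q, model$root_prior,
              er, if (er) model$rates else 0)
}
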