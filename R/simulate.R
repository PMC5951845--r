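#' Simulate a Yule (pure-birth) tree
#'
#' Grows a rooted, binary, ultrametric tree under a constant-rate pure-birth
#' process: starting from two lineages at the root, each of the k extant
#' lineages splits at rate `birth_rate`, until `n_tips` lineages exist; the
#' tree is then extended by one final exponential waiting time so terminal
#' branches have positive length. The expected tree height is
#' `sum(1/(k * birth_rate))` for k = 2..n_tips.
#'
#' @param n_tips Number of terminal taxa (>= 2).
#' @param birth_rate Per-lineage speciation rate (> 0).
#' @param seed Optional integer seed; identical seeds give identical trees.
#' @param tip_labels Optional character vector of `n_tips` unique labels
#'   (default `t1..tn`).
#' @return An object of class `phylo`, rooted, binary and ultrametric, with
#'   all branch lengths positive.
#' @examples
#' tr <- simulate_yule_tree(10, 1, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed = NULL, tip_labels = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2 || n_tips != round(n_tips))
    stop_nestevo("n_tips must be an integer >= 2", "nestevo_invalid_parameter")
  if (!is.numeric(birth_rate) || length(birth_rate) != 1L || birth_rate <= 0)
    stop_nestevo("birth_rate must be > 0", "nestevo_invalid_parameter")
  n <- as.integer(n_tips)
  if (is.null(tip_labels)) tip_labels <- sprintf("t%d", seq_len(n))
  if (length(tip_labels) != n || anyDuplicated(tip_labels))
    stop_nestevo("tip_labels must be n_tips unique labels", "nestevo_invalid_parameter")
  with_seed(seed, {
    waits <- rexp(n - 1L, rate = (2:n) * birth_rate)
    split_times <- cumsum(waits)
    present <- split_times[n - 1L]
    root <- n + 1L
    next_node <- n + 2L
    active_parent <- c(root, root)
    active_start <- c(0, 0)
    edges <- matrix(0L, 2L * n - 2L, 2L)
    elen <- numeric(2L * n - 2L)
    ec <- 0L
    if (n > 2L) {
      for (j in seq_len(n - 2L)) {
        tm <- split_times[j]
        i <- sample.int(length(active_parent), 1L)
        nd <- next_node
        next_node <- next_node + 1L
        ec <- ec + 1L
        edges[ec, ] <- c(active_parent[i], nd)
        elen[ec] <- tm - active_start[i]
        active_parent <- c(active_parent[-i], nd, nd)
        active_start <- c(active_start[-i], tm, tm)
      }
    }
    for (i in seq_along(active_parent)) {
      ec <- ec + 1L
      edges[ec, ] <- c(active_parent[i], i)
      elen[ec] <- present - active_start[i]
    }
    tr <- structure(list(edge = edges, edge.length = elen,
                         tip.label = tip_labels, Nnode = n - 1L),
                    class = "phylo", order = "cladewise")
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Emulate a set of trees with topological and branch-length uncertainty
#'
#' Produces `n_trees` variants of a base tree, each obtained by
#' `perturb_strength` random nearest-neighbour-interchange (NNI) moves
#' followed by multiplicative log-normal branch-length noise with coefficient
#' of variation `bl_jitter` (mean 1, so expected lengths are preserved). This
#' stands in for a pseudo-posterior sample of trees; ultrametricity is not
#' enforced after jitter.
#'
#' @param base_tree A `phylo` tree with branch lengths.
#' @param n_trees Number of trees to generate (>= 1).
#' @param perturb_strength Non-negative integer count of random NNI moves.
#' @param bl_jitter Coefficient of variation of the log-normal noise (>= 0).
#' @param seed Optional integer seed.
#' @return A `multiPhylo` list of `n_trees` trees sharing the tip set of
#'   `base_tree`.
#' @export
perturb_tree_set <- function(base_tree, n_trees, perturb_strength = 0L,
                             bl_jitter = 0, seed = NULL) {
  stopifnot(inherits(base_tree, "phylo"))
  if (!is.numeric(n_trees) || n_trees < 1)
    stop_nestevo("n_trees must be >= 1", "nestevo_invalid_parameter")
  if (perturb_strength < 0 || bl_jitter < 0)
    stop_nestevo("perturb_strength and bl_jitter must be non-negative",
                 "nestevo_invalid_parameter")
  sdlog <- sqrt(log(1 + bl_jitter^2))
  with_seed(seed, {
    out <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      tr <- base_tree
      if (perturb_strength > 0) {
        tr <- phangorn::rNNI(tr, moves = as.integer(perturb_strength), n = 1)
        if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
      }
      if (!setequal(tr$tip.label, base_tree$tip.label))
        stop_nestevo("tip set changed during perturbation",
                     "nestevo_internal_error")
      if (bl_jitter > 0)
        tr$edge.length <- tr$edge.length *
          rlnorm(length(tr$edge.length), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      out[[i]] <- tr
    }
    class(out) <- "multiPhylo"
    out
  })
}

# Simulate a CTMC along a tree. Returns integer states (1..k) for all nodes.
# `er_q` non-NULL triggers the equal-rates closed form; otherwise `Q` is used
# with one transition matrix computed per edge.
sim_ctmc_states <- function(tree, k, root_state, er_q = NULL, Q = NULL) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  state <- integer(nn)
  root <- ntip + 1L
  state[root] <- root_state
  edge <- tree$edge
  elen <- tree$edge.length
  if (!is.null(er_q)) {
    et <- exp(-k * er_q * elen)
    psame <- 1 / k + (k - 1) / k * et
    u <- runif(nrow(edge))
    for (e in seq_len(nrow(edge))) {
      s <- state[edge[e, 1L]]
      if (u[e] < psame[e]) {
        state[edge[e, 2L]] <- s
      } else {
        other <- which(seq_len(k) != s)
        state[edge[e, 2L]] <- other[sample.int(k - 1L, 1L)]
      }
    }
  } else {
    Pcache <- lapply(seq_len(nrow(edge)), function(e) C_expm_Q(Q, elen[e]))
    for (e in seq_len(nrow(edge))) {
      s <- state[edge[e, 1L]]
      p <- Pcache[[e]][s, ]
      state[edge[e, 2L]] <- sample.int(k, 1L, prob = p)
    }
  }
  state
}

#' Simulate a discrete trait on a tree under an Mk model
#'
#' Evolves a k-state character from `root_state` down the tree by drawing each
#' node's state from the model's transition-probability matrix along its
#' parent branch (equal-rates models use the closed form, all-rates-different
#' models the matrix exponential).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model An [mk_model()] with its rate(s) set.
#' @param root_state State at the root: an index in `1..k` or a state label.
#' @param seed Optional integer seed.
#' @return Named character vector mapping each tip to a single state label.
#' @export
simulate_discrete_trait <- function(tree, model, root_state, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"))
  k <- model$k
  rs <- match_state(root_state, model$states)
  with_seed(seed, {
    if (model$rate_model == "ER") {
      st <- sim_ctmc_states(tree, k, rs, er_q = model$rates)
    } else {
      st <- sim_ctmc_states(tree, k, rs, Q = mk_generator(model))
    }
    setNames(model$states[st[seq_along(tree$tip.label)]], tree$tip.label)
  })
}

match_state <- function(root_state, states) {
  if (is.character(root_state)) {
    rs <- match(root_state, states)
    if (is.na(rs))
      stop_nestevo(sprintf("unknown root state '%s'", root_state),
                   "nestevo_invalid_parameter")
    return(rs)
  }
  if (!is.numeric(root_state) || length(root_state) != 1L ||
      root_state < 1 || root_state > length(states) ||
      root_state != round(root_state))
    stop_nestevo("root_state out of range", "nestevo_invalid_parameter")
  as.integer(root_state)
}

#' Inject polymorphism and missing data into simulated tip states
#'
#' Emulates families recorded with more than one state and families whose
#' nests cannot be characterized: each tip is flagged missing with probability
#' `missing_prob`, otherwise it keeps its simulated state and, with
#' probability `poly_prob`, gains one additional distinct state drawn
#' uniformly from the remaining vocabulary.
#'
#' @param tip_states Named character vector from [simulate_discrete_trait()].
#' @param model The [mk_model()] whose state vocabulary applies.
#' @param poly_prob Probability in `[0,1]` of appending a second state.
#' @param missing_prob Probability in `[0,1]` of flagging the tip missing.
#' @param seed Optional integer seed.
#' @return Named list of character vectors (state sets); a missing tip has an
#'   empty set (`character(0)`).
#' @export
simulate_polymorphic_tipset <- function(tip_states, model, poly_prob = 0,
                                        missing_prob = 0, seed = NULL) {
  stopifnot(inherits(model, "mk_model"))
  if (poly_prob < 0 || poly_prob > 1 || missing_prob < 0 || missing_prob > 1 ||
      poly_prob + missing_prob > 1)
    stop_nestevo("poly_prob and missing_prob must lie in [0,1] and sum to <= 1",
                 "nestevo_invalid_parameter")
  states <- model$states
  with_seed(seed, {
    out <- lapply(tip_states, function(s) {
      if (runif(1) < missing_prob) return(character(0))
      set <- s
      if (runif(1) < poly_prob / (1 - missing_prob)) {
        extra <- setdiff(states, s)
        set <- c(s, extra[sample.int(length(extra), 1L)])
      }
      set
    })
    names(out) <- names(tip_states)
    out
  })
}

#' Simulate a pair of binary traits under a dependent (contingent-rates) model
#'
#' Evolves the joint state (A,B) of two binary traits as a 4-state Markov
#' chain over the joint space 00, 01, 10, 11, with eight context-dependent
#' rates (each trait's gain and loss in each state of the other trait) and
#' simultaneous double transitions fixed at rate zero.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param dependent_rates Eight non-negative rates, in the order
#'   `q12, q13, q21, q24, q31, q34, q42, q43` over joint states
#'   1=00, 2=01, 3=10, 4=11 (e.g. `q34` is the gain of B while A = 1).
#' @param root_pair Root joint state: length-2 0/1 vector or one of
#'   `"00","01","10","11"`.
#' @param seed Optional integer seed.
#' @return Integer matrix with one row per tip and columns `A`, `B` (0/1).
#' @export
simulate_correlated_binary_pair <- function(tree, dependent_rates, root_pair,
                                            seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(dependent_rates) != 8L || any(dependent_rates < 0) ||
      any(!is.finite(dependent_rates)))
    stop_nestevo("dependent_rates must be 8 non-negative values",
                 "nestevo_invalid_parameter")
  joint <- c("00", "01", "10", "11")
  if (is.numeric(root_pair) && length(root_pair) == 2L)
    root_pair <- paste0(root_pair[1], root_pair[2])
  rs <- match(root_pair, joint)
  if (is.na(rs))
    stop_nestevo("root_pair must be a binary pair", "nestevo_invalid_parameter")
  Q <- pagel_generator(dependent_rates, kind = "dependent")
  with_seed(seed, {
    st <- sim_ctmc_states(tree, 4L, rs, Q = Q)
    tips <- st[seq_along(tree$tip.label)]
    out <- cbind(A = as.integer(tips >= 3L), B = as.integer(tips %in% c(2L, 4L)))
    rownames(out) <- tree$tip.label
    out
  })
}
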